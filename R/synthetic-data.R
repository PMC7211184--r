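# Ground-truthed synthetic array images. The generator draws the same kind of
# data the slide scanner produces -- a 16-bit grayscale image of the whole
# array -- from a known linear signal model, so every downstream stage can be
# tested against exact truth.
#
# Signal model, per post:
#   noiseless post mean (AFU) = min(background + gain * amount, saturation)
# where `amount` is the miRNA captured by that post's well (amol). Because
# hybridization runs far longer than diffusion/binding timescales, signal
# tracks the total amount per well rather than concentration, which is what
# makes the linear amount -> AFU model appropriate at this scale.
# Negative-control and blank posts always carry amount 0. Pixels not covered
# by a post sit at a darker empty-well floor; a missing post renders at that
# floor, which is what makes its net signal strongly negative (the basis of
# the "< -1000 AFU" missing-post rule).

#' Synthetic assay scenario
#'
#' Bundles the array geometry, plex map, spatial expression pattern and
#' imaging-noise model from which synthetic array images are rendered.
#'
#' @param layout An [array_layout()].
#' @param plex A [plex_map()].
#' @param regions List of regions, each a list with `label` (character),
#'   `polygon` (N x 2 matrix of um coordinates in the array frame) and
#'   `amounts` (named vector, amol/mm^2 of tissue per target probe). Wells
#'   whose centers fall in no region carry amount 0 for every probe.
#' @param gain_afu_per_amol Response slope, AFU per amol captured.
#' @param background_afu Baseline mean AFU of a present post at amount 0
#'   (hydrogel autofluorescence plus nonspecific binding).
#' @param well_floor_afu Mean AFU of well area not covered by a post; missing
#'   posts render at this level. Must be below `background_afu`.
#' @param pixel_noise_sd_afu Gaussian pixel noise SD, AFU.
#' @param saturation_afu Detector cap, AFU.
#' @param dust List with `count`, `side_um` (range, length 2) and
#'   `intensity_afu` (range, length 2) describing bright square dust
#'   artifacts placed uniformly at random.
#' @param missing_post_prob Probability that any given post was lost during
#'   fabrication/handling.
#' @param seed Integer seed; generation is reproducible given the seed.
#'
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(layout = array_layout(),
                               plex = plex_map_default(layout),
                               regions = list(),
                               gain_afu_per_amol = 1000,
                               background_afu = 2000,
                               well_floor_afu = 500,
                               pixel_noise_sd_afu = 50,
                               saturation_afu = 65535,
                               dust = list(count = 0, side_um = c(60, 120),
                                           intensity_afu = c(40000, 60000)),
                               missing_post_prob = 0,
                               seed = 1L) {
  assert_scalar_num(gain_afu_per_amol, "gain_afu_per_amol", nonneg = TRUE)
  assert_scalar_num(background_afu, "background_afu", nonneg = TRUE)
  assert_scalar_num(well_floor_afu, "well_floor_afu", nonneg = TRUE)
  assert_scalar_num(pixel_noise_sd_afu, "pixel_noise_sd_afu", nonneg = TRUE)
  assert_scalar_num(saturation_afu, "saturation_afu", positive = TRUE)
  assert_scalar_num(missing_post_prob, "missing_post_prob", nonneg = TRUE)
  if (missing_post_prob > 1) stop_invalid("missing_post_prob must be <= 1")
  if (well_floor_afu > background_afu)
    stop_invalid("well_floor_afu must not exceed background_afu")
  for (rg in regions) {
    if (is.null(rg$label) || is.null(rg$polygon) || is.null(rg$amounts))
      stop_invalid("each region needs 'label', 'polygon' and 'amounts'")
    if (any(rg$amounts < 0)) stop_invalid("region amounts must be >= 0")
  }
  structure(list(layout = layout, plex = plex, regions = regions,
                 gain_afu_per_amol = gain_afu_per_amol,
                 background_afu = background_afu,
                 well_floor_afu = well_floor_afu,
                 pixel_noise_sd_afu = pixel_noise_sd_afu,
                 saturation_afu = saturation_afu, dust = dust,
                 missing_post_prob = missing_post_prob,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# --- geometry helpers (um -> pixel; array frame has its origin one
#     well-spacing above/left of well (0, 0)) ------------------------------

array_margin_um <- function(layout) layout$well_spacing_um

array_image_dim <- function(layout) {
  ext_x <- 2 * array_margin_um(layout) +
    layout$n_well_cols * layout$well_pitch_um - layout$well_spacing_um
  ext_y <- 2 * array_margin_um(layout) +
    layout$n_well_rows * layout$well_pitch_um - layout$well_spacing_um
  c(ny = as.integer(ceiling(ext_y / layout$pixel_size_um)),
    nx = as.integer(ceiling(ext_x / layout$pixel_size_um)))
}

well_origin_um <- function(layout, well_row, well_col) {
  m <- array_margin_um(layout)
  cbind(x = m + well_col * layout$well_pitch_um,
        y = m + well_row * layout$well_pitch_um)
}

well_center_um <- function(layout, well_row, well_col) {
  o <- well_origin_um(layout, well_row, well_col)
  o + layout$well_side_um / 2
}

post_margin_um <- function(layout) {
  ext <- (layout$post_grid_cols - 1) * layout$post_pitch_um +
    layout$post_side_um
  (layout$well_side_um - ext) / 2
}

# Upper-left corner (um) of post (post_row, post_col) in well (well_row,
# well_col); all indices 0-based.
post_origin_um <- function(layout, well_row, well_col, post_row, post_col) {
  o <- well_origin_um(layout, well_row, well_col)
  pm <- post_margin_um(layout)
  cbind(x = o[, "x"] + pm + post_col * layout$post_pitch_um,
        y = o[, "y"] + pm + post_row * layout$post_pitch_um)
}

um_to_px <- function(um, pixel_size_um) as.integer(floor(um / pixel_size_um))

post_side_px <- function(layout) {
  max(1L, as.integer(round(layout$post_side_um / layout$pixel_size_um)))
}

# --- truth table ----------------------------------------------------------

# Region label for each well center; NA when outside every polygon. Ties go
# to the first-listed region.
well_region_labels <- function(layout, regions) {
  wells <- expand.grid(well_col = seq_len(layout$n_well_cols) - 1L,
                       well_row = seq_len(layout$n_well_rows) - 1L)
  lab <- rep(NA_character_, nrow(wells))
  if (length(regions)) {
    ctr <- well_center_um(layout, wells$well_row, wells$well_col)
    for (rg in rev(regions)) {
      poly <- as.matrix(rg$polygon)
      inside <- mgcv::in.out(poly, cbind(ctr[, "x"], ctr[, "y"]))
      lab[inside] <- rg$label
    }
  }
  data.frame(well_row = wells$well_row, well_col = wells$well_col,
             region = lab, stringsAsFactors = FALSE)
}

# Build the per-(well, post) ground truth for a scenario. `amount_override`,
# if given, is a named vector of per-well amol applied to every well
# (calibration mode), bypassing the region densities.
build_ground_truth <- function(scenario, amount_override = NULL) {
  layout <- scenario$layout
  plex <- scenario$plex$entries
  wl <- well_region_labels(layout, scenario$regions)
  footprint_mm2 <- (layout$well_side_um / 1000)^2

  n_posts <- nrow(plex)
  truth <- do.call(rbind, lapply(seq_len(nrow(wl)), function(i) {
    data.frame(well_row = wl$well_row[i], well_col = wl$well_col[i],
               post_row = plex$post_row, post_col = plex$post_col,
               probe = plex$probe, role = plex$role,
               region = wl$region[i], stringsAsFactors = FALSE)
  }))

  amount <- numeric(nrow(truth))
  is_target <- truth$role == "target"
  if (!is.null(amount_override)) {
    idx <- match(truth$probe, names(amount_override))
    amount[is_target & !is.na(idx)] <-
      amount_override[idx[is_target & !is.na(idx)]]
  } else if (length(scenario$regions)) {
    dens <- matrix(0, nrow(truth), 1)
    for (rg in scenario$regions) {
      sel <- is_target & !is.na(truth$region) & truth$region == rg$label
      d <- rg$amounts[truth$probe[sel]]
      d[is.na(d)] <- 0
      amount[sel] <- d * footprint_mm2
    }
  }
  truth$amount_amol <- amount
  truth$mean_afu <- pmin(scenario$background_afu +
                           scenario$gain_afu_per_amol * amount,
                         scenario$saturation_afu)
  truth$missing <- FALSE
  truth
}

# --- rendering ------------------------------------------------------------

#' Render a synthetic array image
#'
#' Draws a full-array fluorescence image from a scenario: well floors and
#' inter-well gaps at the floor level, each present post at its noiseless
#' mean, independent Gaussian pixel noise, and bright square dust artifacts.
#' Missing posts (lost during fabrication) are drawn at the well-floor level.
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Seed for this render; defaults to `scenario$seed`.
#' @param amount_override Optional named vector of per-well amounts (amol)
#'   applied uniformly to every well, overriding region densities (used for
#'   calibration series).
#' @return A list with `image` (numeric matrix, AFU; rows = y, cols = x) and
#'   `truth` (data frame: well/post indices, probe, role, region,
#'   `amount_amol`, noiseless `mean_afu`, `missing`).
#' @export
render_array_image <- function(scenario, seed = scenario$seed,
                               amount_override = NULL) {
  layout <- scenario$layout
  truth <- build_ground_truth(scenario, amount_override)
  dm <- array_image_dim(layout)
  psz <- layout$pixel_size_um
  side_px <- post_side_px(layout)

  with_seed(seed, {
    truth$missing <- stats::runif(nrow(truth)) < scenario$missing_post_prob

    img <- matrix(scenario$well_floor_afu, nrow = dm["ny"], ncol = dm["nx"])
    po <- post_origin_um(layout, truth$well_row, truth$well_col,
                         truth$post_row, truth$post_col)
    x0 <- um_to_px(po[, "x"], psz)
    y0 <- um_to_px(po[, "y"], psz)
    for (i in seq_len(nrow(truth))) {
      if (truth$missing[i]) next
      img[(y0[i] + 1):(y0[i] + side_px),
          (x0[i] + 1):(x0[i] + side_px)] <- truth$mean_afu[i]
    }

    if (scenario$pixel_noise_sd_afu > 0)
      img <- img + matrix(stats::rnorm(length(img), 0,
                                       scenario$pixel_noise_sd_afu),
                          nrow = nrow(img))

    d <- scenario$dust
    if (!is.null(d) && (d$count %||% 0) > 0) {
      for (k in seq_len(d$count)) {
        side <- stats::runif(1, d$side_um[1], d$side_um[2]) / psz
        side <- max(1L, as.integer(round(side)))
        x <- sample.int(ncol(img) - side + 1L, 1L)
        y <- sample.int(nrow(img) - side + 1L, 1L)
        val <- stats::runif(1, d$intensity_afu[1], d$intensity_afu[2])
        img[y:(y + side - 1L), x:(x + side - 1L)] <- val
      }
    }

    img[img < 0] <- 0
    img[img > scenario$saturation_afu] <- scenario$saturation_afu
    list(image = img, truth = truth)
  })
}

#' Ideal anchors for a synthetic render
#'
#' Returns the two-anchor registration input (upper-left pixel of the
#' upper-left post of two wells) implied by the scenario geometry, as the
#' analyst would read it off the image.
#'
#' @param layout An [array_layout()].
#' @param wells 2 x 2 integer matrix of the two anchor wells' (row, col),
#'   0-based; defaults to the first and last well.
#' @return A list of two [anchor()] objects.
#' @export
scenario_anchors <- function(layout,
                             wells = rbind(c(0L, 0L),
                                           c(layout$n_well_rows - 1L,
                                             layout$n_well_cols - 1L))) {
  lapply(seq_len(nrow(wells)), function(i) {
    po <- post_origin_um(layout, wells[i, 1], wells[i, 2], 0L, 0L)
    anchor(well = c(wells[i, 1], wells[i, 2]),
           pixel = c(um_to_px(po[, "x"], layout$pixel_size_um),
                     um_to_px(po[, "y"], layout$pixel_size_um)))
  })
}

#' Generate a calibration dilution series
#'
#' One rendered image per spiked amount per replicate. Every target post in
#' every well receives the same per-well amount, emulating a synthetic-target
#' calibration run. Seeds are derived deterministically from the scenario
#' seed, so the series is reproducible.
#'
#' @param amounts Spiked per-well amounts (amol); must include 0 (blank).
#' @param replicates Images per amount.
#' @param scenario A [synthetic_scenario()].
#' @return A data-frame-indexed list: `series$amount`, `series$replicate`,
#'   and `series$renders` (list of `render_array_image()` results, in the
#'   same order).
#' @export
generate_calibration_series <- function(amounts, replicates = 1,
                                        scenario = synthetic_scenario()) {
  if (length(amounts) == 0) stop_invalid("'amounts' must be non-empty")
  if (any(amounts < 0)) stop_invalid("'amounts' must be >= 0")
  if (!any(amounts == 0))
    stop_invalid("'amounts' must include 0 (the blank)")
  replicates <- as.integer(replicates)
  if (replicates < 1) stop_invalid("'replicates' must be >= 1")
  targets <- unique(scenario$plex$entries$probe[
    scenario$plex$entries$role == "target"])
  grid <- expand.grid(replicate = seq_len(replicates),
                      amount = amounts)[, 2:1]
  renders <- lapply(seq_len(nrow(grid)), function(i) {
    ov <- stats::setNames(rep(grid$amount[i], length(targets)), targets)
    render_array_image(scenario,
                       seed = derive_seed(scenario$seed, i),
                       amount_override = ov)
  })
  list(amount = grid$amount, replicate = grid$replicate, renders = renders)
}

#' Null scenario (no regional differences)
#'
#' Copies a scenario but gives every region the first region's amounts, so
#' any detected between-region difference is a false positive. Used to check
#' the size of the region-comparison tests.
#'
#' @param base A [synthetic_scenario()] with at least one region.
#' @return A `synthetic_scenario` with identical region amounts.
#' @export
generate_null_scenario <- function(base) {
  if (!length(base$regions)) return(base)
  ref <- base$regions[[1]]$amounts
  base$regions <- lapply(base$regions, function(rg) {
    rg$amounts <- ref
    rg
  })
  base
}

#' Generate serial tissue sections
#'
#' Renders `n_sections` images of the same scenario, multiplying every
#' region's amounts in section s by an independent positive factor with unit
#' mean and coefficient of variation `section_cv` (log-normal), emulating
#' section-to-section biological and assay variability.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_sections Number of sections (>= 2).
#' @param section_cv Coefficient of variation of the section factors
#'   (fraction, e.g. 0.15).
#' @return A list with `factors` (numeric, one per section) and `renders`
#'   (list of render results).
#' @export
generate_serial_sections <- function(scenario, n_sections, section_cv) {
  n_sections <- as.integer(n_sections)
  if (n_sections < 2) stop_invalid("'n_sections' must be >= 2")
  assert_scalar_num(section_cv, "section_cv", nonneg = TRUE)
  factors <- with_seed(derive_seed(scenario$seed, 777L), {
    if (section_cv == 0) rep(1, n_sections)
    else {
      sdl <- sqrt(log(1 + section_cv^2))
      stats::rlnorm(n_sections, meanlog = -sdl^2 / 2, sdlog = sdl)
    }
  })
  renders <- lapply(seq_len(n_sections), function(s) {
    sc <- scenario
    sc$regions <- lapply(sc$regions, function(rg) {
      rg$amounts <- rg$amounts * factors[s]
      rg
    })
    render_array_image(sc, seed = derive_seed(scenario$seed, 1000L + s))
  })
  list(factors = factors, renders = renders)
}

#' Write a rendered image as a 16-bit grayscale TIFF
#'
#' AFU values are stored directly as 16-bit sample values (clamped to
#' 0..65535), matching the slide scanner's output convention.
#'
#' @param image Numeric matrix of AFU values.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_array_tiff <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale array TIFF into AFU
#'
#' @param path TIFF file path.
#' @return Numeric matrix of AFU values.
#' @export
read_array_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 1.0
}
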