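# Physical description of the nanoliter well array and the design arithmetic
# used to size it: well counts per slide area, well volume, post packing,
# expected captured amount per well, and detectability against an assay LOD.

#' Nanoliter well array layout
#'
#' Describes the physical geometry of a nanoliter well array: square wells on
#' a regular lattice, each containing a small square grid of hydrogel posts,
#' imaged at a fixed pixel size. All lengths are in micrometers. The default
#' values describe a 1 cm x 1 cm array of 300 um wells, 39 um deep, separated
#' by 50 um, with a 3 x 3 grid of 40 um posts per well at 100 um pitch,
#' scanned at 5 um per pixel.
#'
#' @param well_side_um Side length of a (square) well, um.
#' @param well_depth_um Well depth, um.
#' @param well_spacing_um Gap between adjacent wells, um. The well pitch is
#'   `well_side_um + well_spacing_um`.
#' @param n_well_rows,n_well_cols Number of well rows/columns on the array.
#' @param post_side_um Side length of a (square) post, um.
#' @param post_grid_rows,post_grid_cols Post grid dimensions within a well.
#' @param post_pitch_um Center-to-center post spacing within a well, um.
#' @param pixel_size_um Scanner pixel size, um/pixel.
#'
#' @return An object of class `array_layout` (a validated list of the above
#'   fields plus the derived `well_pitch_um`).
#' @examples
#' layout <- array_layout()
#' well_volume_nl(layout)
#' @export
array_layout <- function(well_side_um = 300, well_depth_um = 39,
                         well_spacing_um = 50,
                         n_well_rows = 28, n_well_cols = 28,
                         post_side_um = 40, post_grid_rows = 3,
                         post_grid_cols = 3, post_pitch_um = 100,
                         pixel_size_um = 5) {
  for (nm in c("well_side_um", "well_depth_um", "well_spacing_um",
               "post_side_um", "post_pitch_um", "pixel_size_um"))
    assert_scalar_num(get(nm), nm, positive = nm != "well_spacing_um",
                      nonneg = TRUE)
  for (nm in c("n_well_rows", "n_well_cols", "post_grid_rows",
               "post_grid_cols")) {
    v <- get(nm)
    assert_scalar_num(v, nm, positive = TRUE)
    if (v != as.integer(v)) stop_invalid("'%s' must be a whole number", nm)
  }
  extent_c <- (post_grid_cols - 1) * post_pitch_um + post_side_um
  extent_r <- (post_grid_rows - 1) * post_pitch_um + post_side_um
  if (extent_c > well_side_um || extent_r > well_side_um)
    stop_invalid("post grid (%g x %g um) does not fit inside a %g um well",
                 extent_c, extent_r, well_side_um)
  structure(list(
    well_side_um = well_side_um, well_depth_um = well_depth_um,
    well_spacing_um = well_spacing_um,
    n_well_rows = as.integer(n_well_rows),
    n_well_cols = as.integer(n_well_cols),
    post_side_um = post_side_um,
    post_grid_rows = as.integer(post_grid_rows),
    post_grid_cols = as.integer(post_grid_cols),
    post_pitch_um = post_pitch_um, pixel_size_um = pixel_size_um,
    well_pitch_um = well_side_um + well_spacing_um
  ), class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf(
    "array_layout: %d x %d wells of %g um (depth %g um, spacing %g um)\n",
    x$n_well_rows, x$n_well_cols, x$well_side_um, x$well_depth_um,
    x$well_spacing_um))
  cat(sprintf("  posts: %d x %d of %g um at %g um pitch; %g um/pixel\n",
              x$post_grid_rows, x$post_grid_cols, x$post_side_um,
              x$post_pitch_um, x$pixel_size_um))
  invisible(x)
}

#' Probe-per-post assignment (plex map)
#'
#' Maps each post position within a well to a probe name and a role. Every
#' well on the array carries the same post grid, so one map describes the
#' whole array. Roles are `"target"` (a miRNA being measured),
#' `"negative_control"` (a probe against a sequence absent from the sample,
#' e.g. cel-miR-54, used as the subtraction control), and `"blank"` (a post
#' with no probe).
#'
#' @param entries A data frame with columns `post_row`, `post_col` (0-based
#'   position within the well's post grid), `probe` (character) and `role`
#'   (one of `"target"`, `"negative_control"`, `"blank"`).
#' @param layout An [array_layout()]; used to check that every post position
#'   has exactly one entry.
#' @param control_probe Name of the negative-control probe used for net-signal
#'   subtraction. Defaults to the single `negative_control` entry, if unique.
#'
#' @return An object of class `plex_map`.
#' @examples
#' plex_map_default()
#' @export
plex_map <- function(entries, layout = array_layout(), control_probe = NULL) {
  req <- c("post_row", "post_col", "probe", "role")
  if (!is.data.frame(entries) || !all(req %in% names(entries)))
    stop_invalid("'entries' must be a data frame with columns %s",
                 paste(req, collapse = ", "))
  ok_roles <- c("target", "negative_control", "blank")
  if (!all(entries$role %in% ok_roles))
    stop_invalid("roles must be one of: %s", paste(ok_roles, collapse = ", "))
  want <- expand.grid(post_row = seq_len(layout$post_grid_rows) - 1L,
                      post_col = seq_len(layout$post_grid_cols) - 1L)
  key <- function(d) paste(d$post_row, d$post_col)
  if (anyDuplicated(key(entries)))
    stop_invalid("duplicate post positions in plex map")
  if (!setequal(key(entries), key(want)) ||
      nrow(entries) != nrow(want))
    stop_invalid("plex map must cover every post position exactly once")
  nc <- unique(entries$probe[entries$role == "negative_control"])
  if (is.null(control_probe)) {
    if (length(nc) == 1L) control_probe <- nc
    else if (length(nc) > 1L)
      stop_invalid("several negative_control probes; set 'control_probe'")
  } else if (!control_probe %in% entries$probe) {
    stop_invalid("control_probe '%s' is not in the plex map", control_probe)
  }
  entries <- entries[order(entries$post_row, entries$post_col), req]
  rownames(entries) <- NULL
  structure(list(entries = entries, control_probe = control_probe),
            class = "plex_map")
}

#' @rdname plex_map
#' @details `plex_map_default()` returns the nine-post map used throughout
#'   the examples: seven miRNA targets, one cel-miR-54 negative control and
#'   one blank post.
#' @export
plex_map_default <- function(layout = array_layout()) {
  probes <- c("miR-21", "let-7a", "miR-16", "miR-19b",
              "miR-210", "miR-20a", "miR-15b",
              "cel-miR-54", "blank")
  roles <- c(rep("target", 7), "negative_control", "blank")
  grid <- expand.grid(post_col = seq_len(layout$post_grid_cols) - 1L,
                      post_row = seq_len(layout$post_grid_rows) - 1L)
  plex_map(data.frame(post_row = grid$post_row, post_col = grid$post_col,
                      probe = probes[seq_len(nrow(grid))],
                      role = roles[seq_len(nrow(grid))],
                      stringsAsFactors = FALSE),
           layout = layout)
}

#' @export
print.plex_map <- function(x, ...) {
  cat(sprintf("plex_map: %d posts (control: %s)\n", nrow(x$entries),
              x$control_probe %||% "<none>"))
  print(x$entries)
  invisible(x)
}

#' Wells fitting in a rectangular area
#'
#' How many wells fit in a `width_um` x `height_um` area, given the well side
#' and spacing. The trailing gap after the last well in each direction is not
#' required, so an area of exactly `n * pitch - spacing` holds `n` wells; a
#' 1 cm x 1 cm area holds 28 x 28 = 784 wells of 300 um at 50 um spacing.
#'
#' @param width_um,height_um Area dimensions, um.
#' @param layout An [array_layout()].
#' @return A list with `rows`, `cols` and `total`.
#' @examples
#' wells_per_area(10000, 10000, array_layout())$total  # 784
#' @export
wells_per_area <- function(width_um, height_um, layout = array_layout()) {
  assert_scalar_num(width_um, "width_um", positive = TRUE)
  assert_scalar_num(height_um, "height_um", positive = TRUE)
  pitch <- layout$well_pitch_um
  rows <- max(0L, as.integer(floor((height_um + layout$well_spacing_um) / pitch)))
  cols <- max(0L, as.integer(floor((width_um + layout$well_spacing_um) / pitch)))
  list(rows = rows, cols = cols, total = rows * cols)
}

#' Volume of one well in nanoliters
#'
#' `side^2 * depth` converted from cubic micrometers to nanoliters
#' (1 nL = 1e6 um^3). The default geometry gives 3.51 nL.
#'
#' @param layout An [array_layout()].
#' @return Volume in nL.
#' @export
well_volume_nl <- function(layout = array_layout()) {
  layout$well_side_um^2 * layout$well_depth_um / 1e6
}

#' Posts fitting in one well on a square grid
#'
#' Number of square posts of side `post_side_um` that fit inside a square
#' well of side `well_side_um` when placed on a square grid with
#' center-to-center pitch `post_pitch_um`. The grid is anchored so its extent
#' `(n - 1) * pitch + post_side` fits within the well; a 300 um well holds a
#' 6 x 6 grid (36 posts) of 20 um posts at 50 um pitch, and a 3 x 3 grid of
#' 40 um posts at 100 um pitch.
#'
#' @param well_side_um Well side, um.
#' @param post_side_um Post side, um.
#' @param post_pitch_um Post pitch, um (must satisfy
#'   `post_side <= pitch <= well_side`).
#' @return Integer post count.
#' @examples
#' posts_per_well(300, 20, 50)  # 36
#' @export
posts_per_well <- function(well_side_um, post_side_um, post_pitch_um) {
  assert_scalar_num(well_side_um, "well_side_um", positive = TRUE)
  assert_scalar_num(post_side_um, "post_side_um", positive = TRUE)
  assert_scalar_num(post_pitch_um, "post_pitch_um", positive = TRUE)
  if (post_side_um > well_side_um)
    stop_invalid("post (%g um) larger than well (%g um)",
                 post_side_um, well_side_um)
  if (post_pitch_um < post_side_um || post_pitch_um > well_side_um)
    stop_invalid("post_pitch_um must lie in [post_side_um, well_side_um]")
  n <- floor((well_side_um - post_side_um) / post_pitch_um) + 1
  # guard against floating-point overshoot of the grid extent
  while (n > 1 && (n - 1) * post_pitch_um + post_side_um > well_side_um)
    n <- n - 1
  as.integer(n)^2
}

#' Expected captured amount per well
#'
#' Amount of analyte expected in one well when the tissue above it carries an
#' areal density of `areal_density_amol_per_mm2` and the well captures its
#' own footprint's worth: `density * footprint`. A 300 um well has a 0.09 mm^2
#' footprint, so 5 amol/mm^2 gives 0.45 amol/well.
#'
#' @param areal_density_amol_per_mm2 Tissue areal density, amol/mm^2.
#' @param layout An [array_layout()].
#' @return Amount in amol.
#' @export
expected_amount_per_well <- function(areal_density_amol_per_mm2,
                                     layout = array_layout()) {
  assert_scalar_num(areal_density_amol_per_mm2, "areal_density_amol_per_mm2",
                    nonneg = TRUE)
  areal_density_amol_per_mm2 * (layout$well_side_um / 1000)^2
}

#' Detectability ratio
#'
#' Ratio of the expected per-well amount to the assay limit of detection.
#' A ratio above 1 means the expected amount should be detectable.
#'
#' @param expected_amol Expected amount per well, amol.
#' @param lod_amol Limit of detection, amol (must be > 0).
#' @return A list with `ratio` and logical `detectable`.
#' @export
detectability_ratio <- function(expected_amol, lod_amol) {
  assert_scalar_num(expected_amol, "expected_amol", nonneg = TRUE)
  assert_scalar_num(lod_amol, "lod_amol", positive = TRUE)
  r <- expected_amol / lod_amol
  list(ratio = r, detectable = r > 1)
}

#' Fabrication post-loss percentage
#'
#' Percentage of posts lost during fabrication/assay handling, from counted
#' losses: `100 * n_lost / n_total`.
#'
#' @param n_lost,n_total Counts; `0 <= n_lost <= n_total`, `n_total > 0`.
#' @return Percentage.
#' @examples
#' post_loss_percent(10, 1568)  # ~0.64, i.e. 0.6% at one decimal
#' @export
post_loss_percent <- function(n_lost, n_total) {
  assert_scalar_num(n_lost, "n_lost", nonneg = TRUE)
  assert_scalar_num(n_total, "n_total", positive = TRUE)
  if (n_lost > n_total) stop_invalid("n_lost exceeds n_total")
  100 * n_lost / n_total
}

#' Array design summary table
#'
#' One-stop design calculator: well volume, wells per area, post packing
#' options, expected per-well amount at a given tissue density, and
#' detectability against a given LOD.
#'
#' @param layout An [array_layout()].
#' @param area_width_um,area_height_um Usable slide area, um.
#' @param areal_density_amol_per_mm2 Expected tissue areal density, amol/mm^2.
#' @param lod_amol Assay limit of detection, amol.
#' @return A data frame of named design quantities with values and units.
#' @export
design_summary <- function(layout = array_layout(),
                           area_width_um = 10000, area_height_um = 10000,
                           areal_density_amol_per_mm2 = 5,
                           lod_amol = 0.023) {
  wa <- wells_per_area(area_width_um, area_height_um, layout)
  exp_amol <- expected_amount_per_well(areal_density_amol_per_mm2, layout)
  det <- detectability_ratio(exp_amol, lod_amol)
  data.frame(
    quantity = c("well_volume", "well_rows", "well_cols", "wells_total",
                 "posts_per_well", "expected_amount_per_well",
                 "lod", "detectability_ratio"),
    value = c(well_volume_nl(layout), wa$rows, wa$cols, wa$total,
              posts_per_well(layout$well_side_um, layout$post_side_um,
                             layout$post_pitch_um),
              exp_amol, lod_amol, det$ratio),
    unit = c("nL", "wells", "wells", "wells", "posts", "amol", "amol", ""),
    stringsAsFactors = FALSE
  )
}
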