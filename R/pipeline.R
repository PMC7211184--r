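# End-to-end orchestration: structured configs in, CSV/TIFF artifacts out,
# every run recorded in a manifest (config snapshot, seed, file checksums)
# so deterministic stages reproduce bit-for-bit.

#' Read and write array configuration
#'
#' The configuration is a YAML document with sections `layout` (fields of
#' [array_layout()]), `plex` (list of `{post_row, post_col, probe, role}`
#' entries plus optional `control_probe`), and optionally `scenario`
#' (fields of [synthetic_scenario()], with regions' polygons as lists of
#' `[x, y]` pairs) and `qc` (fields of [qc_config()]).
#'
#' @param path Path to a YAML config file.
#' @return A list with `layout`, `plex`, and (if present) `scenario`, `qc`.
#' @export
read_array_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  layout <- do.call(array_layout, cfg$layout %||% list())
  plex <- if (!is.null(cfg$plex)) {
    entries <- do.call(rbind, lapply(cfg$plex$entries, function(e)
      data.frame(post_row = e$post_row, post_col = e$post_col,
                 probe = e$probe, role = e$role, stringsAsFactors = FALSE)))
    plex_map(entries, layout = layout,
             control_probe = cfg$plex$control_probe %||% NULL)
  } else {
    plex_map_default(layout)
  }
  out <- list(layout = layout, plex = plex)
  if (!is.null(cfg$scenario)) {
    sc <- cfg$scenario
    regions <- lapply(sc$regions %||% list(), function(rg)
      list(label = rg$label,
           polygon = do.call(rbind, rg$polygon),
           amounts = unlist(rg$amounts)))
    args <- sc[setdiff(names(sc), "regions")]
    args$layout <- layout; args$plex <- plex; args$regions <- regions
    if (!is.null(args$dust)) args$dust <- lapply(args$dust, unlist)
    out$scenario <- do.call(synthetic_scenario, args)
  }
  if (!is.null(cfg$qc)) out$qc <- do.call(qc_config, cfg$qc)
  out
}

#' @rdname read_array_config
#' @param config A list as returned by `read_array_config()` (or with the
#'   same shape).
#' @export
write_array_config <- function(config, path) {
  lay <- config$layout
  doc <- list(layout = lay[setdiff(names(lay), "well_pitch_um")])
  if (!is.null(config$plex)) {
    entries <- config$plex$entries
    doc$plex <- list(
      control_probe = config$plex$control_probe,
      entries = lapply(seq_len(nrow(entries)), function(i)
        as.list(entries[i, ])))
  }
  if (!is.null(config$scenario)) {
    sc <- unclass(config$scenario)
    sc$layout <- NULL; sc$plex <- NULL
    sc$regions <- lapply(sc$regions, function(rg)
      list(label = rg$label,
           polygon = lapply(seq_len(nrow(rg$polygon)), function(i)
             as.numeric(rg$polygon[i, ])),
           amounts = as.list(rg$amounts)))
    doc$scenario <- sc
  }
  if (!is.null(config$qc)) doc$qc <- unclass(config$qc)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read and write region masks
#'
#' Masks are stored as GeoJSON-style JSON: a list of features, each with a
#' `label` and a `polygon` given as a list of `[x, y]` um coordinates.
#'
#' @param path Path to a JSON mask file.
#' @return A [region_mask()].
#' @export
read_region_mask <- function(path) {
  if (!file.exists(path)) stop_invalid("mask file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- js$features %||% js
  region_mask(lapply(feats, function(f)
    list(label = f$label,
         polygon = do.call(rbind, lapply(f$polygon, as.numeric)))))
}

#' @rdname read_region_mask
#' @param mask A [region_mask()].
#' @export
write_region_mask <- function(mask, path) {
  feats <- lapply(mask$regions, function(rg)
    list(label = rg$label,
         polygon = lapply(seq_len(nrow(rg$polygon)), function(i)
           as.numeric(rg$polygon[i, ]))))
  jsonlite::write_json(list(features = feats), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

write_manifest <- function(out_dir, seed, extra = list()) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(list(
    package = "nanowellr",
    version = as.character(utils::packageVersion("nanowellr")),
    seed = seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.list(stats::setNames(unname(sums), files))), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a scenario to disk
#'
#' Renders the scenario image(s), writes the 16-bit TIFF, the ground-truth
#' table, the per-well region labels and a manifest with checksums.
#' Deterministic for a fixed seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param seed Seed override; defaults to the scenario's seed.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(scenario, out_dir, seed = scenario$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenario$seed <- as.integer(seed)
  ren <- render_array_image(scenario, seed = seed)
  write_array_tiff(ren$image, file.path(out_dir, "array.tiff"))
  utils::write.csv(ren$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  anchors <- scenario_anchors(scenario$layout)
  anc <- do.call(rbind, lapply(anchors, function(a)
    data.frame(well_row = a$well[1], well_col = a$well[2],
               x = a$pixel[1], y = a$pixel[2])))
  utils::write.csv(anc, file.path(out_dir, "anchors.csv"), row.names = FALSE)
  write_manifest(out_dir, seed)
  invisible(out_dir)
}

#' Quantify an array image end to end
#'
#' Runs the fixed stage order: dust removal (optional), two-anchor grid
#' registration, post mean extraction, optional central-window selection,
#' net-signal computation, missing-post flagging, and (when calibration
#' curves are supplied) conversion to amounts. Stage-level removal counts
#' are returned in `log`.
#'
#' @param image Numeric AFU matrix (e.g. from [read_array_tiff()]).
#' @param anchors List of two [anchor()]s.
#' @param layout An [array_layout()].
#' @param plex A [plex_map()].
#' @param qc A [qc_config()].
#' @param dust_threshold_afu Dust threshold, AFU; `NULL` skips dust removal
#'   (arrays handled cleanly do not need it).
#' @param window `NULL`, or `c(rows, cols)` for the centered analysis
#'   window.
#' @param curves Optional named list of calibration curves.
#' @return A list with `measurements` (post table), `wq` (well
#'   quantification after missing-post filtering), `flagged` (rows removed)
#'   and `log` (named counts).
#' @export
run_quantify <- function(image, anchors, layout = array_layout(),
                         plex = plex_map_default(layout),
                         qc = qc_config(), dust_threshold_afu = NULL,
                         window = NULL, curves = NULL) {
  if (length(anchors) != 2L)
    stop_invalid("exactly two anchors are required")
  if (is.null(plex$control_probe))
    stop_invalid("plex map has no designated control probe")
  log <- list()
  if (!is.null(dust_threshold_afu)) {
    dr <- remove_dust(image, dust_threshold_afu, layout)
    image <- dr$image
    log$dust_components_removed <- length(dr$removed_components)
  }
  grid <- register_grid(anchors[[1]], anchors[[2]], layout,
                        image_dim = dim(image))
  tab <- extract_post_means(image, grid, plex)
  log$posts_extracted <- nrow(tab)
  log$posts_out_of_frame <- sum(tab$flags == "out_of_frame")
  if (!is.null(window)) {
    tab <- select_window(tab, window[1], window[2], layout)
    log$posts_in_window <- nrow(tab)
  }
  wq <- net_signal(tab, plex$control_probe)
  fm <- flag_missing_posts(wq, qc)
  log$missing_posts_removed <- fm$n_removed
  wq <- fm$retained
  if (!is.null(curves)) wq <- apply_calibration(wq, curves)
  list(measurements = tab, wq = wq, flagged = fm$flagged, log = log)
}

#' Calibrate from a dilution series
#'
#' Quantifies every render of a calibration series and fits one curve per
#' target probe from the pooled well-level nets.
#'
#' @param series Output of [generate_calibration_series()].
#' @param scenario The scenario the series was generated from (supplies
#'   layout, plex and anchors).
#' @param window Optional centered window `c(rows, cols)` applied to each
#'   image.
#' @param qc A [qc_config()].
#' @return Named list of `calibration_curve`s, one per target probe.
#' @export
run_calibrate <- function(series, scenario, window = NULL,
                          qc = qc_config()) {
  layout <- scenario$layout
  anchors <- scenario_anchors(layout)
  nets <- list()
  for (i in seq_along(series$renders)) {
    q <- run_quantify(series$renders[[i]]$image, anchors, layout,
                      scenario$plex, qc = qc, window = window)
    wq <- q$wq
    wq$amount <- series$amount[i]
    nets[[i]] <- wq[, c("probe", "net_afu", "amount")]
  }
  nets <- do.call(rbind, nets)
  nets <- nets[is.finite(nets$net_afu), ]
  curves <- lapply(split(nets, nets$probe), function(d)
    fit_calibration(d$amount, d$net_afu, probe = d$probe[1]))
  curves
}

#' Report heatmaps and region statistics
#'
#' From a filtered well quantification and a region mask: per-probe
#' heatmaps, per-region summaries, Tukey HSD pairwise comparisons with star
#' labels, and (optionally) writes everything as CSV.
#'
#' @param wq Well quantification (after QC).
#' @param layout An [array_layout()].
#' @param mask A [region_mask()], or `NULL` for heatmaps only.
#' @param what `"amount_amol"` or `"net_afu"`.
#' @param alpha Tukey family-wise level.
#' @param out_dir Optional output directory for CSV artifacts.
#' @return A list with `heatmaps` (named list of matrices), `summary`
#'   (region summary data frame or NULL), `comparisons` (named list of
#'   Tukey tables per probe, or NULL).
#' @export
run_report <- function(wq, layout = array_layout(), mask = NULL,
                       what = c("amount_amol", "net_afu"), alpha = 0.05,
                       out_dir = NULL) {
  what <- match.arg(what)
  probes <- unique(wq$probe)
  heatmaps <- stats::setNames(
    lapply(probes, function(p) build_heatmap(wq, p, layout, what)), probes)
  summary <- comparisons <- NULL
  if (!is.null(mask)) {
    assignment <- assign_wells_to_regions(layout, mask)
    summary <- region_summary(wq, assignment, what)
    values <- attr(summary, "values")
    comparisons <- lapply(stats::setNames(probes, probes), function(p) {
      rows <- summary[summary$probe == p & summary$n >= 2, ]
      if (nrow(rows) < 2L) return(NULL)
      groups <- stats::setNames(
        values[paste(p, rows$region, sep = "\r")], rows$region)
      tukey_hsd(groups, alpha = alpha)
    })
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in probes)
      utils::write.csv(unclass(heatmaps[[p]]),
                       file.path(out_dir, paste0("heatmap_", gsub("[^A-Za-z0-9_-]", "_", p), ".csv")),
                       row.names = FALSE)
    if (!is.null(summary))
      utils::write.csv(summary, file.path(out_dir, "region_summary.csv"),
                       row.names = FALSE)
    cmp <- do.call(rbind, lapply(names(comparisons), function(p) {
      d <- comparisons[[p]]
      if (is.null(d)) return(NULL)
      cbind(probe = p, d)
    }))
    if (!is.null(cmp))
      utils::write.csv(cmp, file.path(out_dir, "tukey_comparisons.csv"),
                       row.names = FALSE)
  }
  list(heatmaps = heatmaps, summary = summary, comparisons = comparisons)
}

#' Write calibration curves as CSV
#'
#' @param curves Named list of `calibration_curve`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cu)
    data.frame(probe = cu$probe, slope = cu$slope,
               intercept = cu$intercept, residual_sd = cu$residual_sd,
               blank_sd = cu$blank_sd, lod_amol = cu$lod_amol,
               n_points = cu$n_points, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read calibration curves from CSV
#'
#' @param path CSV path written by [write_calibration_csv()].
#' @return Named list of `calibration_curve`s.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  curves <- lapply(seq_len(nrow(df)), function(i)
    structure(as.list(df[i, ]), class = "calibration_curve"))
  stats::setNames(curves, df$probe)
}
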