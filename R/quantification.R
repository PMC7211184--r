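# Post intensities -> net signals -> attomole amounts: negative-control
# subtraction, calibration-curve fitting, limit of detection, and the
# normalization / fold-change utilities used when comparing against RT-PCR.

#' Net signal per well and target probe
#'
#' Subtracts the same-well negative-control post mean from every target post
#' mean: `net = target - control`. Wells whose control post is flagged (for
#' example out of frame) yield an undefined net. A lost target post reads
#' near the empty-well floor while the control post carries real signal, so
#' its net is strongly negative -- the basis of the `< -1000 AFU`
#' missing-post rule applied later by [flag_missing_posts()].
#'
#' @param table Post measurement table from [extract_post_means()].
#' @param control_probe Name of the control probe; defaults to the plex
#'   map's designated control when the table came from one.
#' @return A well quantification data frame: `well_row`, `well_col`,
#'   `probe`, `target_afu`, `control_afu`, `net_afu`, `amount_amol` (NA
#'   until calibrated), `flags`.
#' @export
net_signal <- function(table, control_probe) {
  if (!control_probe %in% table$probe)
    stop_invalid("control probe '%s' not present in the table", control_probe)
  ctrl <- table[table$probe == control_probe, ]
  tgt <- table[table$role == "target", ]
  key <- function(d) paste(d$well_row, d$well_col)
  m <- match(key(tgt), key(ctrl))
  ctrl_afu <- ctrl$mean_afu[m]
  ctrl_bad <- is.na(m) | ctrl$flags[m] != "" | is.na(ctrl_afu)
  tgt_bad <- tgt$flags != "" | is.na(tgt$mean_afu)
  net <- ifelse(ctrl_bad | tgt_bad, NA_real_, tgt$mean_afu - ctrl_afu)
  data.frame(well_row = tgt$well_row, well_col = tgt$well_col,
             probe = tgt$probe, target_afu = tgt$mean_afu,
             control_afu = ctrl_afu, net_afu = net,
             amount_amol = NA_real_,
             flags = ifelse(ctrl_bad, "no_control",
                            ifelse(tgt_bad, tgt$flags, "")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit a calibration curve
#'
#' Ordinary least squares of net signal on spiked amount:
#' `net = slope * amount + intercept`. The blank SD (the SD of nets at
#' amount 0) feeds the limit of detection.
#'
#' @param amounts Spiked per-well amounts, amol; at least 3 distinct values
#'   including 0 (blanks).
#' @param nets Matched net signals, AFU.
#' @param probe Optional probe name carried in the result.
#' @return An object of class `calibration_curve`: `probe`, `slope`
#'   (AFU/amol), `intercept` (AFU), `residual_sd`, `blank_sd` (AFU),
#'   `lod_amol`, `n_points`.
#' @export
fit_calibration <- function(amounts, nets, probe = NA_character_) {
  ok <- is.finite(amounts) & is.finite(nets)
  amounts <- amounts[ok]; nets <- nets[ok]
  if (length(unique(amounts)) < 3L)
    stop_invalid("need >= 3 distinct amounts (including 0) to calibrate")
  if (!any(amounts == 0))
    stop_invalid("calibration requires blanks (amount 0)")
  fit <- stats::lm(nets ~ amounts)
  co <- stats::coef(fit)
  blanks <- nets[amounts == 0]
  blank_sd <- if (length(blanks) >= 2L) stats::sd(blanks) else NA_real_
  curve <- structure(list(
    probe = probe,
    slope = unname(co[2]), intercept = unname(co[1]),
    residual_sd = stats::sigma(fit),
    blank_sd = blank_sd,
    lod_amol = NA_real_,
    n_points = length(nets)
  ), class = "calibration_curve")
  if (is.finite(curve$slope) && curve$slope > 0 && is.finite(blank_sd))
    curve$lod_amol <- if (blank_sd == 0) 0 else estimate_lod(curve)
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "calibration_curve [%s]: slope %.4g AFU/amol, intercept %.4g AFU\n",
    x$probe %||% "?", x$slope, x$intercept))
  cat(sprintf("  blank_sd %.4g, residual_sd %.4g, LOD %.4g amol (n = %d)\n",
              x$blank_sd, x$residual_sd, x$lod_amol, x$n_points))
  invisible(x)
}

#' Limit of detection
#'
#' `LOD = 3 * blank_sd / slope`, the conventional three-sigma analytical
#' limit: the amount whose expected net signal exceeds the blank by three
#' blank standard deviations.
#'
#' @param curve A [fit_calibration()] result (slope > 0, blank SD known).
#' @return LOD in amol.
#' @export
estimate_lod <- function(curve) {
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop_invalid("LOD undefined: calibration slope must be > 0")
  if (!is.finite(curve$blank_sd))
    stop_invalid("LOD undefined: blank SD unavailable")
  if (curve$blank_sd == 0)
    warning("blank SD is zero; LOD is degenerate (0 amol)")
  3 * curve$blank_sd / curve$slope
}

#' Convert net signal to amount
#'
#' Inverts the calibration line: `amount = (net - intercept) / slope`.
#' Values below zero are preserved (not clipped) so downstream region
#' statistics stay unbiased; they are flagged `below_zero`.
#'
#' @param net Net signal(s), AFU.
#' @param curve A usable [fit_calibration()] result.
#' @return A data frame with `amount_amol` and `flags`.
#' @export
afu_to_amol <- function(net, curve) {
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop_invalid("calibration curve is not usable (slope <= 0)")
  amount <- (net - curve$intercept) / curve$slope
  data.frame(amount_amol = amount,
             flags = ifelse(is.finite(amount) & amount < 0,
                            "below_zero", ""),
             stringsAsFactors = FALSE)
}

#' Apply calibration curves to a well quantification
#'
#' Fills `amount_amol` for every probe with a usable curve.
#'
#' @param wq Well quantification from [net_signal()].
#' @param curves Named list of `calibration_curve`s (names = probes).
#' @return `wq` with `amount_amol` filled where a curve exists.
#' @export
apply_calibration <- function(wq, curves) {
  for (p in unique(wq$probe)) {
    cu <- curves[[p]]
    if (is.null(cu)) next
    sel <- wq$probe == p & is.finite(wq$net_afu)
    conv <- afu_to_amol(wq$net_afu[sel], cu)
    wq$amount_amol[sel] <- conv$amount_amol
    add <- conv$flags != ""
    wq$flags[sel][add] <- trimws(paste(wq$flags[sel][add], conv$flags[add]))
  }
  wq
}

#' Normalize region signals to a reference region
#'
#' Cell-count-normalized fold change relative to a reference region
#' (typically NAT, the normal tissue adjacent to tumor):
#' `fold(r) = (value_r / cells_r) / (value_ref / cells_ref)`.
#'
#' @param region_values Named numeric vector of region mean signals.
#' @param cell_counts Named numeric vector of approximate cell counts per
#'   region (> 0), same names.
#' @param reference Reference region label.
#' @return Named numeric vector of fold changes (reference = 1).
#' @export
normalize_to_reference <- function(region_values, cell_counts, reference) {
  if (!reference %in% names(region_values))
    stop_invalid("reference region '%s' missing from values", reference)
  if (!all(names(region_values) %in% names(cell_counts)))
    stop_invalid("cell_counts must cover every region")
  counts <- cell_counts[names(region_values)]
  if (any(counts <= 0)) stop_invalid("cell counts must be > 0")
  per_cell <- region_values / counts
  if (per_cell[reference] == 0)
    stop_invalid("reference region has zero signal")
  per_cell / per_cell[reference]
}

#' RT-PCR delta-delta-Ct fold change
#'
#' Relative quantification from qPCR cycle thresholds:
#' `fold(r) = 2^-((Ct_target,r - Ct_endo,r) - (Ct_target,ref - Ct_endo,ref))`,
#' i.e. normalization to an endogenous control followed by normalization to a
#' reference region.
#'
#' @param ct_target Named numeric vector of target-miRNA Ct per region.
#' @param ct_endogenous Named numeric vector of endogenous-control Ct per
#'   region (e.g. miR-26b), same regions.
#' @param reference Reference region label.
#' @return Named numeric vector of fold changes (reference = 1).
#' @export
ddct_fold_change <- function(ct_target, ct_endogenous, reference) {
  regions <- names(ct_target)
  if (!reference %in% regions)
    stop_invalid("reference region '%s' missing", reference)
  if (!all(regions %in% names(ct_endogenous)))
    stop_invalid("ct_endogenous must cover every region in ct_target")
  if (!all(is.finite(ct_target)) ||
      !all(is.finite(ct_endogenous[regions])))
    stop_invalid("all Ct values must be finite")
  dct <- ct_target - ct_endogenous[regions]
  2^-(dct - dct[reference])
}
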