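# Pixelate well quantifications onto the well lattice: heatmaps, region
# assignment from annotation polygons, region summaries, and reproducibility
# (cross-section CV) statistics.

#' Region mask
#'
#' A set of labeled annotation polygons in array (um) coordinates, typically
#' traced from an H&E-stained proximal section: tumor regions plus NAT
#' (normal adjacent to tumor).
#'
#' @param regions List of regions, each a list with `label` (unique
#'   character) and `polygon` (N x 2 matrix of um coordinates, N >= 3).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(regions) {
  labels <- vapply(regions, function(r) r$label %||% NA_character_,
                   character(1))
  if (anyNA(labels) || anyDuplicated(labels))
    stop_invalid("every region needs a unique label")
  for (r in regions) {
    poly <- r$polygon
    if (is.null(poly) || !is.numeric(as.matrix(poly)) ||
        ncol(as.matrix(poly)) != 2L || nrow(as.matrix(poly)) < 3L)
      stop_invalid("region '%s': polygon must be an N x 2 matrix, N >= 3",
                   r$label)
  }
  structure(list(regions = lapply(regions, function(r)
    list(label = r$label, polygon = as.matrix(r$polygon)))),
    class = "region_mask")
}

#' Build a per-probe heatmap on the well lattice
#'
#' Re-indexes a well quantification as an `n_well_rows x n_well_cols` matrix
#' for one probe; each cell is the measurement for one well (amount if
#' calibrated, net AFU otherwise). Wells filtered by QC, or absent from the
#' table, are `NA`.
#'
#' @param wq Well quantification (after QC filtering, typically).
#' @param probe Probe to map.
#' @param layout An [array_layout()].
#' @param what `"amount_amol"` or `"net_afu"`.
#' @return A matrix of class `heatmap_grid` with attributes `probe` and
#'   `what`.
#' @export
build_heatmap <- function(wq, probe, layout = array_layout(),
                          what = c("amount_amol", "net_afu")) {
  what <- match.arg(what)
  if (!probe %in% wq$probe)
    stop_invalid("probe '%s' not present in the quantification", probe)
  sub <- wq[wq$probe == probe, ]
  m <- matrix(NA_real_, layout$n_well_rows, layout$n_well_cols)
  ok <- sub$well_row >= 0 & sub$well_row < layout$n_well_rows &
    sub$well_col >= 0 & sub$well_col < layout$n_well_cols
  m[cbind(sub$well_row[ok] + 1L, sub$well_col[ok] + 1L)] <- sub[[what]][ok]
  structure(m, probe = probe, what = what,
            class = c("heatmap_grid", "matrix", "array"))
}

#' Assign wells to annotation regions
#'
#' A well belongs to the region whose polygon contains its center point.
#' When polygons overlap, the first-listed region wins (with a warning);
#' wells inside no polygon are unassigned (`NA`).
#'
#' @param layout An [array_layout()].
#' @param mask A [region_mask()].
#' @return A data frame: `well_row`, `well_col`, `region` (character or NA).
#' @export
assign_wells_to_regions <- function(layout, mask) {
  wells <- expand.grid(well_col = seq_len(layout$n_well_cols) - 1L,
                       well_row = seq_len(layout$n_well_rows) - 1L)
  ctr <- well_center_um(layout, wells$well_row, wells$well_col)
  region <- rep(NA_character_, nrow(wells))
  overlap <- FALSE
  for (rg in mask$regions) {
    inside <- mgcv::in.out(rg$polygon, cbind(ctr[, "x"], ctr[, "y"]))
    clash <- inside & !is.na(region)
    if (any(clash)) overlap <- TRUE
    take <- inside & is.na(region)
    region[take] <- rg$label
  }
  if (overlap)
    warning("overlapping region polygons; ties assigned to the first-listed region")
  data.frame(well_row = wells$well_row, well_col = wells$well_col,
             region = region, stringsAsFactors = FALSE)
}

#' Per-region summary statistics
#'
#' For each probe and region: number of contributing wells, mean, and sample
#' SD of the chosen quantity. `n` counts only unfiltered wells with a
#' defined value under the region.
#'
#' @param wq Well quantification (after QC filtering).
#' @param assignment Output of [assign_wells_to_regions()].
#' @param what `"amount_amol"` or `"net_afu"`.
#' @return A data frame: `probe`, `region`, `n`, `mean`, `sd`; plus an
#'   attribute `values`, a list of the per-well values behind each row.
#' @export
region_summary <- function(wq, assignment,
                           what = c("amount_amol", "net_afu")) {
  what <- match.arg(what)
  key <- function(d) paste(d$well_row, d$well_col)
  wq$region <- assignment$region[match(key(wq), key(assignment))]
  sub <- wq[!is.na(wq$region) & is.finite(wq[[what]]), ]
  if (!nrow(sub)) {
    warning("no assigned wells with defined values; empty summary")
    return(data.frame(probe = character(), region = character(),
                      n = integer(), mean = numeric(), sd = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- interaction(sub$probe, sub$region, sep = "\r", drop = TRUE)
  grp <- split(sub[[what]], f)
  keyparts <- strsplit(names(grp), "\r", fixed = TRUE)
  out <- data.frame(
    probe = vapply(keyparts, `[`, character(1), 1),
    region = vapply(keyparts, `[`, character(1), 2),
    n = lengths(grp),
    mean = vapply(grp, mean, numeric(1)),
    sd = vapply(grp, stats::sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$probe, out$region), ]
  rownames(out) <- NULL
  attr(out, "values") <- grp
  out
}

#' Cross-section coefficient of variation
#'
#' Reproducibility across serial sections: the CV (percent) of each
#' (region, probe) mean across sections, plus the unweighted grand average
#' of those CVs.
#'
#' @param summaries A data frame with columns `section`, `region`, `probe`,
#'   `mean` (one row per section x region x probe), from stacking
#'   [region_summary()] outputs.
#' @return A list with `per_cell` (data frame `region`, `probe`,
#'   `cv_percent`, `n_sections`) and `grand_mean_cv_percent`.
#' @export
cross_section_cv <- function(summaries) {
  req <- c("section", "region", "probe", "mean")
  if (!is.data.frame(summaries) || !all(req %in% names(summaries)))
    stop_invalid("'summaries' needs columns %s", paste(req, collapse = ", "))
  if (length(unique(summaries$section)) < 2L)
    stop_invalid("need >= 2 sections")
  cells <- unique(summaries[, c("region", "probe")])
  n_sections <- length(unique(summaries$section))
  per_section_n <- table(summaries$region, summaries$probe)
  if (any(per_section_n[per_section_n > 0] != n_sections))
    stop_invalid("every (region, probe) cell must appear in every section")
  cv <- mapply(function(r, p) {
    v <- summaries$mean[summaries$region == r & summaries$probe == p]
    if (mean(v) == 0) NA_real_ else coefficient_of_variation(v)
  }, cells$region, cells$probe)
  per_cell <- data.frame(region = cells$region, probe = cells$probe,
                         cv_percent = as.numeric(cv),
                         n_sections = n_sections,
                         stringsAsFactors = FALSE, row.names = NULL)
  if (anyNA(per_cell$cv_percent))
    warning("CV undefined (zero mean) for some (region, probe) cells")
  list(per_cell = per_cell,
       grand_mean_cv_percent = mean(per_cell$cv_percent, na.rm = TRUE))
}

#' Plot a heatmap grid
#'
#' Renders a [build_heatmap()] matrix with ggplot2 (viridis colormap), one
#' tile per well, NA wells blank.
#'
#' @param grid A `heatmap_grid`.
#' @return A ggplot object.
#' @export
plot_heatmap <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_invalid("ggplot2 is required for plotting")
  df <- expand.grid(well_col = seq_len(ncol(grid)) - 1L,
                    well_row = seq_len(nrow(grid)) - 1L)
  df$value <- as.vector(t(unclass(grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$well_col, y = .data$well_row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(grid, "probe"),
                  fill = if (identical(attr(grid, "what"), "amount_amol"))
                    "amol/well" else "net AFU",
                  x = "well column", y = "well row") +
    ggplot2::theme_minimal()
}
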