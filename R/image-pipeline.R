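# Raw image -> per-post mean-intensity table: dust removal, two-anchor grid
# registration, post extraction and central window selection.
#
# Pixel conventions: 0-based coordinates, x = column, y = row, origin at the
# image's top-left; post boxes are half-open [x0, x0 + w) x [y0, y0 + h).

#' Registration anchor
#'
#' A registration anchor marks the pixel at the upper-left corner of the
#' upper-left post of a chosen well. Two anchors in different wells define
#' the well lattice in pixel space.
#'
#' @param well Integer (row, col) of the well, 0-based.
#' @param pixel Integer (x, y) of the upper-left corner pixel, 0-based.
#' @return An object of class `anchor`.
#' @export
anchor <- function(well, pixel) {
  if (length(well) != 2L || length(pixel) != 2L)
    stop_invalid("'well' and 'pixel' must each have length 2")
  if (any(well < 0) || any(pixel < 0))
    stop_invalid("anchor indices and pixels must be >= 0")
  structure(list(well = as.integer(well), pixel = as.integer(pixel)),
            class = "anchor")
}

# 8-connected component labeling of a logical mask by breadth-first search.
# Returns an integer matrix of labels (0 = background). Written here because
# the dust rule is defined on 8-connectivity.
label_components_8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  idx <- which(mask)
  if (!length(idx)) return(labels)
  lab <- 0L
  # neighbor offsets in linear (column-major) index space, guarded at borders
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- integer(256L); queue[1L] <- start; qh <- 1L; qt <- 1L
    labels[start] <- lab
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      y <- ((p - 1L) %% ny) + 1L
      x <- ((p - 1L) %/% ny) + 1L
      for (dx in -1L:1L) {
        xx <- x + dx
        if (xx < 1L || xx > nx) next
        base <- (xx - 1L) * ny
        for (dy in -1L:1L) {
          yy <- y + dy
          if (yy < 1L || yy > ny || (dx == 0L && dy == 0L)) next
          q <- base + yy
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- lab
            qt <- qt + 1L
            if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[qt] <- q
          }
        }
      }
    }
  }
  labels
}

#' Remove bright dust artifacts
#'
#' Finds 8-connected components of pixels brighter than
#' `intensity_threshold_afu` whose pixel count exceeds the post footprint
#' (post side in pixels, squared) and replaces them with the background
#' level, defined as the median of all pixels at or below the threshold.
#' Posts themselves are never removed: a post's footprint does not exceed
#' the cutoff.
#'
#' @param image Numeric matrix, AFU.
#' @param intensity_threshold_afu Dust threshold, AFU (> 0). Choose it above
#'   the brightest plausible post signal.
#' @param layout An [array_layout()] (supplies the post footprint in pixels).
#' @return A list with `image` (cleaned), `removed_components` (list of
#'   integer vectors of linear pixel indices) and `background_afu` (the
#'   replacement level).
#' @export
remove_dust <- function(image, intensity_threshold_afu,
                        layout = array_layout()) {
  assert_scalar_num(intensity_threshold_afu, "intensity_threshold_afu",
                    positive = TRUE)
  below <- image <= intensity_threshold_afu
  if (!any(below))
    stop_invalid("every pixel exceeds the dust threshold; no background definable")
  footprint_px <- post_side_px(layout)^2
  labels <- label_components_8(image > intensity_threshold_afu)
  removed <- list()
  bg <- NA_real_
  if (max(labels) > 0L) {
    sizes <- tabulate(labels)
    big <- which(sizes > footprint_px)
    if (length(big)) {
      bg <- stats::median(image[below])
      for (lb in big) {
        px <- which(labels == lb)
        removed[[length(removed) + 1L]] <- px
        image[px] <- bg
      }
    }
  }
  list(image = image, removed_components = removed, background_afu = bg)
}

#' Register the post grid from two anchors
#'
#' Builds the pixel box of every post on the array from two anchor wells.
#' The model is axis-aligned: the well pitch in pixels along an axis is the
#' anchor displacement divided by the well-index offset when that offset is
#' nonzero, and the nominal pitch (`well_pitch_um / pixel_size_um`)
#' otherwise. Post boxes are placed at
#' `anchor + well offset * well pitch + post offset * post pitch`, with the
#' post pitch taken from the layout. No rotation is modeled; visibly rotated
#' scans must be rectified upstream.
#'
#' @param anchor_a,anchor_b Two [anchor()]s with distinct well indices.
#' @param layout An [array_layout()].
#' @param image_dim Optional image dimensions `c(ny, nx)`; when supplied,
#'   boxes falling outside the image are flagged out-of-frame.
#' @return A data frame of class `post_grid`: `well_row`, `well_col`,
#'   `post_row`, `post_col`, box `x0`, `y0`, `w`, `h` (pixels, 0-based,
#'   half-open) and `out_of_frame`.
#' @export
register_grid <- function(anchor_a, anchor_b, layout = array_layout(),
                          image_dim = NULL) {
  if (!inherits(anchor_a, "anchor") || !inherits(anchor_b, "anchor"))
    stop_invalid("anchors must be created with anchor()")
  dwell <- anchor_b$well - anchor_a$well
  if (all(dwell == 0L))
    stop_invalid("anchors must lie in different wells")
  dpix <- anchor_b$pixel - anchor_a$pixel
  nominal <- layout$well_pitch_um / layout$pixel_size_um
  # x follows columns, y follows rows
  pitch_x <- if (dwell[2] != 0L) dpix[1] / dwell[2] else nominal
  pitch_y <- if (dwell[1] != 0L) dpix[2] / dwell[1] else nominal
  if (pitch_x <= 0 || pitch_y <= 0)
    stop_invalid("anchors imply a non-positive well pitch")
  if (abs(pitch_x - nominal) / nominal > 0.1 ||
      abs(pitch_y - nominal) / nominal > 0.1)
    warning("inferred well pitch deviates >10% from nominal; check anchors")

  post_pitch_px <- layout$post_pitch_um / layout$pixel_size_um
  side <- post_side_px(layout)
  wells <- expand.grid(well_col = seq_len(layout$n_well_cols) - 1L,
                       well_row = seq_len(layout$n_well_rows) - 1L)
  posts <- expand.grid(post_col = seq_len(layout$post_grid_cols) - 1L,
                       post_row = seq_len(layout$post_grid_rows) - 1L)
  grid <- merge(wells, posts)
  x0 <- round(anchor_a$pixel[1] +
                (grid$well_col - anchor_a$well[2]) * pitch_x +
                grid$post_col * post_pitch_px)
  y0 <- round(anchor_a$pixel[2] +
                (grid$well_row - anchor_a$well[1]) * pitch_y +
                grid$post_row * post_pitch_px)
  out <- data.frame(well_row = grid$well_row, well_col = grid$well_col,
                    post_row = grid$post_row, post_col = grid$post_col,
                    x0 = as.integer(x0), y0 = as.integer(y0),
                    w = side, h = side)
  out$out_of_frame <- if (is.null(image_dim)) {
    out$x0 < 0L | out$y0 < 0L
  } else {
    out$x0 < 0L | out$y0 < 0L |
      out$x0 + out$w > image_dim[2] | out$y0 + out$h > image_dim[1]
  }
  out <- out[order(out$well_row, out$well_col, out$post_row, out$post_col), ]
  rownames(out) <- NULL
  class(out) <- c("post_grid", "data.frame")
  out
}

#' Extract per-post mean intensities
#'
#' Computes the mean AFU of every in-frame post box and joins the plex map's
#' probe identity and role, producing the post measurement table the rest of
#' the pipeline consumes.
#'
#' @param image Numeric matrix, AFU.
#' @param grid A [register_grid()] result.
#' @param plex A [plex_map()].
#' @return A data frame: `well_row`, `well_col`, `post_row`, `post_col`,
#'   `probe`, `role`, `mean_afu`, `n_pixels`, `flags` (character; `""` or
#'   `"out_of_frame"`).
#' @export
extract_post_means <- function(image, grid, plex) {
  if (!nrow(grid)) stop_invalid("empty post grid")
  pk <- paste(grid$post_row, grid$post_col)
  ek <- paste(plex$entries$post_row, plex$entries$post_col)
  m <- match(pk, ek)
  if (anyNA(m)) stop_invalid("post grid has positions missing from the plex map")
  oob <- grid$out_of_frame |
    grid$x0 + grid$w > ncol(image) | grid$y0 + grid$h > nrow(image) |
    grid$x0 < 0L | grid$y0 < 0L
  mean_afu <- rep(NA_real_, nrow(grid))
  npx <- integer(nrow(grid))
  for (i in which(!oob)) {
    box <- image[(grid$y0[i] + 1L):(grid$y0[i] + grid$h[i]),
                 (grid$x0[i] + 1L):(grid$x0[i] + grid$w[i])]
    mean_afu[i] <- mean(box)
    npx[i] <- length(box)
  }
  data.frame(well_row = grid$well_row, well_col = grid$well_col,
             post_row = grid$post_row, post_col = grid$post_col,
             probe = plex$entries$probe[m], role = plex$entries$role[m],
             mean_afu = mean_afu, n_pixels = npx,
             flags = ifelse(oob, "out_of_frame", ""),
             stringsAsFactors = FALSE)
}

#' Restrict a measurement table to a centered well window
#'
#' Keeps only wells inside a centered `rows x cols` block, the standard way
#' to avoid array edges and cracks. Centering uses the integer floor of each
#' margin. The default 9 x 11 window holds 99 wells.
#'
#' @param table A post measurement table (from [extract_post_means()]).
#' @param rows,cols Window size in wells.
#' @param layout An [array_layout()] giving the full well grid size.
#' @return The table restricted to the window.
#' @export
select_window <- function(table, rows = 9, cols = 11,
                          layout = array_layout()) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop_invalid("window must be at least 1 x 1")
  if (rows > layout$n_well_rows || cols > layout$n_well_cols)
    stop_invalid("window (%d x %d) larger than the well grid (%d x %d)",
                 rows, cols, layout$n_well_rows, layout$n_well_cols)
  r0 <- (layout$n_well_rows - rows) %/% 2L
  c0 <- (layout$n_well_cols - cols) %/% 2L
  keep <- table$well_row >= r0 & table$well_row < r0 + rows &
    table$well_col >= c0 & table$well_col < c0 + cols
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
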