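# Shared fixtures and independent oracles used across the suite.

# A small array that renders quickly: 6 x 6 wells, default 300/50/39 wells,
# 3 x 3 posts of 40 um at 100 um pitch, 5 um pixels (image 430 x 430 px).
small_layout <- function(rows = 6, cols = 6) {
  array_layout(n_well_rows = rows, n_well_cols = cols)
}

# Two-region scenario: left half high miR-21, right half low. Polygons are
# axis-aligned rectangles in array um coordinates.
two_region_scenario <- function(layout = small_layout(), noise = 0,
                                seed = 11, high = 20, low = 5, ...) {
  ext_x <- 2 * layout$well_spacing_um +
    layout$n_well_cols * layout$well_pitch_um - layout$well_spacing_um
  ext_y <- 2 * layout$well_spacing_um +
    layout$n_well_rows * layout$well_pitch_um - layout$well_spacing_um
  half <- ext_x / 2
  regions <- list(
    list(label = "Tumor 1",
         polygon = rbind(c(0, 0), c(half, 0), c(half, ext_y), c(0, ext_y)),
         amounts = c("miR-21" = high, "let-7a" = low)),
    list(label = "NAT",
         polygon = rbind(c(half, 0), c(ext_x, 0), c(ext_x, ext_y),
                         c(half, ext_y)),
         amounts = c("miR-21" = low, "let-7a" = low)))
  synthetic_scenario(layout, plex_map_default(layout), regions,
                     pixel_noise_sd_afu = noise, seed = seed, ...)
}

# Independent 8-connected component labeling oracle: depth-first flood fill
# driven by an explicit stack, structured differently from the package's
# breadth-first implementation.
flood_fill_label_oracle <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (!mask[y, x] || lab[y, x] != 0L) next
    cur <- cur + 1L
    stack <- list(c(y, x))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > ny || p[2] < 1 || p[2] > nx) next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
      lab[p[1], p[2]] <- cur
      for (dy in -1:1) for (dx in -1:1)
        if (dy != 0 || dx != 0)
          stack[[length(stack) + 1L]] <- c(p[1] + dy, p[2] + dx)
    }
  }
  lab
}

# Brute-force dust removal oracle built on the flood-fill labeler.
remove_dust_oracle <- function(image, threshold, footprint_px) {
  lab <- flood_fill_label_oracle(image > threshold)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    big <- which(sizes > footprint_px)
    if (length(big)) {
      bg <- median(image[image <= threshold])
      image[lab %in% big] <- bg
    }
  }
  image
}

# Brute-force post-packing oracle: count grid positions (i, j) such that a
# square grid anchored at offset fits in the well, maximized over n.
posts_per_well_oracle <- function(well, post, pitch) {
  best <- 0L
  for (n in 1:floor(well / post)) {
    extent <- (n - 1) * pitch + post
    if (extent <= well) best <- n
  }
  best^2
}
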