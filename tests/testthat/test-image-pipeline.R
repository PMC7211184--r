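test_that("dust removal erases big bright blobs and keeps small ones", {
  lay <- array_layout()  # 40 um posts at 5 um/px -> 8 x 8 = 64 px footprint
  img <- matrix(100, 80, 80)
  img[10:21, 10:21] <- 60000  # 12 x 12 = 144 px > 64
  out <- remove_dust(img, 30000, lay)
  expect_length(out$removed_components, 1L)
  expect_true(all(out$image[10:21, 10:21] == 100))
  expect_equal(out$background_afu, 100)

  img2 <- matrix(100, 80, 80)
  img2[10:15, 10:15] <- 60000  # 36 px <= 64: preserved
  out2 <- remove_dust(img2, 30000, lay)
  expect_length(out2$removed_components, 0L)
  expect_identical(out2$image, img2)

  # boundary: exactly footprint-sized component is preserved (strict >)
  img3 <- matrix(100, 80, 80)
  img3[1:8, 1:8] <- 60000
  expect_length(remove_dust(img3, 30000, lay)$removed_components, 0L)

  expect_error(remove_dust(matrix(5e4, 4, 4), 30000, lay), "background")
})

test_that("dust removal matches a brute-force flood-fill oracle", {
  lay <- array_layout()
  footprint <- 64
  set.seed(42)
  for (i in 1:8) {
    img <- matrix(runif(100 * 100, 0, 1000), 100, 100)
    for (b in 1:4) {
      side <- sample(3:15, 1)
      x <- sample(1:(100 - side), 1); y <- sample(1:(100 - side), 1)
      img[y:(y + side - 1), x:(x + side - 1)] <- runif(1, 40000, 60000)
    }
    out <- remove_dust(img, 30000, lay)
    expect_identical(out$image, remove_dust_oracle(img, 30000, footprint))
  }
})

test_that("dust removal is idempotent and leaves other pixels untouched", {
  lay <- array_layout()
  set.seed(7)
  img <- matrix(runif(150 * 150, 0, 2000), 150, 150)
  img[20:40, 20:40] <- 55000
  out1 <- remove_dust(img, 30000, lay)
  out2 <- remove_dust(out1$image, 30000, lay)
  expect_identical(out2$image, out1$image)
  expect_length(out2$removed_components, 0L)
  removed <- unlist(out1$removed_components)
  expect_identical(out1$image[-removed], img[-removed])
})

test_that("two-anchor registration infers pitch and places boxes", {
  lay <- array_layout(n_well_rows = 2, n_well_cols = 11)
  a <- anchor(c(0, 0), c(100, 100))
  b <- anchor(c(0, 10), c(800, 100))
  grid <- suppressWarnings(register_grid(a, b, lay))
  # x pitch = 700 px / 10 wells = 70 px; y falls back to nominal 350/5 = 70
  first <- grid[grid$well_row == 0 & grid$well_col == 0 &
                  grid$post_row == 0 & grid$post_col == 0, ]
  expect_equal(first$x0, 100L)
  expect_equal(first$y0, 100L)
  nxt <- grid[grid$well_row == 1 & grid$well_col == 1 &
                grid$post_row == 0 & grid$post_col == 0, ]
  expect_equal(nxt$x0, 170L)
  expect_equal(nxt$y0, 170L)
  # post pitch within a well: 100 um / 5 = 20 px
  p11 <- grid[grid$well_row == 0 & grid$well_col == 0 &
                grid$post_row == 1 & grid$post_col == 1, ]
  expect_equal(p11$x0, 120L)

  expect_error(register_grid(a, anchor(c(1, 0), c(100, 100 - 70)), lay),
               "non-positive")
  expect_error(register_grid(a, a, lay), "different wells")
})

test_that("registration on a synthetic render matches generator geometry", {
  lay <- small_layout(4, 4)
  sc <- two_region_scenario(lay, noise = 0, seed = 2)
  ren <- render_array_image(sc)
  anchors <- scenario_anchors(lay)
  grid <- register_grid(anchors[[1]], anchors[[2]], lay,
                        image_dim = dim(ren$image))
  expect_false(any(grid$out_of_frame))
  tab <- extract_post_means(ren$image, grid, sc$plex)
  key <- function(d) paste(d$well_row, d$well_col, d$post_row, d$post_col)
  m <- match(key(tab), key(ren$truth))
  expect_false(anyNA(m))
  expect_equal(tab$mean_afu, ren$truth$mean_afu[m])
  expect_identical(tab$probe, ren$truth$probe[m])
})

test_that("post mean extraction equals direct pixel averaging", {
  lay <- small_layout(2, 2)
  img <- matrix(0, 300, 300)
  grid <- register_grid(anchor(c(0, 0), c(16, 16)),
                        anchor(c(1, 1), c(86, 86)), lay,
                        image_dim = dim(img))
  img[, ] <- 500
  tab <- extract_post_means(img, grid, plex_map_default(lay))
  expect_true(all(tab$mean_afu == 500))
  expect_true(all(tab$n_pixels == 64))
  expect_equal(nrow(tab), 2 * 2 * 9)
  expect_false(anyDuplicated(paste(tab$well_row, tab$well_col,
                                   tab$post_row, tab$post_col)) > 0)

  # half 0 / half 1000 box
  img2 <- matrix(0, 300, 300)
  img2[17:20, 17:24] <- 1000   # top half of the first 8 x 8 box
  tab2 <- extract_post_means(img2, grid, plex_map_default(lay))
  expect_equal(tab2$mean_afu[tab2$well_row == 0 & tab2$well_col == 0 &
                               tab2$post_row == 0 & tab2$post_col == 0], 500)

  # arbitrary content vs direct summation
  set.seed(3)
  img3 <- matrix(runif(300 * 300, 0, 65535), 300, 300)
  tab3 <- extract_post_means(img3, grid, plex_map_default(lay))
  i <- 5
  box <- img3[(grid$y0[i] + 1):(grid$y0[i] + 8),
              (grid$x0[i] + 1):(grid$x0[i] + 8)]
  row <- tab3[tab3$well_row == grid$well_row[i] &
                tab3$well_col == grid$well_col[i] &
                tab3$post_row == grid$post_row[i] &
                tab3$post_col == grid$post_col[i], ]
  expect_equal(row$mean_afu, sum(box) / 64)

  expect_error(extract_post_means(img, grid[0, ], plex_map_default(lay)),
               "empty")
})

test_that("out-of-frame boxes are flagged, not averaged", {
  lay <- small_layout(2, 2)
  img <- matrix(1, 100, 100)  # too small for the full grid
  grid <- register_grid(anchor(c(0, 0), c(16, 16)),
                        anchor(c(1, 1), c(86, 86)), lay,
                        image_dim = dim(img))
  expect_true(any(grid$out_of_frame))
  tab <- extract_post_means(img, grid, plex_map_default(lay))
  oob <- tab$flags == "out_of_frame"
  expect_true(any(oob))
  expect_true(all(is.na(tab$mean_afu[oob])))
  expect_true(all(!is.na(tab$mean_afu[!oob])))
})

test_that("window selection keeps the centered block of wells", {
  lay <- array_layout()  # 28 x 28
  tab <- expand.grid(well_row = 0:27, well_col = 0:27)
  tab$probe <- "miR-21"; tab$mean_afu <- 1
  win <- select_window(tab, 9, 11, lay)
  expect_equal(length(unique(paste(win$well_row, win$well_col))), 99L)
  expect_equal(range(win$well_row), c(9, 17))   # floor((28 - 9)/2) = 9
  expect_equal(range(win$well_col), c(8, 18))   # floor((28 - 11)/2) = 8

  full <- select_window(tab, 28, 28, lay)
  expect_equal(nrow(full), nrow(tab))

  lay8 <- array_layout(n_well_rows = 8, n_well_cols = 28)
  expect_error(select_window(tab, 9, 11, lay8), "larger than")
})
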