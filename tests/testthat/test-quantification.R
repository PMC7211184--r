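make_table <- function(targets, control, control_probe = "cel-miR-54") {
  # one well, one control post plus named target posts
  n <- length(targets)
  data.frame(well_row = 0L, well_col = 0L,
             post_row = c(seq_len(n) - 1L, n), post_col = 0L,
             probe = c(names(targets), control_probe),
             role = c(rep("target", n), "negative_control"),
             mean_afu = c(unname(targets), control),
             n_pixels = 64L, flags = "", stringsAsFactors = FALSE)
}

test_that("net signal subtracts the same-well control post", {
  tab <- make_table(c("miR-21" = 2000), 500)
  wq <- net_signal(tab, "cel-miR-54")
  expect_equal(wq$net_afu, 1500)

  expect_equal(net_signal(make_table(c("miR-21" = 500), 500),
                          "cel-miR-54")$net_afu, 0)

  # lost target post reads near the well floor while the control keeps
  # signal: strongly negative net, the missing-post signature
  wq3 <- net_signal(make_table(c("miR-21" = 0), 1500), "cel-miR-54")
  expect_equal(wq3$net_afu, -1500)
  expect_equal(flag_missing_posts(wq3)$n_removed, 1L)

  expect_error(net_signal(tab, "nope"), "not present")
})

test_that("net signal is antisymmetric and shift-invariant within a well", {
  tab <- make_table(c("miR-21" = 1800, "let-7a" = 700), 600)
  wq <- net_signal(tab, "cel-miR-54")
  shifted <- tab
  shifted$mean_afu <- shifted$mean_afu + 1234
  expect_equal(net_signal(shifted, "cel-miR-54")$net_afu, wq$net_afu)
  # swapping target and control values negates the net
  swapped <- make_table(c("miR-21" = 600), 1800)
  expect_equal(net_signal(swapped, "cel-miR-54")$net_afu,
               -(1800 - 600))
})

test_that("wells with a flagged control yield undefined nets", {
  tab <- make_table(c("miR-21" = 2000), 500)
  tab$flags[tab$probe == "cel-miR-54"] <- "out_of_frame"
  wq <- net_signal(tab, "cel-miR-54")
  expect_true(is.na(wq$net_afu))
  expect_equal(wq$flags, "no_control")
})

test_that("calibration fitting recovers exact and shifted lines", {
  amounts <- c(0, 0, 0.5, 1, 2)
  fit <- fit_calibration(amounts, 1000 * amounts)
  expect_equal(fit$slope, 1000)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-9)
  expect_equal(fit$blank_sd, 0)

  fit2 <- fit_calibration(amounts, 1000 * amounts + 200)
  expect_equal(fit2$slope, 1000)
  expect_equal(fit2$intercept, 200)

  expect_error(fit_calibration(c(0, 0, 1), c(1, 2, 3) * NA), "distinct")
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(c(1, 2, 3), c(1, 2, 3)), "blank")
})

test_that("noisy calibration recovers the generator gain", {
  set.seed(10)
  amounts <- rep(c(0, 0.01, 0.03, 0.1, 0.3, 1), each = 30)
  gain <- 1000
  nets <- gain * amounts + rnorm(length(amounts), 0, 9)
  fit <- fit_calibration(amounts, nets)
  se <- fit$residual_sd / sqrt(sum((amounts - mean(amounts))^2))
  expect_lt(abs(fit$slope - gain), 3 * se)
})

test_that("LOD follows the three-sigma convention and its scalings", {
  cu <- structure(list(slope = 1000, blank_sd = 10),
                  class = "calibration_curve")
  expect_equal(estimate_lod(cu), 0.03)
  cu2 <- cu; cu2$slope <- 2000
  expect_equal(estimate_lod(cu2), estimate_lod(cu) / 2)
  cu3 <- cu; cu3$blank_sd <- 20
  expect_equal(estimate_lod(cu3), 2 * estimate_lod(cu))
  cu0 <- cu; cu0$blank_sd <- 0
  expect_warning(z <- estimate_lod(cu0), "degenerate")
  expect_equal(z, 0)
  bad <- cu; bad$slope <- -1
  expect_error(estimate_lod(bad), "slope")
})

test_that("Monte-Carlo LOD agrees with the analytic closed form", {
  # post means over 64 px with pixel noise sd: net sd = sd * sqrt(2/64)
  noise <- 50; n_px <- 64; gain <- 1000
  analytic <- 3 * noise * sqrt(2 / n_px) / gain
  set.seed(77)
  reps <- 200
  amounts <- rep(c(0, 0.01, 0.03, 0.1, 0.3, 1), each = reps)
  nets <- gain * amounts + rnorm(length(amounts), 0, noise * sqrt(2 / n_px))
  fit <- fit_calibration(amounts, nets)
  expect_lt(abs(fit$lod_amol - analytic) / analytic, 0.25)
})

test_that("AFU-to-amount inverts the calibration line exactly", {
  cu <- fit_calibration(c(0, 0, 1, 2), c(50, 50, 1050, 2050))
  expect_equal(afu_to_amol(cu$intercept, cu)$amount_amol, 0)
  expect_equal(afu_to_amol(cu$intercept + cu$slope, cu)$amount_amol, 1)
  x <- c(-0.4, 0, 0.3, 2.2)
  back <- afu_to_amol(cu$slope * x + cu$intercept, cu)
  expect_equal(back$amount_amol, x)
  expect_equal(back$flags, c("below_zero", "", "", ""))
})

test_that("cell-count normalization gives reference-relative folds", {
  folds <- normalize_to_reference(c(NAT = 10, T1 = 40),
                                  c(NAT = 100, T1 = 200), "NAT")
  expect_equal(unname(folds["NAT"]), 1.0)
  expect_equal(unname(folds["T1"]), 2.0)
  # scale invariance: doubling both value and cells changes nothing
  folds2 <- normalize_to_reference(c(NAT = 10, T1 = 80),
                                   c(NAT = 100, T1 = 400), "NAT")
  expect_equal(folds2, folds)
  expect_error(normalize_to_reference(c(A = 1), c(A = 1), "B"), "missing")
  expect_error(normalize_to_reference(c(A = 0, B = 1), c(A = 1, B = 1), "A"),
               "zero")
})

test_that("delta-delta-Ct fold changes follow the textbook definition", {
  ct_t <- c(NAT = 25, T1 = 24, T2 = 28.3219)
  ct_e <- c(NAT = 20, T1 = 20, T2 = 20)
  folds <- ddct_fold_change(ct_t, ct_e, "NAT")
  expect_equal(unname(folds["NAT"]), 1.0)
  expect_equal(unname(folds["T1"]), 2.0)          # ddCt = -1
  expect_equal(unname(folds["T2"]), 0.1, tolerance = 1e-4)  # ddCt = log2(10)
  expect_error(ddct_fold_change(c(A = NA_real_), c(A = 1), "A"), "finite")
  expect_error(ddct_fold_change(ct_t, ct_e, "XX"), "missing")
})
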