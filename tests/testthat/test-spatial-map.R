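test_that("heatmaps re-index well values losslessly", {
  lay <- small_layout(2, 2)
  wq <- data.frame(well_row = c(0, 0, 1, 1), well_col = c(0, 1, 0, 1),
                   probe = "miR-21", net_afu = c(1, 2, 3, 4),
                   amount_amol = c(1, 2, 3, 4), flags = "",
                   stringsAsFactors = FALSE)
  hm <- build_heatmap(wq, "miR-21", lay)
  expect_equal(unclass(hm)[1:2, 1:2], rbind(c(1, 2), c(3, 4)),
               ignore_attr = TRUE)
  # flatten back: every well value recoverable
  expect_equal(hm[cbind(wq$well_row + 1, wq$well_col + 1)], wq$amount_amol)

  # a filtered (absent) well is NA, others intact
  hm2 <- build_heatmap(wq[-2, ], "miR-21", lay)
  expect_true(is.na(hm2[1, 2]))
  expect_equal(hm2[cbind(c(1, 2, 2), c(1, 1, 2))], c(1, 3, 4))

  expect_error(build_heatmap(wq, "nope", lay), "not present")
})

test_that("wells are assigned to the region containing their center", {
  lay <- small_layout(5, 5)
  big <- rbind(c(-1e4, -1e4), c(1e5, -1e4), c(1e5, 1e5), c(-1e4, 1e5))
  all_in <- assign_wells_to_regions(lay, region_mask(list(
    list(label = "everything", polygon = big))))
  expect_true(all(all_in$region == "everything"))

  none <- assign_wells_to_regions(lay, region_mask(list(
    list(label = "far", polygon = big + 1e6))))
  expect_true(all(is.na(none$region)))

  # rectangle covering exactly wells (0..2, 0..2): well pitch 350 um,
  # margin 50 um, centers at 200 + 350 k um
  rect <- rbind(c(0, 0), c(1150, 0), c(1150, 1150), c(0, 1150))
  asg <- assign_wells_to_regions(lay, region_mask(list(
    list(label = "corner", polygon = rect))))
  hit <- asg[!is.na(asg$region), ]
  expect_equal(nrow(hit), 9L)
  expect_true(all(hit$well_row <= 2 & hit$well_col <= 2))

  # oracle: point-in-polygon on each well center
  centers_in <- with(asg, 200 + 350 * well_row <= 1150 &
                       200 + 350 * well_col <= 1150)
  expect_equal(!is.na(asg$region), centers_in)
})

test_that("overlapping polygons warn and go to the first-listed region", {
  lay <- small_layout(3, 3)
  big <- rbind(c(-1e3, -1e3), c(1e4, -1e3), c(1e4, 1e4), c(-1e3, 1e4))
  mask <- region_mask(list(list(label = "first", polygon = big),
                           list(label = "second", polygon = big)))
  expect_warning(asg <- assign_wells_to_regions(lay, mask), "overlap")
  expect_true(all(asg$region == "first"))
})

test_that("region summaries count unfiltered wells and conserve totals", {
  lay <- small_layout(4, 4)
  sc <- two_region_scenario(lay, noise = 0, seed = 31)
  ren <- render_array_image(sc)
  anchors <- scenario_anchors(lay)
  q <- run_quantify(ren$image, anchors, lay, sc$plex)
  mask <- region_mask(lapply(sc$regions, function(r)
    list(label = r$label, polygon = r$polygon)))
  asg <- assign_wells_to_regions(lay, mask)
  s <- region_summary(q$wq, asg, what = "net_afu")

  m21 <- s[s$probe == "miR-21", ]
  expect_equal(sum(m21$n), nrow(asg[!is.na(asg$region), ]))
  # noiseless: recovered means equal gain * density * footprint exactly
  foot <- (lay$well_side_um / 1000)^2
  want_t <- sc$gain_afu_per_amol * 20 * foot
  want_n <- sc$gain_afu_per_amol * 5 * foot
  expect_equal(m21$mean[m21$region == "Tumor 1"], want_t)
  expect_equal(m21$mean[m21$region == "NAT"], want_n)
  expect_equal(m21$sd, c(0, 0), ignore_attr = TRUE)
})

test_that("noisy region means land within standard-error bounds", {
  lay <- small_layout(4, 4)
  sc <- two_region_scenario(lay, noise = 50, seed = 32)
  ren <- render_array_image(sc)
  q <- run_quantify(ren$image, scenario_anchors(lay), lay, sc$plex)
  mask <- region_mask(lapply(sc$regions, function(r)
    list(label = r$label, polygon = r$polygon)))
  s <- region_summary(q$wq, assign_wells_to_regions(lay, mask), "net_afu")
  foot <- (lay$well_side_um / 1000)^2
  for (rg in c("Tumor 1", "NAT")) {
    row <- s[s$probe == "miR-21" & s$region == rg, ]
    truth <- sc$gain_afu_per_amol * ifelse(rg == "NAT", 5, 20) * foot
    expect_lt(abs(row$mean - truth), 3 * 50 * sqrt(2 / 64) / sqrt(row$n) * 3)
  }
})

test_that("cross-section CV recovers planted section variability", {
  s <- expand.grid(section = 1:4, region = c("r1", "r2"),
                   probe = c("miR-21", "let-7a"))
  s$mean <- 100
  out <- cross_section_cv(s)
  expect_true(all(out$per_cell$cv_percent == 0))
  expect_equal(out$grand_mean_cv_percent, 0)

  set.seed(13)
  factors <- rlnorm(50, 0, sqrt(log(1 + 0.15^2)))
  s2 <- data.frame(section = 1:50, region = "r1", probe = "miR-21",
                   mean = 100 * factors)
  out2 <- cross_section_cv(s2)
  expect_lt(abs(out2$per_cell$cv_percent - 15), 5)

  expect_error(cross_section_cv(s[s$section == 1, ]), ">= 2")
  expect_error(cross_section_cv(s[-1, ]), "every section")
})

test_that("serial-section pipeline reproduces a 17%-style CV study", {
  # four sections of the same tissue, modest section-to-section variability
  lay <- small_layout(3, 3)
  sc <- two_region_scenario(lay, noise = 0, seed = 41)
  ss <- generate_serial_sections(sc, 4, 0.17)
  mask <- region_mask(lapply(sc$regions, function(r)
    list(label = r$label, polygon = r$polygon)))
  asg <- assign_wells_to_regions(lay, mask)
  sums <- do.call(rbind, lapply(seq_along(ss$renders), function(i) {
    q <- run_quantify(ss$renders[[i]]$image, scenario_anchors(lay), lay,
                      sc$plex)
    s <- region_summary(q$wq, asg, "net_afu")
    s$section <- i
    s
  }))
  out <- suppressWarnings(
    cross_section_cv(sums[, c("section", "region", "probe", "mean")]))
  # noiseless within-section measurement: per-cell CV equals the CV of the
  # four drawn section factors exactly (for nonzero-amount cells)
  cv_factors <- 100 * sd(ss$factors) / mean(ss$factors)
  nz <- out$per_cell$probe %in% c("miR-21", "let-7a")
  expect_equal(out$per_cell$cv_percent[nz],
               rep(cv_factors, sum(nz)), tolerance = 1e-8)
})
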