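test_that("scenario validation names the offending field", {
  expect_error(scenario_config(ib4_positive_fraction = 1.2),
               "ib4_positive_fraction")
  expect_error(scenario_config(baseline_cv = 0), "baseline_cv")
  expect_error(scenario_config(responder_fold_change = -1),
               "responder_fold_change")
  expect_error(scenario_config(cluster_fraction = 0.7, border_fraction = 0.4),
               "cluster_fraction")
  expect_error(scenario_config(diameter_range_neg = c(24, 14)),
               "diameter_range_neg")
})

test_that("population honours geometry and subgroup structure", {
  pop <- generate_population(scenario_config(n_cells = 5000, seed = 3),
                             layout = FALSE)
  expect_equal(pop$area_um2, pi * (pop$diameter_um / 2)^2)
  ## subgroup fractions within 3 binomial SE
  for (spec in list(c("positive", 0.71), c("cluster", 0.16),
                    c("border", 0.03))) {
    obs <- switch(spec[1],
                  positive = mean(pop$ib4_status == "positive"),
                  cluster = mean(pop$is_clustered),
                  border = mean(pop$touches_border))
    p <- as.numeric(spec[2])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 5000) + 1 / 5000)
  }
  ## subgroup-specific diameters
  pos <- pop$ib4_status == "positive"
  expect_true(all(pop$diameter_um[pos] >= 22 & pop$diameter_um[pos] <= 32))
  expect_true(all(pop$diameter_um[!pos] >= 14 & pop$diameter_um[!pos] <= 24))
})

test_that("no responders means identical baseline and stimulated intensities", {
  pop <- generate_population(
    scenario_config(n_cells = 1000, responder_fraction = 0,
                    responder_fold_change = 10, seed = 5), layout = FALSE)
  expect_identical(pop$intensity_baseline, pop$intensity_stimulated)
})

test_that("baseline moments match the lognormal law within 3 SE", {
  n <- 49503
  pop <- generate_population(
    scenario_config(n_cells = n, baseline_mean = 1, baseline_cv = 1.8,
                    seed = 11), layout = FALSE)
  se <- lnorm_se(1, 1.8, n)
  expect_lt(abs(mean(pop$intensity_baseline) - 1), 3 * se$se_mean)
  expect_lt(abs(sd(pop$intensity_baseline) - 1.8), 3 * se$se_sd)
})

test_that("stratified lognormal population has near-exact moments", {
  pop <- lognormal_population(20000, mean = 1, cv = 1.8,
                              method = "stratified", seed = 2)
  expect_equal(mean(pop), 1, tolerance = 1e-9)
  expect_lt(abs(sd(pop) / 1.8 - 1), 0.01)
  expect_true(all(pop > 0))
})

test_that("population and renders are seed-reproducible", {
  sc <- scenario_config(n_cells = 30, glia_density = 4, debris_density = 6,
                        seed = 9)
  fs <- tiny_field()
  p1 <- generate_population(sc, fs)
  p2 <- generate_population(sc, fs)
  expect_identical(p1, p2)
  f1 <- render_fields(p1, fs, 0.96, seed = 4)
  f2 <- render_fields(p2, fs, 0.96, seed = 4)
  expect_identical(f1[[1]]$images, f2[[1]]$images)
})

test_that("noise-free renders recover every true intensity exactly", {
  sc <- singlet_scenario(n = 10, seed = 21)
  fs <- tiny_field(noise = 0)
  pop <- generate_population(sc, fs)
  flds <- render_fields(pop, fs, exposure_s = 0.96, noise = FALSE,
                        quantize = FALSE, channels = "marker")
  for (f in flds) {
    img <- f$images$marker
    lab <- EBImage::bwlabel(img > fs$background_level + 1e-9)
    for (r in seq_len(nrow(f$truth))) {
      tr <- f$truth[r, ]
      m <- lab == lab[round(tr$center_y_px) + 1, round(tr$center_x_px) + 1]
      v <- measure_cell(m, img, 0.96, fs$background_level,
                        pixel_size_um = fs$pixel_size_um, gain = fs$gain)
      expect_lt(abs(v$normalized / tr$intensity_marker - 1), 0.01)
    }
  }
})

test_that("rendered mask area converges to the true disc area", {
  ## one 20-um cell at 0.645 um/px: pi * 10^2 = 314 um2
  sc <- singlet_scenario(n = 1, seed = 2,
                         diameter_range_pos = c(20, 20),
                         diameter_range_neg = c(20, 20))
  fs <- tiny_field(noise = 0)
  pop <- generate_population(sc, fs)
  pop$aspect <- 1  # exact disc for the area oracle
  flds <- render_fields(pop, fs, 0.96, noise = FALSE, quantize = FALSE,
                        channels = "marker")
  img <- flds[[1]]$images$marker
  n_px <- sum(img > fs$background_level + 1e-9)
  expect_lt(abs(n_px * fs$pixel_size_um^2 / (pi * 100) - 1), 0.05)
})

test_that("renders at different exposures agree after normalization", {
  sc <- singlet_scenario(n = 8, seed = 13)
  fs <- tiny_field(noise = 0)
  pop <- generate_population(sc, fs)
  f1 <- render_fields(pop, fs, 0.48, noise = FALSE, channels = "marker")
  f2 <- render_fields(pop, fs, 0.96, noise = FALSE, channels = "marker")
  img1 <- f1[[1]]$images$marker; img2 <- f2[[1]]$images$marker
  lab <- EBImage::bwlabel(img2 > fs$background_level * 1.1)
  for (r in seq_len(nrow(f2[[1]]$truth))) {
    tr <- f2[[1]]$truth[r, ]
    m <- lab == lab[round(tr$center_y_px) + 1, round(tr$center_x_px) + 1]
    v1 <- measure_cell(m, img1, 0.48, fs$background_level,
                       pixel_size_um = fs$pixel_size_um, gain = fs$gain)
    v2 <- measure_cell(m, img2, 0.96, fs$background_level,
                       pixel_size_um = fs$pixel_size_um, gain = fs$gain)
    ## quantization tolerance: half a count per pixel relative to the signal
    expect_lt(abs(v1$normalized - v2$normalized),
              0.02 * max(v2$normalized, 0.05))
  }
})

test_that("renderer rejects invalid exposure and missing layout", {
  sc <- singlet_scenario(n = 4, seed = 1)
  fs <- tiny_field()
  pop <- generate_population(sc, fs)
  expect_error(render_fields(pop, fs, exposure_s = 0), "exposure")
  nolay <- generate_population(sc, fs, layout = FALSE)
  expect_error(render_fields(nolay, fs, 0.96), "layout")
})

test_that("field TIFF round trip preserves camera counts", {
  sc <- singlet_scenario(n = 4, seed = 6)
  fs <- tiny_field(noise = 2)
  pop <- generate_population(sc, fs)
  flds <- render_fields(pop, fs, 0.96, channels = "marker", seed = 1)
  dir <- withr::local_tempdir()
  write_field_tiffs(flds, dir)
  back <- read_field_tiff(file.path(
    dir, sprintf("field_%03d_marker.tif", flds[[1]]$field_id)))
  expect_equal(round(back), flds[[1]]$images$marker, tolerance = 1e-8)
  expect_true(file.exists(file.path(dir, "truth.csv")))
})
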