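test_that("histograms are proper densities on both scales", {
  set.seed(1)
  u <- runif(1000)
  h <- build_histogram(u, n_bins = 10, scale = "linear",
                       range_quantiles = c(0, 1))
  expect_true(all(abs(h$density - 1) < 0.2))
  expect_lt(abs(sum(h$density * h$width) - 1), 1e-9)

  x <- rlnorm(5000, 0, 1.2)
  for (sc in c("log", "linear")) {
    h2 <- build_histogram(x, scale = sc)
    expect_lt(abs(sum(h2$density * h2$width) - 1), 1e-9)
    expect_true(all(h2$density >= 0))
  }
  expect_error(build_histogram(1), "2 finite")
})

test_that("lognormal histogram shows the mode below the mean", {
  x <- lognormal_population(30000, 1, 1.8, method = "stratified", seed = 3)
  h <- build_histogram(x, scale = "linear", n_bins = 200)
  mode_x <- h$mids[which.max(h$density)]
  expect_lt(mode_x, mean(x))
  ## long right tail: generator quantiles far beyond the mode
  expect_gt(quantile(x, 0.999) / mode_x, 10)
})

test_that("disjoint supports give exact separation", {
  ctrl <- runif(3000, 0.5, 1)
  test <- c(runif(1800, 10, 20), runif(1200, 0.5, 1))
  g <- intersection_gate(ctrl, test)
  expect_equal(mean(g$labels_test), 0.6, tolerance = 0.02)
  expect_true(all(g$labels_test[test > 10]))
  expect_false(any(g$labels_test[test < 1]))
  expect_equal(g$fraction_positive_control, 0)
})

test_that("identical samples yield a near-zero positive fraction", {
  x <- rlnorm(4000, 0, 1.2)
  g <- intersection_gate(x, x)
  expect_equal(g$diagnostic, "no_responders")
  expect_equal(g$fraction_positive_test, 0)
})

test_that("a complete shift is recognized and gates every cell", {
  ctrl <- rlnorm(3000, 0, 0.5)
  test <- ctrl * 50
  g <- intersection_gate(ctrl, test)
  expect_equal(g$diagnostic, "complete_shift")
  expect_gt(g$fraction_positive_test, 0.999)
})

test_that("swapping control and test inverts the positive side", {
  set.seed(7)
  ctrl <- rlnorm(5000, 0, 1.2)
  test <- rlnorm(5000, 0, 1.2) * ifelse(runif(5000) < 0.5, 10, 1)
  g1 <- intersection_gate(ctrl, test)
  g2 <- intersection_gate(test, ctrl)
  expect_equal(g1$side, "above")
  expect_equal(g2$side, "below")
  ## cutoffs agree within half the inter-mode distance (log 10 / 2 = 1.15):
  ## with a mixture as "control" the taller smoothed mode is ambiguous
  expect_lt(abs(log(g1$cutoff) - log(g2$cutoff)), 1.15)
  ## the control sample is mostly "positive" on the mirrored side
  expect_gt(g2$fraction_positive_test, 0.6)
})

test_that("cutoff objects expose their diagnostics", {
  ctrl <- rlnorm(2000, 0, 1)
  test <- rlnorm(2000, 0, 1) * ifelse(runif(2000) < 0.4, 8, 1)
  g <- intersection_gate(ctrl, test)
  expect_s3_class(g, "cutoff_result")
  expect_true(is.finite(g$cutoff))
  expect_gte(g$n_crossings, 1)
  expect_true(g$crossing_bin >= 1)
  pooled <- range(c(ctrl, test))
  expect_gte(g$cutoff, pooled[1])
  expect_lte(g$cutoff, pooled[2])
})

test_that("intersection_cutoff demands shared bin edges", {
  a <- build_histogram(rlnorm(500), n_bins = 50)
  b <- build_histogram(rlnorm(500) * 4, n_bins = 50)
  expect_error(intersection_cutoff(a, b), "share")
})

test_that("responder classification recovers generator truth", {
  stim <- generate_population(
    scenario_config(n_cells = 4000, responder_fraction = 0.5, seed = 61),
    layout = FALSE)
  ctrl <- generate_population(
    scenario_config(n_cells = 4000, responder_fraction = 0, seed = 62),
    layout = FALSE)
  cells <- data.frame(
    cell_id = c(ctrl$cell_id, stim$cell_id),
    condition = rep(c("control", "ngf"), each = 4000),
    culture = rep(sprintf("c%d", 1:4), 2000),
    intensity_perk = c(ctrl$intensity_baseline, stim$intensity_stimulated))
  res <- classify_responders(cells, "control", "ngf")
  expect_lt(abs(res$fraction - 0.5), 0.05)
  ## labels track the generator's responder flags; with a 10-fold shift at
  ## sdlog 1.2 the crossing misclassifies ~17% on each side of the cutoff
  agree <- mean(res$labels$responder == stim$is_responder)
  expect_gt(agree, 0.75)
  expect_false(is.null(res$per_culture))
  expect_equal(nrow(res$per_culture), 4)
  expect_lt(res$fraction_sd_culture, 0.1)

  expect_error(classify_responders(cells, "control", "gdnf"), "gdnf")
  expect_error(classify_responders(cells[c(1:100, 4001:4100), ],
                                   "control", "ngf"), "at least")
})

test_that("zero-responder scenarios classify almost nothing", {
  ctrl <- generate_population(
    scenario_config(n_cells = 3000, responder_fraction = 0, seed = 71),
    layout = FALSE)
  stim <- generate_population(
    scenario_config(n_cells = 3000, responder_fraction = 0, seed = 72),
    layout = FALSE)
  g <- intersection_gate(ctrl$intensity_baseline, stim$intensity_stimulated)
  expect_lt(g$fraction_positive_test, 0.1)
})

test_that("subgroup profiles match hand-computed means and SEMs", {
  cells <- data.frame(
    diameter_um = c(20, 22, 24, 14, 16),
    intensity_perk = c(1, 2, 3, 10, 20),
    intensity_ib4 = c(5, 5, 8, 1, 1))
  grp <- factor(c("a", "a", "a", "b", "b"), levels = c("a", "b"))
  s <- subgroup_profiles(cells, grp)
  expect_equal(as.numeric(s$n), c(3, 2))
  st <- s$stats
  expect_equal(st$mean[st$group == "a" & st$channel == "perk"], 2)
  expect_equal(st$sem[st$group == "a" & st$channel == "perk"], 1 / sqrt(3))
  expect_equal(st$mean[st$group == "b" & st$channel == "perk"], 15)
  expect_equal(st$sem[st$group == "b" & st$channel == "perk"],
               sd(c(10, 20)) / sqrt(2))
  expect_equal(sum(s$n), nrow(cells))
  ## one-tailed unpaired t against the direct computation
  tt <- t.test(c(1, 2, 3), c(10, 20), alternative = "greater",
               var.equal = TRUE)
  expect_equal(s$tests$p[s$tests$channel == "perk"], tt$p.value)
})

test_that("diameter profiles separate the IB4 subgroups", {
  pop <- generate_population(scenario_config(n_cells = 8000, seed = 81),
                             layout = FALSE)
  s <- subgroup_profiles(pop, factor(pop$ib4_status,
                                     levels = c("positive", "negative")),
                         channels = "baseline")
  mids <- s$diameter_breaks[-1] - 1
  mode_pos <- mids[which.max(s$diameter_hist$positive)]
  mode_neg <- mids[which.max(s$diameter_hist$negative)]
  expect_true(mode_pos >= 22 && mode_pos <= 32)
  expect_true(mode_neg >= 14 && mode_neg <= 24)
  expect_gt(mode_pos, mode_neg)
})

test_that("null subgroup comparisons give uniform-looking p values", {
  set.seed(5)
  ps <- replicate(20, {
    cells <- data.frame(intensity_perk = rlnorm(60, 0, 1))
    grp <- factor(rep(c("a", "b"), each = 30))
    subgroup_profiles(cells, grp)$tests$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(min(ps), 1e-4)
})

test_that("an empty subgroup is reported with n = 0 and no test", {
  cells <- data.frame(intensity_perk = c(1, 2, 3))
  grp <- factor(rep("a", 3), levels = c("a", "b"))
  s <- subgroup_profiles(cells, grp)
  expect_equal(as.numeric(s$n), c(3, 0))
  expect_null(s$tests)
})

test_that("time courses report verbatim group sizes and ordered means", {
  set.seed(9)
  make_cells <- function(time, fold, n) data.frame(
    time_min = time,
    intensity_perk = rlnorm(n, log(fold), 0.1))
  cells <- rbind(make_cells(0, 1, 120), make_cells(5, 2, 150),
                 make_cells(15, 5, 130), make_cells(30, 5, 140))
  tc <- summarize_timecourse(cells, by = "time_min")
  expect_equal(tc$time_min, c(0, 5, 15, 30))
  expect_equal(tc$n, c(120, 150, 130, 140))
  ## monotone rise to plateau within SEM
  expect_true(all(diff(tc$mean) > -3 * tc$sem[-1]))
  expect_lt(abs(tc$mean[3] - tc$mean[4]), 3 * (tc$sem[3] + tc$sem[4]))

  flat <- rbind(make_cells(0, 1, 200), make_cells(10, 1, 200))
  tf <- summarize_timecourse(flat, by = "time_min")
  expect_true(all(abs(tf$mean - 1) < 3 * tf$sem + 0.02))
})
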