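test_that("shape metrics of a digital disc are round and convex", {
  for (r in c(8, 15, 24)) {
    m <- disc_mask(r)
    met <- shape_metrics(m, 1)
    expect_lt(abs(met$equivalent_diameter_um / (2 * r) - 1), 0.05)
    expect_lt(abs(met$aspect_ratio - 1), 0.08)
    ## convexity: rasterization leaves at most ~1 px of apparent depth
    expect_lt(met$concavity_depth, 1.2 / met$equivalent_diameter_um)
  }
})

test_that("ellipse aspect ratio matches the brute-force caliper oracle", {
  ## 40 x 15 um ellipse at 0.645 um/px, axes a = 31, b = 11.6 px
  px <- 0.645
  m <- ellipse_px_mask(20 / px, 7.5 / px, theta = 0.4)
  met <- shape_metrics(m, px)
  oracle <- bf_feret(m)
  expect_lt(abs(met$aspect_ratio / (oracle["max"] / oracle["min"]) - 1), 0.05)
  expect_gt(met$aspect_ratio, 2)  # fails the roundness rule
})

test_that("dumbbell of touching discs exceeds the concavity threshold", {
  px <- 0.645
  m <- dumbbell_mask(10 / px)
  met <- shape_metrics(m, px)
  oracle_rel <- bf_concavity_px(m) * px / met$equivalent_diameter_um
  expect_lt(abs(met$concavity_depth / oracle_rel - 1), 0.15)
  expect_gt(met$concavity_depth, 0.25)
})

test_that("shape metrics reject degenerate input", {
  expect_error(shape_metrics(matrix(FALSE, 5, 5)), "empty")
  expect_error(shape_metrics(1:10), "matrix")
})

test_that("uniform or sub-contrast images yield no objects", {
  params <- detection_params()
  expect_equal(nrow(detect_objects(flat_patch_image(), params)), 0)
  ## disc at only 1.25x background with a 30% contrast requirement
  img <- add_disc(flat_patch_image(), 60, 60, 12, value = 25)
  expect_equal(nrow(detect_objects(img, params)), 0)
  expect_error(detect_objects(array(0, c(4, 4, 2)), params), "matrix")
})

test_that("well-separated rendered somata are all detected with true areas", {
  ## brightly stained somata: threshold erosion of the dim rim stays < 2%
  sc <- singlet_scenario(n = 20, seed = 17, marker_mean = 3,
                         marker_cv = 0.2)
  fs <- field_spec(background_noise_sd = 2)
  pop <- generate_population(sc, fs)
  flds <- render_fields(pop, fs, 0.96, channels = "marker", seed = 3)
  dp <- detection_params()
  total <- 0
  for (f in flds) {
    obj <- detect_objects(f$images$marker, dp)
    total <- total + nrow(obj)
    for (r in seq_len(nrow(f$truth))) {
      tr <- f$truth[r, ]
      d <- sqrt((obj$centroid_x - tr$center_x_px)^2 +
                (obj$centroid_y - tr$center_y_px)^2)
      j <- which.min(d)
      expect_lt(d[j], 5)
      expect_gt(obj$area_um2[j], 0.95 * tr$area_um2)
      expect_lt(obj$area_um2[j], 1.05 * tr$area_um2)
    }
  }
  expect_equal(total, 20)
})

test_that("filter annotates every failed rule, not just the first", {
  img <- flat_patch_image(200, 200)
  img <- add_disc(img, 30, 30, 7, 100)     # ~95 um2: too small
  img <- add_disc(img, 100, 100, 25, 100)  # fine singlet
  obj <- segment_field(img, detection_params())
  expect_equal(nrow(obj), 2)
  small <- which.min(obj$area_um2)
  expect_false(obj$accepted[small])
  expect_match(obj$rejection_reasons[small], "size")
  expect_true(obj$accepted[-small])
  expect_identical(obj$rejection_reasons[-small], "")

  ## an edge-touching object collects the border reason
  img2 <- add_disc(flat_patch_image(120, 120), 3, 60, 10, 100)
  obj2 <- segment_field(img2, detection_params())
  expect_match(obj2$rejection_reasons[1], "border")

  ## multiple failures are all reported (size and aspect)
  img3 <- flat_patch_image(120, 200)
  img3[58:62, 40:160] <- 220  # thin bright bar
  obj3 <- segment_field(img3, detection_params())
  expect_match(obj3$rejection_reasons[1], "aspect")
})

test_that("loosening any single threshold never drops an accepted object", {
  fx <- standard_fixture(n_cells = 80, seed = 31)
  flds <- render_fields(fx$pop, fx$field, 0.96, channels = "marker", seed = 8)
  img <- flds[[1]]$images$marker
  base_params <- detection_params()
  objects <- detect_objects(img, base_params)
  base_acc <- filter_neurons(objects, base_params)$accepted
  looser <- list(detection_params(area_min_um2 = 100),
                 detection_params(area_max_um2 = 3000),
                 detection_params(aspect_ratio_max = 3),
                 detection_params(concavity_depth_max = 0.5),
                 detection_params(contrast_min = 0.15),
                 detection_params(reject_border = FALSE),
                 detection_params(reject_clusters = FALSE))
  for (p in looser) {
    acc <- filter_neurons(objects, p)$accepted
    expect_true(all(acc[base_acc]))
  }
})

test_that("segmentation decisions are deterministic", {
  fx <- standard_fixture(n_cells = 60, seed = 33)
  flds <- render_fields(fx$pop, fx$field, 0.96, channels = "marker", seed = 5)
  img <- flds[[1]]$images$marker
  o1 <- segment_field(img)
  o2 <- segment_field(img)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
})

test_that("touching neuron pairs are flagged as clusters", {
  sc <- scenario_config(n_cells = 16, cluster_fraction = 1, seed = 19,
                        border_fraction = 0, glia_density = 0,
                        debris_density = 0)
  fs <- field_spec(background_noise_sd = 2)
  pop <- generate_population(sc, fs)
  flds <- render_fields(pop, fs, 0.96, channels = "marker", seed = 2)
  n_acc <- 0
  for (f in flds) {
    obj <- segment_field(f$images$marker)
    n_acc <- n_acc + sum(obj$accepted)
    expect_true(all(grepl("cluster|concavity|aspect|size",
                          obj$rejection_reasons[!obj$accepted])))
  }
  expect_equal(n_acc, 0)
})
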