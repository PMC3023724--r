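# Shared fixture builders. Fixtures are generated in code at test time; the
# small field keeps renders fast while leaving room for the slot layout.

tiny_field <- function(noise = 0, ...) {
  field_spec(width_px = 512, height_px = 512, background_noise_sd = noise,
             ...)
}

## a clean layout scenario: singlets only, no distractors
singlet_scenario <- function(n = 12, seed = 1, ...) {
  scenario_config(n_cells = n, cluster_fraction = 0, border_fraction = 0,
                  glia_density = 0, debris_density = 0, seed = seed, ...)
}

## the standard heterogeneous fixture used for recall/precision checks
standard_fixture <- function(n_cells = 650, seed = 42) {
  sc <- scenario_config(n_cells = n_cells, seed = seed)
  fs <- field_spec()
  pop <- generate_population(sc, fs)
  list(scenario = sc, field = fs, pop = pop)
}

## match accepted objects back to ground-truth rows by centroid distance;
## returns per-truth-row logical "was accepted" plus the matched truth type
match_accepted <- function(fields, objects_list, pop, pixel_size_um) {
  accepted_of <- logical(nrow(pop))
  matched_types <- character(0)
  for (k in seq_along(fields)) {
    tr <- fields[[k]]$truth
    acc <- objects_list[[k]][objects_list[[k]]$accepted, , drop = FALSE]
    for (i in seq_len(nrow(acc))) {
      d <- sqrt((tr$center_x_px - acc$centroid_x[i])^2 +
                (tr$center_y_px - acc$centroid_y[i])^2)
      j <- which.min(d)
      if (d[j] < tr$diameter_um[j] / pixel_size_um) {
        accepted_of[match(tr$cell_id[j], pop$cell_id)] <- TRUE
        matched_types <- c(matched_types, tr$object_type[j])
      } else {
        matched_types <- c(matched_types, "unmatched")
      }
    }
  }
  list(accepted = accepted_of, types = matched_types)
}

## central moments of a lognormal with given mean and cv (oracle for
## standard-error computations)
lnorm_se <- function(mean, cv, n) {
  s2 <- log(1 + cv^2)
  mu <- log(mean) - s2 / 2
  Mk <- function(k) exp(k * mu + k^2 * s2 / 2)
  m1 <- Mk(1)
  mu2 <- Mk(2) - m1^2
  mu4 <- Mk(4) - 4 * Mk(3) * m1 + 6 * Mk(2) * m1^2 - 3 * m1^4
  var_s2 <- (mu4 - mu2^2 * (n - 3) / (n - 1)) / n
  list(se_mean = sqrt(mu2 / n), se_sd = sqrt(var_s2) / (2 * sqrt(mu2)))
}
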