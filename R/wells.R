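#' Virtual culture wells: resampled sensitivity of the culture mean
#'
#' Draws `n_wells` pseudo-replicate "virtual wells" of `n_per_well` cells
#' from a measured (or simulated) intensity population and computes each
#' well's mean. The SD of these well means is the sampling error a real
#' culture well of that cell count would carry, and so converts measured
#' cell numbers into assay sensitivity. Sampling is without replacement by
#' default, for which the closed-form SD carries the finite-population
#' correction (see [closed_form_sd()]); sampling with replacement is also
#' available.
#'
#' @param intensities numeric population of per-cell intensities.
#' @param n_per_well cells per virtual well (>= 1; `<= length(intensities)`
#'   when sampling without replacement).
#' @param n_wells number of wells to draw.
#' @param replacement sample with replacement?
#' @param seed optional RNG seed; fixed seed gives identical wells.
#' @return An object of class `virtual_well_summary`: population size `N`,
#'   `n_per_well`, `n_wells`, `replacement`, the vector of well `means`,
#'   `mean_of_means`, `sd_of_means`, the matching `sd_closed_form`
#'   (evaluated at the realized population SD), and `pop_mean`/`pop_sd`.
#' @examples
#' pop <- lognormal_population(5000, 1, 1.8, method = "stratified", seed = 1)
#' sample_virtual_wells(pop, 250, n_wells = 2000, seed = 2)
#' @export
sample_virtual_wells <- function(intensities, n_per_well, n_wells = 10000,
                                 replacement = FALSE, seed = NULL) {
  N <- length(intensities)
  if (N < 1) stop("population must be non-empty", call. = FALSE)
  if (n_per_well < 1) stop("n_per_well must be >= 1", call. = FALSE)
  if (!replacement && n_per_well > N)
    stop("n_per_well exceeds the population size; sampling is without ",
         "replacement", call. = FALSE)
  means <- with_seed(seed, vapply(seq_len(n_wells), function(i)
    mean(intensities[sample.int(N, n_per_well, replace = replacement)]),
    numeric(1)))
  pop_sd <- stats::sd(intensities)
  out <- list(N = N, n_per_well = as.integer(n_per_well),
              n_wells = as.integer(n_wells), replacement = replacement,
              means = means,
              mean_of_means = mean(means),
              sd_of_means = stats::sd(means),
              sd_closed_form = closed_form_sd(pop_sd, n_per_well, N,
                                              replacement),
              pop_mean = mean(intensities), pop_sd = pop_sd,
              seed = seed)
  class(out) <- "virtual_well_summary"
  out
}

#' @export
print.virtual_well_summary <- function(x, ...) {
  cat(sprintf("Virtual wells: %d wells of %d cells (N = %d, %s replacement)\n",
              x$n_wells, x$n_per_well, x$N,
              if (x$replacement) "with" else "without"))
  cat(sprintf("  mean of means %.4f, SD of means %.4f (closed form %.4f)\n",
              x$mean_of_means, x$sd_of_means, x$sd_closed_form))
  invisible(x)
}

#' Closed-form SD of a well mean
#'
#' `pop_sd / sqrt(n)` for sampling with replacement; multiplied by the
#' finite-population correction `sqrt((N - n) / (N - 1))` for sampling
#' without replacement. The correction vanishes as `N` grows and reaches
#' zero when the whole population is sampled.
#'
#' @param pop_sd population SD (>= 0).
#' @param n cells per well.
#' @param N population size (may be `Inf` with replacement).
#' @param replacement with or without replacement.
#' @return Expected SD of the well mean.
#' @export
closed_form_sd <- function(pop_sd, n, N = Inf, replacement = FALSE) {
  if (pop_sd < 0) stop("pop_sd must be >= 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  base <- pop_sd / sqrt(n)
  if (replacement || is.infinite(N)) return(base)
  if (n > N) stop("n exceeds N without replacement", call. = FALSE)
  if (N == 1) return(0)
  base * sqrt((N - n) / (N - 1))
}

#' Minimal detectable intensity change for a given cell count
#'
#' Converts the SD of the virtual-well mean into the smallest whole-culture
#' intensity change that can be called at `k` standard deviations (default
#' `k = 2`), expressed in percent of the culture mean. When only a subgroup
#' of the cells can respond, the required change *within the subgroup* is
#' the whole-culture bound divided by the subgroup fraction: a response
#' confined to one fifth of the cells must be five times larger to move the
#' culture mean by the same amount.
#'
#' @param summary a [sample_virtual_wells()] result, or a numeric SD of the
#'   well mean (as a fraction of the mean).
#' @param k detection threshold in SDs of the well mean.
#' @param subgroup_fraction fraction of cells able to respond, in (0, 1].
#' @param round_percent round the SD to whole percent before scaling, the
#'   convention used when quoting headline bounds (11% -> 22% -> 110%).
#' @return List with `sd_percent`, `whole_culture_percent` and
#'   `within_subgroup_percent`.
#' @examples
#' detectable_effect(0.1133, k = 2, subgroup_fraction = 1 / 5,
#'                   round_percent = TRUE)
#' @export
detectable_effect <- function(summary, k = 2, subgroup_fraction = 1,
                              round_percent = FALSE) {
  sd_mean <- if (inherits(summary, "virtual_well_summary"))
    summary$sd_of_means else summary
  if (!is.numeric(sd_mean) || length(sd_mean) != 1 || sd_mean < 0)
    stop("summary must be a virtual_well_summary or a single SD >= 0",
         call. = FALSE)
  if (subgroup_fraction <= 0 || subgroup_fraction > 1)
    stop("subgroup_fraction must lie in (0, 1]", call. = FALSE)
  sd_pct <- 100 * sd_mean
  if (round_percent) sd_pct <- round(sd_pct)
  whole <- k * sd_pct
  list(sd_percent = sd_pct, whole_culture_percent = whole,
       within_subgroup_percent = whole / subgroup_fraction)
}

#' Compare treated and untreated cultures via well means
#'
#' One-tailed unpaired t-test on (virtual or real) well means, the
#' statistical comparison used for treated-versus-control cultures. The
#' degenerate case of two zero-variance groups with equal means is reported
#' as `p = 0.5`, `t = 0` and flagged.
#'
#' @param control_means,treated_means numeric vectors of well means (>= 2
#'   each).
#' @param direction alternative hypothesis: treated `"greater"` (default) or
#'   `"less"` than control.
#' @return List with `t`, `df`, `p`, `mean_ratio` (treated / control) and
#'   `degenerate` flag.
#' @export
compare_conditions <- function(control_means, treated_means,
                               direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(control_means) < 2 || length(treated_means) < 2)
    stop("need at least 2 means per group", call. = FALSE)
  ratio <- mean(treated_means) / mean(control_means)
  if (stats::sd(control_means) == 0 && stats::sd(treated_means) == 0 &&
      mean(control_means) == mean(treated_means)) {
    return(list(t = 0, df = length(control_means) + length(treated_means) - 2,
                p = 0.5, mean_ratio = ratio, degenerate = TRUE))
  }
  tt <- stats::t.test(treated_means, control_means,
                      alternative = direction, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_ratio = ratio, degenerate = FALSE)
}
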