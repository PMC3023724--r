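#' Density histogram of per-cell intensities
#'
#' Builds a density histogram for one condition/channel, by default on
#' log-intensity bins: single-cell immunofluorescence intensities span two
#' orders of magnitude (CV around 180%), and on a linear axis the low-intensity
#' mode collapses into one or two bins. Bin edges default to 100 equal bins
#' over the 0.1-99.9 percentile range of the input (pass `edges` to share
#' edges across conditions); values outside the range are counted in the end
#' bins so the density always integrates to one. A Gaussian-kernel smoothed
#' density (Silverman's rule bandwidth by default) is kept alongside the raw
#' densities for crossing detection.
#'
#' @param values numeric vector of per-cell intensities (at least 2 finite).
#' @param edges explicit bin edges on the binning scale (overrides `n_bins`
#'   and `range_quantiles`).
#' @param n_bins number of equal-width bins.
#' @param range_quantiles quantile pair defining the binning range.
#' @param scale bin on `"log"` (natural log, default) or `"linear"` scale.
#' @param bw smoothing bandwidth on the binning scale; default
#'   `stats::bw.nrd0` of the (transformed) values.
#' @param condition,channel optional labels carried in the object.
#' @return An object of class `intensity_histogram`: bin `edges`, `mids`,
#'   `width`, `counts`, `density`, `smoothed`, sample size `n`, `scale`,
#'   `bw` and the labels.
#' @export
build_histogram <- function(values, edges = NULL, n_bins = 100,
                            range_quantiles = c(0.001, 0.999),
                            scale = c("log", "linear"), bw = NULL,
                            condition = NULL, channel = NULL) {
  scale <- match.arg(scale)
  values <- values[is.finite(values)]
  if (length(values) < 2)
    stop("need at least 2 finite values", call. = FALSE)
  tv <- transform_values(values, scale)
  if (is.null(edges)) {
    rng <- stats::quantile(tv, range_quantiles, names = FALSE)
    if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  if (length(edges) < 3 || any(diff(edges) <= 0))
    stop("edges must be increasing with at least 2 bins", call. = FALSE)
  tv <- pmin(pmax(tv, edges[1]), edges[length(edges)])
  h <- graphics::hist(tv, breaks = edges, plot = FALSE)
  if (is.null(bw)) bw <- stats::bw.nrd0(tv)
  hist <- list(edges = edges, mids = h$mids, width = diff(edges),
               counts = h$counts, density = h$density,
               smoothed = smooth_density(h$density, diff(edges)[1], bw),
               n = length(values), scale = scale, bw = bw,
               condition = condition, channel = channel)
  class(hist) <- "intensity_histogram"
  hist
}

transform_values <- function(values, scale) {
  if (scale == "linear") return(values)
  if (any(values <= 0)) {
    floor_v <- min(values[values > 0], 1e-12) / 2
    values <- pmax(values, floor_v)
  }
  log(values)
}

## Gaussian-kernel smoothing of binned densities (edge-replicated)
smooth_density <- function(density, width, bw) {
  bw_bins <- max(bw / width, 1e-6)
  half <- max(1L, ceiling(4 * bw_bins))
  k <- stats::dnorm(seq(-half, half) / bw_bins)
  k <- k / sum(k)
  n <- length(density)
  padded <- c(rep(density[1], half), density, rep(density[n], half))
  out <- stats::filter(padded, k, sides = 2)
  as.numeric(out)[(half + 1):(half + n)]
}

#' @export
print.intensity_histogram <- function(x, ...) {
  lab <- paste(c(x$condition, x$channel), collapse = " / ")
  cat(sprintf("Intensity histogram%s: n = %d, %d %s-scale bins, bw = %.3g\n",
              if (nzchar(lab)) paste0(" (", lab, ")") else "", x$n,
              length(x$mids), x$scale, x$bw))
  invisible(x)
}

#' @export
plot.intensity_histogram <- function(x, ..., col = "grey40") {
  mids <- if (x$scale == "log") exp(x$mids) else x$mids
  graphics::plot(mids, x$density, type = "s", log = if (x$scale == "log")
    "x" else "", xlab = "normalized intensity", ylab = "density",
    col = col, ...)
  graphics::lines(mids, x$smoothed, col = "red3")
  invisible(x)
}

#' Histogram-intersection cutoff between a control and a test condition
#'
#' Finds the intensity at which the test-condition density crosses above the
#' control density and stays above it, and takes that crossing as the
#' classification cutoff: test-condition cells beyond it are called
#' marker-positive / stimulus-responsive. The crossing is searched on the
#' smoothed densities between the control mode and the test mode, and must
#' persist for at least `min_run` bins, which suppresses noise crossings.
#' The rule is direction-aware: if the test mode lies below the control mode
#' the roles of the two sides are mirrored, so swapping control and test
#' inverts which side is "positive".
#'
#' Classifying by this cutoff is conservative for the truly positive class:
#' cells of the shifted population that fall below the crossing are counted
#' negative.
#'
#' @param control,test `intensity_histogram` objects with identical bin
#'   edges (build both with shared `edges`).
#' @param min_run minimum number of consecutive smoothed bins the test
#'   density must dominate.
#' @return An object of class `cutoff_result`: `cutoff` (intensity units),
#'   `side` (`"above"`/`"below"`), `diagnostic` (`"ok"`, `"no_responders"`,
#'   `"complete_shift"`), `n_crossings`, `crossing_bin`, `bw`,
#'   `fraction_positive_test`, `fraction_positive_control`, and the two
#'   sample sizes.
#' @export
intersection_cutoff <- function(control, test, min_run = 3) {
  stopifnot(inherits(control, "intensity_histogram"),
            inherits(test, "intensity_histogram"))
  if (!isTRUE(all.equal(control$edges, test$edges)) ||
      control$scale != test$scale)
    stop("histograms must share bin edges and scale", call. = FALSE)
  dc <- control$smoothed; dt <- test$smoothed
  cm <- which.max(dc); tm <- which.max(dt)
  side <- if (tm >= cm) "above" else "below"
  if (side == "below") {  # mirror and reuse the upward search
    dc <- rev(dc); dt <- rev(dt); cm <- length(dc) + 1 - cm
  }
  cc <- control$counts; tc <- test$counts
  if (side == "below") { cc <- rev(cc); tc <- rev(tc) }
  diffd <- dt - dc
  n_crossings <- sum(diff(sign(diffd[diffd != 0])) != 0)

  res <- if (max(abs(diffd)) <= 1e-9 * max(dc)) {
    list(status = "no_responders", bin = NA)  # indistinguishable densities
  } else if (any(tc > 0) && any(cc > 0) &&
             min(which(tc > 0)) > max(which(cc > 0))) {
    ## the test sample lies wholly beyond the control sample
    list(status = "complete_shift", bin = 1L)
  } else find_crossing(diffd, cm, min_run)
  nb <- length(control$mids)
  if (res$status == "complete_shift") {
    cut_t <- if (side == "above") control$edges[1] else
      control$edges[nb + 1]
    crossing_bin <- if (side == "above") 1L else nb
  } else if (res$status == "no_responders") {
    cut_t <- if (side == "above") Inf else -Inf
    crossing_bin <- NA_integer_
  } else {
    i <- res$bin
    ## interpolate the zero of (test - control) between bin midpoints
    i_orig <- if (side == "above") i else length(diffd) + 1 - i
    crossing_bin <- i_orig
    if (i > 1 && diffd[i - 1] < 0) {
      j_orig <- if (side == "above") i_orig - 1 else i_orig + 1
      d0 <- diffd[i - 1]; d1 <- diffd[i]
      w <- if (d1 > d0) -d0 / (d1 - d0) else 0.5
      m0 <- control$mids[j_orig]; m1 <- control$mids[i_orig]
      cut_t <- m0 + w * (m1 - m0)
    } else {
      cut_t <- control$edges[min(i_orig, nb)]
    }
  }
  cutoff <- back_transform(cut_t, control$scale)

  out <- list(cutoff = cutoff, side = side,
              diagnostic = res$status, n_crossings = n_crossings,
              crossing_bin = crossing_bin, bw = test$bw,
              fraction_positive_test = hist_fraction_beyond(test, cut_t, side),
              fraction_positive_control =
                hist_fraction_beyond(control, cut_t, side),
              control_n = control$n, test_n = test$n)
  class(out) <- "cutoff_result"
  out
}

find_crossing <- function(diffd, cm, min_run) {
  if (all(diffd >= 0)) return(list(status = "complete_shift", bin = 1L))
  pos <- diffd >= 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= min_run & starts > cm)
  if (!length(cand)) {
    ## relax: allow a dominating run that contains or precedes the mode tail
    cand <- which(r$values & r$lengths >= min_run & ends > cm)
    if (!length(cand)) return(list(status = "no_responders", bin = NA))
    return(list(status = "ok", bin = max(starts[cand[1]], cm + 1L)))
  }
  list(status = "ok", bin = starts[cand[1]])
}

back_transform <- function(x, scale) if (scale == "log") exp(x) else x

## fraction of a histogram's mass beyond the cutoff (transformed scale),
## linear within the crossing bin
hist_fraction_beyond <- function(hist, cut_t, side) {
  if (is.infinite(cut_t))
    return(if ((cut_t > 0) == (side == "above")) 0 else 1)
  e <- hist$edges
  p <- hist$counts / max(sum(hist$counts), 1)
  above <- sum(p[e[-length(e)] >= cut_t])
  k <- which(e[-length(e)] < cut_t & e[-1] > cut_t)
  if (length(k) == 1)
    above <- above + p[k] * (e[k + 1] - cut_t) / (e[k + 1] - e[k])
  if (side == "above") above else 1 - above
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Histogram-intersection cutoff: %.4g (%s, positive %s)\n",
              x$cutoff, x$diagnostic, x$side))
  cat(sprintf("  positive fraction: test %.1f%%, control %.1f%% (n = %d / %d)\n",
              100 * x$fraction_positive_test,
              100 * x$fraction_positive_control, x$test_n, x$control_n))
  invisible(x)
}

#' Gate raw intensity vectors by the histogram-intersection cutoff
#'
#' Builds shared-edge histograms for a control and a test sample, finds the
#' intersection cutoff, and labels every value. Cells exactly at the cutoff
#' are classified negative (the conservative choice for the truly positive
#' class). Positive fractions are recomputed exactly from the raw values.
#'
#' @param control_values,test_values numeric intensity vectors.
#' @param n_bins,range_quantiles,scale,bw passed to [build_histogram()].
#' @param min_run passed to [intersection_cutoff()].
#' @return A `cutoff_result` with added elements `labels_test` and
#'   `labels_control` (logical positivity per input value).
#' @examples
#' ctrl <- rlnorm(2000)
#' test <- rlnorm(2000) * ifelse(runif(2000) < 0.5, 10, 1)
#' intersection_gate(ctrl, test)$fraction_positive_test
#' @export
intersection_gate <- function(control_values, test_values, n_bins = 100,
                              range_quantiles = c(0.001, 0.999),
                              scale = c("log", "linear"), bw = NULL,
                              min_run = 3) {
  scale <- match.arg(scale)
  pooled <- c(control_values, test_values)
  pooled <- pooled[is.finite(pooled)]
  tp <- transform_values(pooled, scale)
  rng <- stats::quantile(tp, range_quantiles, names = FALSE)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  if (is.null(bw)) bw <- stats::bw.nrd0(tp)
  hc <- build_histogram(control_values, edges = edges, scale = scale,
                        bw = bw, condition = "control")
  ht <- build_histogram(test_values, edges = edges, scale = scale, bw = bw,
                        condition = "test")
  res <- intersection_cutoff(hc, ht, min_run = min_run)
  gate <- function(v) if (res$side == "above") v > res$cutoff else
    v < res$cutoff
  res$labels_test <- gate(test_values)
  res$labels_control <- gate(control_values)
  res$fraction_positive_test <- mean(res$labels_test)
  res$fraction_positive_control <- mean(res$labels_control)
  res
}

#' Classify stimulus-responsive cells in a cell table
#'
#' Compares the intensity distribution of a stimulated condition against the
#' unstimulated control on one channel and labels each stimulated cell as
#' responder or non-responder by the histogram-intersection cutoff. When a
#' culture/well column is present, the responder fraction is also reported
#' per culture with its across-culture spread (mean and SD), which is how
#' subgroup fractions of the form "50 +/- 8%" are quoted; the across-cell
#' binomial SE is reported alongside.
#'
#' @param cells cell table with condition and intensity columns.
#' @param control_condition,test_condition condition labels to compare.
#' @param channel channel name (uses column `intensity_<channel>`).
#' @param condition_col,culture_col column names.
#' @param min_cells minimum cells required per condition (error below).
#' @param warn_below warn when a condition has fewer cells than this
#'   (sampling error of the histogram grows quickly below ~1000 cells).
#' @param ... passed to [intersection_gate()].
#' @return A `responder_classification`: the `cutoff_result` plus `labels`
#'   (data.frame of test-condition `cell_id` and `responder`), `fraction`,
#'   `se_cells`, and `per_culture` (or `NULL`).
#' @export
classify_responders <- function(cells, control_condition = "control",
                                test_condition, channel = "perk",
                                condition_col = "condition",
                                culture_col = "culture",
                                min_cells = 250, warn_below = 1000, ...) {
  col <- paste0("intensity_", channel)
  for (nm in c(condition_col, col))
    if (!nm %in% names(cells))
      stop("column '", nm, "' not found in cells", call. = FALSE)
  ctrl <- cells[cells[[condition_col]] == control_condition, , drop = FALSE]
  test <- cells[cells[[condition_col]] == test_condition, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("control condition '", control_condition,
                            "' not present", call. = FALSE)
  if (nrow(test) == 0) stop("test condition '", test_condition,
                            "' not present", call. = FALSE)
  if (nrow(ctrl) < min_cells || nrow(test) < min_cells)
    stop("need at least ", min_cells, " cells per condition", call. = FALSE)
  if (nrow(ctrl) < warn_below || nrow(test) < warn_below)
    warning("fewer than ", warn_below, " cells in a condition; ",
            "classification cutoff will be noisy", call. = FALSE)
  res <- intersection_gate(ctrl[[col]], test[[col]], ...)
  res$labels <- data.frame(cell_id = if ("cell_id" %in% names(test))
    test$cell_id else seq_len(nrow(test)), responder = res$labels_test)
  res$fraction <- mean(res$labels_test)
  res$se_cells <- sqrt(res$fraction * (1 - res$fraction) / nrow(test))
  res$per_culture <- NULL
  if (culture_col %in% names(cells) && !all(is.na(test[[culture_col]]))) {
    by_c <- tapply(res$labels_test, test[[culture_col]], mean)
    res$per_culture <- data.frame(culture = names(by_c),
                                  fraction = as.numeric(by_c),
                                  row.names = NULL)
    res$fraction_mean_culture <- mean(by_c)
    res$fraction_sd_culture <- stats::sd(by_c)
  }
  class(res) <- c("responder_classification", "cutoff_result")
  res
}

#' @export
print.responder_classification <- function(x, ...) {
  cat(sprintf("Responder classification: %.1f%% positive (cutoff %.4g, %s)\n",
              100 * x$fraction, x$cutoff, x$diagnostic))
  if (!is.null(x$per_culture))
    cat(sprintf("  per culture: %.1f +/- %.1f%% (SD over %d cultures)\n",
                100 * x$fraction_mean_culture, 100 * x$fraction_sd_culture,
                nrow(x$per_culture)))
  invisible(x)
}

#' Profile two cell subgroups
#'
#' Cross-tabulates subgroup sizes and summarizes, per subgroup, the mean and
#' SEM of every intensity channel and the soma-diameter histogram (2-um bins
#' by default). When exactly two non-empty subgroups are present, each
#' channel is compared with a one-tailed unpaired t-test (first level greater
#' by default).
#'
#' @param cells cell table.
#' @param group factor (or column name in `cells`) defining the subgroups.
#' @param channels channels to summarize; default every `intensity_*`
#'   column.
#' @param diameter_bin_um bin width of the diameter profile.
#' @param alternative direction of the one-tailed test: first group level
#'   `"greater"` or `"less"` than the second.
#' @return An object of class `subgroup_summary`: `n` (named subgroup
#'   sizes), `stats` (group x channel mean/SEM table), `diameter_breaks`
#'   and `diameter_hist` (per-group counts), and `tests` (per-channel t, df,
#'   one-tailed p; `NULL` unless exactly two non-empty groups).
#' @export
subgroup_profiles <- function(cells, group, channels = NULL,
                              diameter_bin_um = 2,
                              alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.character(group) && length(group) == 1) {
    if (!group %in% names(cells))
      stop("grouping column '", group, "' not found", call. = FALSE)
    group <- cells[[group]]
  }
  if (length(group) != nrow(cells))
    stop("group labels must align with cells", call. = FALSE)
  if (!is.factor(group)) group <- factor(group)  # keep declared empty levels
  cols <- if (is.null(channels)) grep("^intensity_", names(cells),
                                      value = TRUE) else
    paste0("intensity_", channels)
  dcol <- intersect(c("equivalent_diameter_um", "diameter_um"),
                    names(cells))[1]

  lev <- levels(group)
  n <- table(group)
  stats_df <- do.call(rbind, lapply(lev, function(g) {
    sub <- cells[group == g, , drop = FALSE]
    do.call(rbind, lapply(cols, function(cl) data.frame(
      group = g, channel = sub("^intensity_", "", cl), n = nrow(sub),
      mean = if (nrow(sub)) mean(sub[[cl]]) else NA_real_,
      sem = if (nrow(sub) > 1) stats::sd(sub[[cl]]) / sqrt(nrow(sub))
            else NA_real_)))
  }))

  diameter_breaks <- diameter_hist <- NULL
  if (!is.na(dcol)) {
    dmax <- max(cells[[dcol]], 0, na.rm = TRUE)
    diameter_breaks <- seq(0, ceiling(dmax / diameter_bin_um + 1) *
                             diameter_bin_um, by = diameter_bin_um)
    diameter_hist <- lapply(stats::setNames(lev, lev), function(g) {
      v <- cells[[dcol]][group == g]
      if (!length(v)) return(integer(length(diameter_breaks) - 1))
      graphics::hist(v, breaks = diameter_breaks, plot = FALSE)$counts
    })
  }

  tests <- NULL
  nonempty <- lev[n[lev] > 1]
  if (length(nonempty) == 2) {
    tests <- do.call(rbind, lapply(cols, function(cl) {
      a <- cells[[cl]][group == nonempty[1]]
      b <- cells[[cl]][group == nonempty[2]]
      tt <- stats::t.test(a, b, alternative = alternative, var.equal = TRUE)
      data.frame(channel = sub("^intensity_", "", cl),
                 group_a = nonempty[1], group_b = nonempty[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, alternative = alternative)
    }))
  }
  out <- list(n = n, stats = stats_df, diameter_breaks = diameter_breaks,
              diameter_hist = diameter_hist, tests = tests)
  class(out) <- "subgroup_summary"
  out
}

#' @export
print.subgroup_summary <- function(x, ...) {
  cat("Subgroup profile:", paste(sprintf("%s (n = %d)", names(x$n), x$n),
                                 collapse = ", "), "\n")
  print(x$stats, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("One-tailed unpaired t-tests:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a time course or dose response
#'
#' Groups cells by a time or dose column and reports, per group in
#' increasing order, the cell count, mean and SEM of the chosen channel. No
#' interpolation or curve fitting is applied.
#'
#' @param cells cell table.
#' @param by grouping column name (e.g. `"time_min"` or `"dose"`).
#' @param channel channel to summarize.
#' @return `data.frame` with columns `by`-value, `n`, `mean`, `sem`.
#' @export
summarize_timecourse <- function(cells, by = "time_min", channel = "perk") {
  col <- paste0("intensity_", channel)
  for (nm in c(by, col))
    if (!nm %in% names(cells))
      stop("column '", nm, "' not found in cells", call. = FALSE)
  g <- cells[[by]]
  lev <- sort(unique(g))
  out <- do.call(rbind, lapply(lev, function(v) {
    x <- cells[[col]][g == v]
    data.frame(v, n = length(x), mean = mean(x),
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_)
  }))
  names(out)[1] <- by
  rownames(out) <- NULL
  out
}
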