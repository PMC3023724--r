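#' Object-identifier parameters
#'
#' The rule set used to accept an object as a single, intact neuron: area
#' between `area_min_um2` and `area_max_um2`, Feret aspect ratio (longest /
#' shortest caliper diameter) at most `aspect_ratio_max`, relative concavity
#' depth (maximum convex-hull-to-boundary distance divided by the equivalent
#' diameter) at most `concavity_depth_max`, and a pixel contrast of at least
#' `contrast_min` over the local background. Border-cut objects and cell
#' clusters are rejected when the corresponding flags are set.
#'
#' Defaults are the published identifier settings for DRG somata at 10x:
#' size 150-1500 um2, aspect ratio 2, concavity depth 0.25, contrast 30%.
#'
#' @param area_min_um2,area_max_um2 accepted area interval, um2.
#' @param aspect_ratio_max maximum longest/shortest caliper ratio (>= 1).
#' @param concavity_depth_max maximum relative concavity depth.
#' @param contrast_min minimum fractional intensity excess over the local
#'   background.
#' @param reject_border reject objects touching the field border.
#' @param reject_clusters reject objects recognized as cell clusters.
#' @param pixel_size_um pixel size used to convert pixel counts to um2.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(area_min_um2 = 150, area_max_um2 = 1500,
                             aspect_ratio_max = 2,
                             concavity_depth_max = 0.25,
                             contrast_min = 0.30,
                             reject_border = TRUE, reject_clusters = TRUE,
                             pixel_size_um = 0.645) {
  if (!(area_min_um2 > 0 && area_max_um2 > area_min_um2))
    stop("need 0 < area_min_um2 < area_max_um2", call. = FALSE)
  if (aspect_ratio_max < 1) stop("aspect_ratio_max must be >= 1", call. = FALSE)
  if (concavity_depth_max < 0 || contrast_min < 0)
    stop("concavity_depth_max and contrast_min must be >= 0", call. = FALSE)
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  p <- list(area_min_um2 = area_min_um2, area_max_um2 = area_max_um2,
            aspect_ratio_max = aspect_ratio_max,
            concavity_depth_max = concavity_depth_max,
            contrast_min = contrast_min,
            reject_border = isTRUE(reject_border),
            reject_clusters = isTRUE(reject_clusters),
            pixel_size_um = pixel_size_um)
  class(p) <- "detection_params"
  p
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(paste0("Object identifier: area %g-%g um2, aspect <= %g, ",
                     "concavity <= %g, contrast >= %g%%\n"),
              x$area_min_um2, x$area_max_um2, x$aspect_ratio_max,
              x$concavity_depth_max, 100 * x$contrast_min))
  cat(sprintf("  reject border: %s; reject clusters: %s; pixel %g um\n",
              x$reject_border, x$reject_clusters, x$pixel_size_um))
  invisible(x)
}

#' Shape metrics of a pixel mask
#'
#' Area and equivalent diameter from the pixel count; aspect ratio as the
#' ratio of the longest to the shortest caliper (Feret) diameter of the
#' boundary-pixel convex hull (rotating calipers, shortest caliper floored at
#' one pixel); concavity depth as the maximum distance from the convex hull
#' boundary to the object boundary, reported relative to the equivalent
#' diameter so the threshold is scale-free.
#'
#' @param mask logical matrix, `TRUE` inside the object.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return Named list: `area_um2`, `equivalent_diameter_um`, `aspect_ratio`,
#'   `concavity_depth`.
#' @examples
#' m <- outer(-20:20, -20:20, function(y, x) x^2 + y^2 <= 15^2)
#' shape_metrics(m, 1)
#' @export
shape_metrics <- function(mask, pixel_size_um = 1) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask > 0
  npx <- sum(mask)
  if (npx == 0) stop("empty mask", call. = FALSE)
  area <- npx * pixel_size_um^2
  eqd <- 2 * sqrt(area / pi)
  pts <- boundary_points(mask)
  cal <- caliper_diameters(pts)
  depth_px <- hull_concavity_depth(pts)
  list(area_um2 = area, equivalent_diameter_um = eqd,
       aspect_ratio = cal["max"] / cal["min"],
       concavity_depth = unname(depth_px * pixel_size_um / eqd))
}

## boundary pixel centres as (x, y) 0-based coordinates
boundary_points <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  bnd <- mask & !inner
  idx <- which(bnd, arr.ind = TRUE)
  cbind(x = idx[, "col"] - 1, y = idx[, "row"] - 1)
}

## longest and shortest caliper (Feret) diameters of a point set, in pixels
caliper_diameters <- function(pts) {
  if (nrow(pts) == 1L) return(c(max = 1, min = 1))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  d2 <- as.matrix(stats::dist(hp))
  fmax <- max(d2)
  nh <- nrow(hp)
  if (nh <= 2) {
    fmin <- 1  # collinear set: one-pixel extent across
  } else {
    ## rotating calipers: min over hull edges of the farthest point distance
    fmin <- Inf
    for (i in seq_len(nh)) {
      a <- hp[i, ]; b <- hp[if (i == nh) 1L else i + 1L, ]
      e <- b - a; len <- sqrt(sum(e^2))
      if (len == 0) next
      wdt <- max(abs((pts[, "x"] - a[1]) * e[2] -
                     (pts[, "y"] - a[2]) * e[1]) / len)
      fmin <- min(fmin, wdt)
    }
  }
  c(max = max(fmax, 1), min = max(fmin, 1))
}

## max distance (px) from the hull boundary to the object boundary
hull_concavity_depth <- function(pts) {
  if (nrow(pts) <= 3L) return(0)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(0)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nh)) {
    a <- hp[i, ]; b <- hp[if (i == nh) 1L else i + 1L, ]
    dmin <- pmin(dmin, point_segment_distance(pts, a, b))
  }
  max(dmin)
}

point_segment_distance <- function(pts, a, b) {
  e <- b - a
  len2 <- sum(e^2)
  if (len2 == 0) return(sqrt((pts[, "x"] - a[1])^2 + (pts[, "y"] - a[2])^2))
  t <- ((pts[, "x"] - a[1]) * e[1] + (pts[, "y"] - a[2]) * e[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((pts[, "x"] - (a[1] + t * e[1]))^2 +
       (pts[, "y"] - (a[2] + t * e[2]))^2)
}

#' Detect candidate objects in a marker-channel image
#'
#' Thresholds the image at `(1 + contrast_min)` times the global background
#' estimate (the image median; objects are sparse), labels connected
#' components, and computes for each component its shape metrics, its
#' contrast against a local background (median of an annulus of width 10 um
#' around the object, excluding other objects; falls back to the global
#' estimate), whether it touches the field border, and whether it looks like
#' a cell cluster. Cluster recognition uses two rules: two or more regional
#' intensity maxima (on a lightly smoothed image) separated by more than half
#' the shortest caliper diameter, or merging with another above-minimum-size
#' object after a one-pixel dilation.
#'
#' No rule other than the pixel threshold is applied here; [filter_neurons()]
#' turns the metrics into accept/reject decisions.
#'
#' @param image single-channel numeric matrix (camera counts).
#' @param params a [detection_params()].
#' @param min_pixels discard components smaller than this many pixels
#'   (camera noise specks).
#' @return A `data.frame` (class `segmented_objects`) with one row per
#'   candidate: `label`, `n_pixels`, `area_um2`, `equivalent_diameter_um`,
#'   `aspect_ratio`, `concavity_depth`, `contrast`, `local_background`,
#'   0-based `centroid_x`/`centroid_y`, `touches_border`, `in_cluster`.
#'   The label matrix and parameters are attached as attributes.
#' @export
detect_objects <- function(image, params = detection_params(),
                           min_pixels = 4L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix", call. = FALSE)
  stopifnot(inherits(params, "detection_params"))
  empty <- empty_objects(image, params)
  if (length(image) == 0) return(empty)
  bg_global <- stats::median(image)
  thr <- if (bg_global > 0) bg_global * (1 + params$contrast_min) else 0
  bin <- image > thr
  if (!any(bin)) return(empty)
  lab <- EBImage::bwlabel(bin)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_pixels)
  if (!length(keep)) return(empty)

  h <- nrow(image); w <- ncol(image)
  ann_px <- max(1L, round(10 / params$pixel_size_um))
  smooth <- smooth_image(image)
  merged <- dilation_merge_labels(bin, lab, keep, tab, params)

  res <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    l <- keep[k]
    idx <- which(lab == l)
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    r0 <- max(1L, min(rows) - ann_px - 2L); r1 <- min(h, max(rows) + ann_px + 2L)
    c0 <- max(1L, min(cols) - ann_px - 2L); c1 <- min(w, max(cols) + ann_px + 2L)
    sub_lab <- lab[r0:r1, c0:c1]
    sub_img <- image[r0:r1, c0:c1]
    m <- sub_lab == l
    area <- length(idx) * params$pixel_size_um^2
    eqd <- 2 * sqrt(area / pi)
    pts <- boundary_points(m)
    cal <- caliper_diameters(pts)
    depth_px <- hull_concavity_depth(pts)

    ring <- EBImage::dilate(m * 1, EBImage::makeBrush(2 * ann_px + 1, "disc")) > 0
    clear <- EBImage::dilate((sub_lab > 0) * 1, EBImage::makeBrush(5, "box")) > 0
    ring <- ring & !clear
    local_bg <- if (any(ring)) stats::median(sub_img[ring]) else bg_global
    contrast <- if (local_bg > 0)
      (stats::median(sub_img[m]) - local_bg) / local_bg else Inf

    n_max <- intensity_maxima_spread(smooth[r0:r1, c0:c1], m)
    in_cluster <- (n_max$spread > 0.5 * cal["min"] && n_max$n >= 2) ||
      l %in% merged

    res[[k]] <- data.frame(
      label = l, n_pixels = length(idx),
      area_um2 = area,
      equivalent_diameter_um = eqd,
      aspect_ratio = unname(cal["max"] / cal["min"]),
      concavity_depth = unname(depth_px * params$pixel_size_um / eqd),
      contrast = contrast, local_background = local_bg,
      centroid_x = mean(cols) - 1, centroid_y = mean(rows) - 1,
      touches_border = min(rows) == 1L || max(rows) == h ||
        min(cols) == 1L || max(cols) == w,
      in_cluster = in_cluster)
  }
  objects <- do.call(rbind, res)
  rownames(objects) <- NULL
  attr(objects, "labels") <- lab
  attr(objects, "params") <- params
  class(objects) <- c("segmented_objects", "data.frame")
  objects
}

empty_objects <- function(image, params) {
  objects <- data.frame(label = integer(), n_pixels = integer(),
                        area_um2 = numeric(), equivalent_diameter_um = numeric(),
                        aspect_ratio = numeric(), concavity_depth = numeric(),
                        contrast = numeric(), local_background = numeric(),
                        centroid_x = numeric(), centroid_y = numeric(),
                        touches_border = logical(), in_cluster = logical())
  attr(objects, "labels") <- matrix(0L, nrow(image), ncol(image))
  attr(objects, "params") <- params
  class(objects) <- c("segmented_objects", "data.frame")
  objects
}

smooth_image <- function(image) {
  br <- EBImage::makeBrush(9, "Gaussian", sigma = 2)
  as.matrix(EBImage::filter2(image, br))
}

## labels whose objects merge with another above-min-size object after a
## 1-pixel dilation
dilation_merge_labels <- function(bin, lab, keep, tab, params) {
  big <- keep[tab[keep] * params$pixel_size_um^2 >= params$area_min_um2]
  if (length(big) < 2) return(integer())
  dil <- EBImage::bwlabel(EBImage::dilate(bin * 1,
                                          EBImage::makeBrush(3, "box")) > 0)
  merged <- integer()
  ## map each big label to its dilated component via one member pixel
  first_px <- vapply(big, function(l) which(lab == l)[1], integer(1))
  comp <- dil[first_px]
  dup <- comp[duplicated(comp)]
  merged <- big[comp %in% dup]
  merged
}

## regional maxima inside the mask: connected plateau components count as
## one maximum each; spread is the largest centroid distance between them
intensity_maxima_spread <- function(sub_smooth, mask) {
  mx <- EBImage::dilate(sub_smooth, EBImage::makeBrush(3, "box"))
  is_max <- mask & (sub_smooth >= as.matrix(mx) - 1e-9)
  if (!any(is_max)) return(list(n = 0L, spread = 0))
  lab <- EBImage::bwlabel(is_max)
  n <- max(lab)
  if (n < 2) return(list(n = n, spread = 0))
  idx <- which(lab > 0, arr.ind = TRUE)
  cen <- cbind(tapply(idx[, 1], lab[lab > 0], mean),
               tapply(idx[, 2], lab[lab > 0], mean))
  list(n = n, spread = max(stats::dist(cen)))
}

#' Apply the object-identifier rules
#'
#' Annotates every candidate object with *all* rules it fails (`size`,
#' `aspect`, `concavity`, `contrast`, `border`, `cluster`) and flags as
#' accepted exactly the objects that pass every enabled rule.
#'
#' @param objects a `segmented_objects` table from [detect_objects()].
#' @param params a [detection_params()]; defaults to the parameters the
#'   objects were detected with.
#' @return The table with added columns `accepted` (logical) and
#'   `rejection_reasons` (comma-joined string, empty when accepted).
#' @export
filter_neurons <- function(objects, params = attr(objects, "params")) {
  stopifnot(inherits(params, "detection_params"))
  n <- nrow(objects)
  reasons <- vector("list", n)
  fail <- function(cond, tag) lapply(seq_len(n), function(i)
    if (isTRUE(cond[i])) tag else NULL)
  checks <- list(
    fail(objects$area_um2 < params$area_min_um2 |
         objects$area_um2 > params$area_max_um2, "size"),
    fail(objects$aspect_ratio > params$aspect_ratio_max, "aspect"),
    fail(objects$concavity_depth > params$concavity_depth_max, "concavity"),
    fail(objects$contrast < params$contrast_min, "contrast"),
    fail(params$reject_border & objects$touches_border, "border"),
    fail(params$reject_clusters & objects$in_cluster, "cluster"))
  reasons <- lapply(seq_len(n), function(i)
    unlist(lapply(checks, `[[`, i)))
  objects$accepted <- lengths(reasons) == 0L
  objects$rejection_reasons <- vapply(reasons, paste, character(1),
                                      collapse = ",")
  objects
}

#' Detect and filter neurons in one marker-channel image
#'
#' Convenience wrapper: [detect_objects()] followed by [filter_neurons()].
#'
#' @inheritParams detect_objects
#' @return A filtered `segmented_objects` table.
#' @export
segment_field <- function(image, params = detection_params(),
                          min_pixels = 4L) {
  filter_neurons(detect_objects(image, params, min_pixels), params)
}
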