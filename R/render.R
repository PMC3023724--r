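#' Render synthetic multi-channel field images
#'
#' Rasterizes a laid-out ground-truth population (see
#' [generate_population()]) into camera images, one matrix per channel per
#' field. Neurons are drawn as mildly elliptic somata with a hemispheric
#' (chord-depth) radial profile; glia as dim irregular blobs that violate the
#' contrast and/or concavity identifier rules; debris as bright sub-150-um2
#' specks. Pixel weights are scaled so that for every object the integrated
#' signal above background equals `true_intensity x mask area (um2) x
#' exposure x gain` exactly, before read noise, quantization and clipping at
#' the camera saturation level.
#'
#' @param cells a `ground_truth` table with a field layout.
#' @param spec a [field_spec()]; defaults to the one attached to `cells`.
#' @param exposure_s exposure time in seconds (> 0), one value for all
#'   channels.
#' @param condition which phospho-channel truth to render: the unstimulated
#'   baseline or the stimulated-condition intensity.
#' @param channels channel names to render (subset of the spec's channels).
#' @param noise add Gaussian read noise (disable for oracle renders).
#' @param quantize round to integer counts and clip at saturation.
#' @param seed RNG seed for read noise and distractor shapes; the same seed
#'   reproduces bit-identical images.
#' @return An object of class `rendered_fields`: a list with one element per
#'   field, each holding `field_id`, `images` (named list of
#'   `height_px x width_px` matrices, camera counts) and `truth` (the rows
#'   rendered into that field). Exposure and spec are attached as attributes.
#' @export
render_fields <- function(cells, spec = attr(cells, "field_spec"),
                          exposure_s = 0.96,
                          condition = c("baseline", "stimulated"),
                          channels = spec$channels,
                          noise = TRUE, quantize = TRUE, seed = 0L) {
  condition <- match.arg(condition)
  if (!is.numeric(exposure_s) || length(exposure_s) != 1L || exposure_s <= 0)
    stop("exposure_s must be a single positive number", call. = FALSE)
  stopifnot(inherits(spec, "field_spec"))
  if (!all(channels %in% spec$channels))
    stop("unknown channel(s): ",
         paste(setdiff(channels, spec$channels), collapse = ", "),
         call. = FALSE)
  if (all(is.na(cells$field_id)))
    stop("cells carry no field layout; run generate_population(layout = TRUE)",
         call. = FALSE)
  ok <- !is.na(cells$center_x_px) &
    cells$center_x_px > -cells$diameter_um / spec$pixel_size_um &
    cells$center_x_px < spec$width_px + cells$diameter_um / spec$pixel_size_um &
    cells$center_y_px > -cells$diameter_um / spec$pixel_size_um &
    cells$center_y_px < spec$height_px + cells$diameter_um / spec$pixel_size_um
  if (any(!ok))
    stop("some cells lie outside the field grid", call. = FALSE)

  source_col <- c(marker = "intensity_marker", ib4 = "intensity_ib4",
                  perk = if (condition == "baseline") "intensity_baseline"
                         else "intensity_stimulated")

  fields <- sort(unique(cells$field_id[!is.na(cells$field_id)]))
  out <- vector("list", length(fields))
  names(out) <- sprintf("field_%03d", fields)
  for (k in seq_along(fields)) {
    f <- fields[k]
    rows <- cells[!is.na(cells$field_id) & cells$field_id == f, , drop = FALSE]
    imgs <- with_seed(seed + f, {
      render_one_field(rows, spec, exposure_s, channels, source_col,
                       noise, quantize)
    })
    out[[k]] <- list(field_id = f, images = imgs, truth = rows)
  }
  attr(out, "field_spec") <- spec
  attr(out, "exposure_s") <- exposure_s
  attr(out, "condition") <- condition
  class(out) <- "rendered_fields"
  out
}

render_one_field <- function(rows, spec, exposure_s, channels, source_col,
                             noise, quantize) {
  h <- spec$height_px; w <- spec$width_px
  pix2 <- spec$pixel_size_um^2
  rasters <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    r_px <- r$diameter_um / 2 / spec$pixel_size_um
    if (r$object_type == "glia")
      blob_raster(r$center_x_px, r$center_y_px, r_px, h, w)
    else
      ellipse_raster(r$center_x_px, r$center_y_px, r_px, r$aspect, r$theta,
                     h, w, profile = "hemisphere")
  })
  imgs <- list()
  for (ch in channels) {
    img <- matrix(spec$background_level, nrow = h, ncol = w)
    ivals <- rows[[source_col[[ch]]]]
    for (i in seq_len(nrow(rows))) {
      ra <- rasters[[i]]
      if (length(ra$idx) == 0 || ivals[i] <= 0) next
      amount <- ivals[i] * exposure_s * spec$gain * length(ra$idx) * pix2
      img[ra$idx] <- img[ra$idx] + amount * ra$w / sum(ra$w)
    }
    if (noise && spec$background_noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$background_noise_sd), h, w)
    if (quantize)
      img <- pmin(pmax(round(img), 0), spec$saturation_level)
    imgs[[ch]] <- img
  }
  imgs
}

## elliptic soma raster: pixel linear indices + profile weights.
## 0-based centre coordinates; matrix is indexed [row = y + 1, col = x + 1].
ellipse_raster <- function(cx, cy, r_px, aspect = 1, theta = 0, h, w,
                           profile = c("hemisphere", "flat")) {
  profile <- match.arg(profile)
  a <- r_px * sqrt(aspect); b <- r_px / sqrt(aspect)  # area-preserving
  ext <- ceiling(a) + 1L
  cols <- max(1L, floor(cx + 1 - ext)):min(w, ceiling(cx + 1 + ext))
  rws <- max(1L, floor(cy + 1 - ext)):min(h, ceiling(cy + 1 + ext))
  if (!length(cols) || !length(rws)) return(list(idx = integer(), w = numeric()))
  dx <- outer(rep(1, length(rws)), cols - 1 - cx)
  dy <- outer(rws - 1 - cy, rep(1, length(cols)))
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  q <- (xr / a)^2 + (yr / b)^2
  inside <- q <= 1
  if (!any(inside)) return(list(idx = integer(), w = numeric()))
  wts <- if (profile == "hemisphere") sqrt(pmax(1 - q[inside], 0)) else
    rep(1, sum(inside))
  ## guard against zero total weight on tiny rasters
  if (sum(wts) <= 0) wts <- rep(1, sum(inside))
  idx <- (rep(cols, each = length(rws)) - 1L) * h + rep(rws, length(cols))
  list(idx = idx[as.vector(inside)], w = wts)
}

## irregular glia blob: union of overlapping flat ellipses (concave outline)
blob_raster <- function(cx, cy, r_px, h, w) {
  k <- sample(3:5, 1)
  acc <- list(idx = integer(), w = numeric())
  for (i in seq_len(k)) {
    off <- runif(2, -0.6, 0.6) * r_px
    ra <- ellipse_raster(cx + off[1], cy + off[2],
                         r_px * runif(1, 0.35, 0.65),
                         aspect = runif(1, 1, 2.5), theta = runif(1, 0, pi),
                         h, w, profile = "flat")
    acc$idx <- c(acc$idx, ra$idx)
  }
  idx <- unique(acc$idx)
  list(idx = idx, w = rep(1, length(idx)))
}

#' Write rendered fields as TIFF images plus a truth table
#'
#' One 16-bit grayscale TIFF per field and channel
#' (`field_<id>_<channel>.tif`, counts stored as `value / (2^16 - 1)`), plus
#' `truth.csv` with the per-field ground-truth rows.
#'
#' @param fields a `rendered_fields` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_field_tiffs <- function(fields, dir) {
  stopifnot(inherits(fields, "rendered_fields"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (f in fields) {
    for (ch in names(f$images)) {
      p <- file.path(dir, sprintf("field_%03d_%s.tif", f$field_id, ch))
      tiff::writeTIFF(f$images[[ch]] / 65535, p, bits.per.sample = 16L,
                      compression = "none")
      paths <- c(paths, p)
    }
  }
  truth <- do.call(rbind, lapply(fields, `[[`, "truth"))
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE)
  invisible(c(paths, tp))
}

#' Read a single-channel field TIFF written by [write_field_tiffs()]
#'
#' @param path TIFF file path.
#' @return Matrix of camera counts.
#' @export
read_field_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img * 65535
}
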