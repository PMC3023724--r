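# Constructed pixel masks and brute-force shape oracles. The oracles use
# their own boundary extraction and exhaustive search so they stay
# independent of the package's caliper / hull code paths.

disc_mask <- function(r_px, pad = 3L) {
  n <- 2L * (ceiling(r_px) + pad) + 1L
  c0 <- ceiling(r_px) + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r_px^2)
}

ellipse_px_mask <- function(a_px, b_px, theta = 0, pad = 3L) {
  n <- 2L * (ceiling(max(a_px, b_px)) + pad) + 1L
  c0 <- ceiling(max(a_px, b_px)) + pad + 1L
  outer(seq_len(n), seq_len(n), function(i, j) {
    dx <- j - c0; dy <- i - c0
    xr <- dx * cos(theta) + dy * sin(theta)
    yr <- -dx * sin(theta) + dy * cos(theta)
    (xr / a_px)^2 + (yr / b_px)^2 <= 1
  })
}

dumbbell_mask <- function(r_px, pad = 3L) {
  w <- 4L * ceiling(r_px) + 2L * pad + 1L
  h <- 2L * (ceiling(r_px) + pad) + 1L
  cy <- ceiling(r_px) + pad + 1L
  cx1 <- ceiling(r_px) + pad + 1L
  cx2 <- cx1 + 2L * r_px
  outer(seq_len(h), seq_len(w), function(i, j)
    (i - cy)^2 + (j - cx1)^2 <= r_px^2 | (i - cy)^2 + (j - cx2)^2 <= r_px^2)
}

## 8-connected boundary pixel centres, (x, y), own implementation
bf_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  keep <- vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    i == 1 || i == h || j == 1 || j == w ||
      !(mask[i - 1, j] && mask[i + 1, j] && mask[i, j - 1] && mask[i, j + 1])
  }, logical(1))
  cbind(x = idx[keep, 2], y = idx[keep, 1])
}

## Feret diameters by exhaustive projection over angles
bf_feret <- function(mask, n_angles = 720) {
  pts <- bf_boundary(mask)
  fmax <- 0
  fmin <- Inf
  for (th in seq(0, pi, length.out = n_angles)) {
    proj <- pts[, "x"] * cos(th) + pts[, "y"] * sin(th)
    ext <- max(proj) - min(proj)
    fmax <- max(fmax, ext)
    fmin <- min(fmin, ext)
  }
  c(max = fmax, min = fmin)
}

## concavity depth (px) by dense sampling of the convex hull outline
bf_concavity_px <- function(mask, step = 0.05) {
  pts <- bf_boundary(mask)
  hull <- grDevices::chull(pts)
  hp <- pts[c(hull, hull[1]), , drop = FALSE]
  samp <- do.call(rbind, lapply(seq_len(nrow(hp) - 1), function(i) {
    a <- hp[i, ]; b <- hp[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, by = if (len > 0) step / max(len, step) else 1)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  dmin <- vapply(seq_len(nrow(pts)), function(k)
    min(sqrt((samp[, 1] - pts[k, "x"])^2 + (samp[, 2] - pts[k, "y"])^2)),
    numeric(1))
  max(dmin)
}

## uniform synthetic field: background plus flat-value patches
flat_patch_image <- function(h = 120, w = 120, bg = 100) {
  matrix(bg, h, w)
}
add_disc <- function(img, cy, cx, r, value) {
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) img[i, j] <- img[i, j] + value
  img
}
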