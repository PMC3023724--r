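#' Generate a ground-truthed synthetic culture population
#'
#' Draws a cell table with the statistical structure of a dissociated DRG
#' culture: IB4 status, subgroup-dependent soma diameters, a lognormal
#' phospho-channel baseline, multiplicative stimulus responses restricted to
#' the responder subgroup, a bimodal IB4 channel whose low component models
#' unspecific lectin binding, plus clustered and border-cut neurons and
#' (when a field layout is produced) glia and debris distractors.
#'
#' With `layout = TRUE` every object is assigned to a field and a pixel
#' position on a collision-free grid, so the table can be handed directly to
#' [render_fields()]. Clustered neurons are placed as touching pairs; border
#' neurons are centred on the field edge. With `layout = FALSE` only the
#' per-cell quantities are generated (fast; sufficient for histogram and
#' virtual-well work).
#'
#' Stimulated-condition intensities are `intensity_baseline *
#' responder_fold_change * noise` for responders and exactly
#' `intensity_baseline` otherwise, so a scenario with `responder_fraction = 0`
#' has identical baseline and stimulated distributions.
#'
#' @param scenario a [scenario_config()].
#' @param field a [field_spec()]; geometry used for the layout.
#' @param layout place objects on fields (`TRUE`) or skip placement.
#' @return A `data.frame` (class `ground_truth`) with one row per object:
#'   `cell_id`, `object_type` ("neuron", "glia", "debris"), `field_id`,
#'   0-based `center_x_px`/`center_y_px`, `diameter_um`, `area_um2`,
#'   `aspect`, `theta`, logical `is_neuron`, `is_clustered`,
#'   `touches_border`, `ib4_status` ("positive"/"negative"), `is_responder`,
#'   and true intensities `intensity_marker`, `intensity_ib4`,
#'   `intensity_baseline`, `intensity_stimulated`. The scenario and field
#'   spec are attached as attributes.
#' @examples
#' pop <- generate_population(scenario_config(n_cells = 500, seed = 1),
#'                            layout = FALSE)
#' mean(pop$ib4_status == "positive")
#' @export
generate_population <- function(scenario, field = field_spec(),
                                layout = TRUE) {
  validate_scenario(scenario)
  with_seed(scenario$seed, {
    n <- scenario$n_cells
    ib4_pos <- runif(n) < scenario$ib4_positive_fraction
    dr <- ifelse(ib4_pos, 1L, 2L)
    lo <- c(scenario$diameter_range_pos[1], scenario$diameter_range_neg[1])[dr]
    hi <- c(scenario$diameter_range_pos[2], scenario$diameter_range_neg[2])[dr]
    diameter <- runif(n, lo, hi)

    pb <- lnorm_params(scenario$baseline_mean, scenario$baseline_cv)
    baseline <- rlnorm(n, pb["meanlog"], pb["sdlog"])
    responder <- runif(n) < scenario$responder_fraction
    pr <- lnorm_params(1, max(scenario$response_cv, 1e-12))
    fold <- ifelse(responder,
                   scenario$responder_fold_change *
                     rlnorm(n, pr["meanlog"], pr["sdlog"]), 1)
    stimulated <- baseline * fold

    pn <- lnorm_params(scenario$ib4_neg_mean, scenario$ib4_neg_cv)
    pp <- lnorm_params(scenario$ib4_pos_mean, scenario$ib4_pos_cv)
    ib4 <- ifelse(ib4_pos, rlnorm(n, pp["meanlog"], pp["sdlog"]),
                  rlnorm(n, pn["meanlog"], pn["sdlog"]))
    pm <- lnorm_params(scenario$marker_mean, scenario$marker_cv)
    marker <- rlnorm(n, pm["meanlog"], pm["sdlog"])

    ## disjoint nuisance categories: cluster / border / singlet
    u <- runif(n)
    clustered <- u < scenario$cluster_fraction
    border <- !clustered &
      u < scenario$cluster_fraction + scenario$border_fraction
    if (sum(clustered) %% 2L == 1L)  # pairs only; flip one back to singlet
      clustered[which(clustered)[sum(clustered)]] <- FALSE

    cells <- data.frame(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      object_type = "neuron",
      field_id = NA_integer_, slot = NA_integer_,
      center_x_px = NA_real_, center_y_px = NA_real_,
      diameter_um = diameter,
      area_um2 = pi * (diameter / 2)^2,
      aspect = runif(n, 1.0, 1.3),
      theta = runif(n, 0, pi),
      is_neuron = TRUE,
      is_clustered = clustered,
      touches_border = border,
      ib4_status = ifelse(ib4_pos, "positive", "negative"),
      is_responder = responder,
      intensity_marker = marker,
      intensity_ib4 = ib4,
      intensity_baseline = baseline,
      intensity_stimulated = stimulated,
      stringsAsFactors = FALSE)

    if (layout)
      cells <- layout_population(cells, scenario, field)

    attr(cells, "scenario") <- scenario
    attr(cells, "field_spec") <- field
    class(cells) <- c("ground_truth", "data.frame")
    cells
  })
}

## place neurons (and add distractors) on a collision-free slot grid;
## runs inside the scenario RNG stream
layout_population <- function(cells, scenario, field) {
  pix <- field$pixel_size_um
  max_d_px <- max(scenario$diameter_range_pos, scenario$diameter_range_neg) /
    pix
  slot <- ceiling(max_d_px * 1.45)
  nx <- floor(field$width_px / slot)
  ny <- floor(field$height_px / slot)
  if (nx < 3 || ny < 3)
    stop("field too small for the configured soma diameters", call. = FALSE)
  interior <- expand.grid(ix = 2:(nx - 1), iy = 2:(ny - 1))
  edge <- rbind(data.frame(ix = 1:nx, iy = 1L, side = "top"),
                data.frame(ix = 1:nx, iy = ny, side = "bottom"),
                data.frame(ix = 1L, iy = 2:(ny - 1), side = "left"),
                data.frame(ix = nx, iy = 2:(ny - 1), side = "right"))

  singl <- which(!cells$is_clustered & !cells$touches_border)
  clust <- which(cells$is_clustered)
  bord <- which(cells$touches_border)
  pairs <- if (length(clust)) split(clust, rep(seq_len(length(clust) / 2),
                                               each = 2)) else list()

  n_distract <- ceiling(scenario$glia_density + scenario$debris_density)
  cap_int <- nrow(interior) - n_distract
  if (cap_int < 1)
    stop("distractor densities exceed the field capacity", call. = FALSE)
  n_fields <- max(ceiling((length(singl) + length(pairs)) / cap_int),
                  ceiling(length(bord) / nrow(edge)), 1L)

  ## interior slot bookings: one per singlet / cluster pair, field by field
  demand <- c(rep(list(NULL), length(singl)), pairs)
  units <- c(as.list(singl), pairs)
  unit_field <- rep(seq_len(n_fields), length.out = length(units))
  ## shuffle assignment so fields fill evenly but randomly
  unit_field <- sample(unit_field)

  slot_of <- integer(nrow(cells))
  half <- slot / 2
  place_xy <- function(ix, iy, jx, jy) {
    c(x = (ix - 1) * slot + half + jx, y = (iy - 1) * slot + half + jy)
  }

  for (f in seq_len(n_fields)) {
    iu <- which(unit_field == f)
    if (!length(iu)) next
    picks <- interior[sample.int(nrow(interior), length(iu)), , drop = FALSE]
    for (k in seq_along(iu)) {
      members <- units[[iu[k]]]
      ix <- picks$ix[k]; iy <- picks$iy[k]
      if (length(members) == 1L) {
        i <- members
        r_px <- cells$diameter_um[i] / 2 / pix
        room <- max(half - r_px - 2, 0)
        xy <- place_xy(ix, iy, runif(1, -room, room), runif(1, -room, room))
        cells$center_x_px[i] <- xy["x"]; cells$center_y_px[i] <- xy["y"]
      } else {
        ## touching pair along the slot diagonal (most room)
        i <- members[1]; j <- members[2]
        r1 <- cells$diameter_um[i] / 2 / pix
        r2 <- cells$diameter_um[j] / 2 / pix
        sep <- 0.92 * (r1 + r2)
        ang <- sample(c(pi / 4, 3 * pi / 4), 1) + runif(1, -0.15, 0.15)
        ux <- cos(ang); uy <- sin(ang)
        cxy <- place_xy(ix, iy, 0, 0)
        cells$center_x_px[i] <- cxy["x"] - ux * sep / 2
        cells$center_y_px[i] <- cxy["y"] - uy * sep / 2
        cells$center_x_px[j] <- cxy["x"] + ux * sep / 2
        cells$center_y_px[j] <- cxy["y"] + uy * sep / 2
      }
      cells$field_id[members] <- f
      cells$slot[members] <- (iy - 1) * nx + ix
    }
  }

  ## border neurons: centre on the field edge so the mask is cut
  if (length(bord)) {
    bf <- sample(rep(seq_len(n_fields), length.out = length(bord)))
    for (k in seq_along(bord)) {
      i <- bord[k]
      e <- edge[sample.int(nrow(edge), 1), ]
      along <- runif(1, -half / 2, half / 2)
      xy <- switch(as.character(e$side),
        top = c((e$ix - 1) * slot + half + along, 0),
        bottom = c((e$ix - 1) * slot + half + along, field$height_px - 1),
        left = c(0, (e$iy - 1) * slot + half + along),
        right = c(field$width_px - 1, (e$iy - 1) * slot + half + along))
      cells$center_x_px[i] <- xy[1]; cells$center_y_px[i] <- xy[2]
      cells$field_id[i] <- bf[k]
      cells$slot[i] <- NA_integer_
    }
  }

  ## distractors occupy interior slots not used by neurons in their field
  distract <- list()
  for (f in seq_len(n_fields)) {
    used <- stats::na.omit(cells$slot[cells$field_id == f & !is.na(cells$slot)])
    free <- setdiff((interior$iy - 1) * nx + interior$ix, used)
    n_g <- rpois(1, scenario$glia_density)
    n_d <- rpois(1, scenario$debris_density)
    take <- min(n_g + n_d, length(free))
    if (take == 0) next
    sl <- sample(free, take)
    n_g <- min(n_g, take); n_d <- take - n_g
    typ <- c(rep("glia", n_g), rep("debris", n_d))
    d_um <- c(runif(n_g, 25, 45), runif(n_d, 3, 8))
    ## glia: dim (pixel contrast 0.10-0.25 at 0.96 s reference exposure);
    ## debris: bright autofluorescent specks
    g_int <- field$background_level * runif(n_g, 0.10, 0.25) /
      (0.96 * field$gain * pix^2)
    marker_i <- c(g_int, runif(n_d, 1, 3))
    ix <- (sl - 1) %% nx + 1; iy <- (sl - 1) %/% nx + 1
    r_px <- d_um / 2 / pix
    room <- pmax(half - r_px - 2, 0)
    distract[[f]] <- data.frame(
      cell_id = sprintf("f%d_%s_%03d", f, typ, seq_len(take)),
      object_type = typ, field_id = f, slot = sl,
      center_x_px = (ix - 1) * slot + half + runif(take, -room, room),
      center_y_px = (iy - 1) * slot + half + runif(take, -room, room),
      diameter_um = d_um, area_um2 = pi * (d_um / 2)^2,
      aspect = runif(take, 1.0, 1.6), theta = runif(take, 0, pi),
      is_neuron = FALSE, is_clustered = FALSE, touches_border = FALSE,
      ib4_status = NA_character_, is_responder = FALSE,
      intensity_marker = marker_i, intensity_ib4 = 0,
      intensity_baseline = 0, intensity_stimulated = 0,
      stringsAsFactors = FALSE)
  }
  if (length(distract))
    cells <- rbind(cells, do.call(rbind, distract))
  cells
}

#' Flag ground-truth neurons that conform to the detection criteria
#'
#' A neuron counts as *eligible* for software detection when it is a singlet,
#' does not touch the field border, and its true geometry and staining
#' intensity conform to the object-identifier rules: true area within
#' `[area_min_um2, area_max_um2]`, aspect ratio within `aspect_ratio_max`,
#' and a predicted marker-channel pixel contrast of at least `contrast_min`
#' over the background. Detection-rate (recall) figures are quoted relative
#' to this set, mirroring how by-eye detection rates exclude clusters and
#' border-cut cells.
#'
#' @param truth a `ground_truth` table from [generate_population()].
#' @param params a [detection_params()].
#' @param field the [field_spec()] used for rendering.
#' @param exposure_s exposure time of the marker channel render.
#' @return Logical vector along `truth` rows.
#' @export
eligible_neurons <- function(truth, params = detection_params(),
                             field = attr(truth, "field_spec"),
                             exposure_s = 0.96) {
  stopifnot(inherits(field, "field_spec"))
  ## median pixel value of the hemispheric soma profile relative to the
  ## flat-equivalent level: 1.5 * sqrt(1 - u) at the median covered u
  med_factor <- 1.5 * sqrt(1 - 0.5)
  contrast <- truth$intensity_marker * med_factor * exposure_s *
    field$gain * field$pixel_size_um^2 / field$background_level
  truth$is_neuron & !truth$is_clustered & !truth$touches_border &
    truth$area_um2 >= params$area_min_um2 &
    truth$area_um2 <= params$area_max_um2 &
    truth$aspect <= params$aspect_ratio_max &
    contrast >= params$contrast_min
}
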