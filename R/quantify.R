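#' Exposure auto-selection policy
#'
#' The camera exposure is chosen automatically as the longest candidate for
#' which the number of saturated pixels stays within budget, with a hard
#' maximum of 0.96 s. The published budget is 1000 saturated pixels per
#' 100 um2 of evaluated area; note that at 10x magnification 100 um2 holds
#' far fewer than 1000 pixels, so the literal default can never be exceeded
#' per evaluated area — the budget is therefore configurable, and a per-field
#' absolute count mode (`budget_mode = "per_field"`) is provided as the
#' alternative reading.
#'
#' @param exposure_candidates candidate exposures in seconds, used in
#'   descending order.
#' @param exposure_max hard upper limit, seconds.
#' @param saturation_budget allowed saturated pixels per 100 um2 of evaluated
#'   area (`"per_area"`) or per field (`"per_field"`).
#' @param budget_mode how the budget is counted.
#' @param saturation_level camera counts at which a pixel is saturated
#'   (`2^bit_depth - 1`).
#' @return An object of class `exposure_policy`.
#' @export
exposure_policy <- function(exposure_candidates = c(0.96, 0.48, 0.24),
                            exposure_max = 0.96,
                            saturation_budget = 1000,
                            budget_mode = c("per_area", "per_field"),
                            saturation_level = 4095) {
  budget_mode <- match.arg(budget_mode)
  if (length(exposure_candidates) < 1)
    stop("exposure_candidates must not be empty", call. = FALSE)
  if (any(exposure_candidates <= 0) || any(exposure_candidates > exposure_max))
    stop("exposure candidates must be positive and <= exposure_max",
         call. = FALSE)
  if (saturation_budget < 0)
    stop("saturation_budget must be >= 0", call. = FALSE)
  p <- list(exposure_candidates = sort(exposure_candidates, decreasing = TRUE),
            exposure_max = exposure_max,
            saturation_budget = saturation_budget,
            budget_mode = budget_mode,
            saturation_level = saturation_level)
  class(p) <- "exposure_policy"
  p
}

#' Select the exposure time for a scene
#'
#' Given the same scene imaged at each candidate exposure, returns the
#' longest exposure whose saturated-pixel count stays within the policy
#' budget. If no candidate qualifies the shortest one is returned with a
#' warning.
#'
#' @param images named list of single-channel matrices; names are the
#'   exposure times in seconds (e.g. `"0.96"`).
#' @param policy an [exposure_policy()].
#' @param mask optional logical matrix restricting the evaluation to object
#'   pixels; saturation is counted (and, in `"per_area"` mode, the area
#'   measured) inside it.
#' @param pixel_size_um pixel size used to convert the evaluated area to um2.
#' @return The selected exposure in seconds, with the per-candidate
#'   saturation counts attached as attribute `"diagnostics"`.
#' @export
select_exposure <- function(images, policy = exposure_policy(), mask = NULL,
                            pixel_size_um = 0.645) {
  stopifnot(inherits(policy, "exposure_policy"))
  if (length(images) == 0 || is.null(names(images)))
    stop("images must be a named list keyed by exposure seconds",
         call. = FALSE)
  exps <- as.numeric(names(images))
  if (anyNA(exps)) stop("image names must be numeric exposures", call. = FALSE)
  cand <- policy$exposure_candidates
  if (!all(cand %in% exps))
    stop("missing renders for candidate exposures: ",
         paste(setdiff(cand, exps), collapse = ", "), call. = FALSE)

  diag <- data.frame(exposure_s = cand, saturated = NA_real_,
                     budget_value = NA_real_, ok = NA)
  for (i in seq_along(cand)) {
    img <- images[[match(cand[i], exps)]]
    px <- if (is.null(mask)) img else img[mask]
    n_sat <- sum(px >= policy$saturation_level)
    if (policy$budget_mode == "per_area") {
      n_eval <- if (is.null(mask)) length(img) else sum(mask)
      area_100um2 <- n_eval * pixel_size_um^2 / 100
      val <- if (area_100um2 > 0) n_sat / area_100um2 else 0
    } else {
      val <- n_sat
    }
    diag$saturated[i] <- n_sat
    diag$budget_value[i] <- val
    diag$ok[i] <- val <= policy$saturation_budget
  }
  sel <- if (any(diag$ok)) cand[which(diag$ok)[1]] else {
    warning("saturation budget unreachable; using shortest exposure",
            call. = FALSE)
    cand[length(cand)]
  }
  attr(sel, "diagnostics") <- diag
  sel
}

#' Measure one cell on one channel
#'
#' Integrates the background-subtracted pixel values over the cell mask and
#' normalizes by the cell area and the exposure time:
#' `normalized = raw / area_um2 / exposure_s / gain`. The raw integral is
#' clamped at zero so normalized intensities are never negative.
#'
#' @param mask logical matrix, `TRUE` on the cell's pixels.
#' @param image single-channel matrix of the same size.
#' @param exposure_s exposure time, seconds (> 0).
#' @param background scalar background level subtracted per pixel.
#' @param area_um2 cell area; defaults to the mask area at `pixel_size_um`.
#' @param pixel_size_um pixel size, um.
#' @param gain detector gain (counts per intensity x um2 x s); leave at 1 to
#'   express intensities in camera-count units.
#' @return List with `raw` (integrated background-subtracted counts) and
#'   `normalized`.
#' @export
measure_cell <- function(mask, image, exposure_s, background,
                         area_um2 = NULL, pixel_size_um = 0.645, gain = 1) {
  if (!is.matrix(mask) || !is.matrix(image) ||
      !all(dim(mask) == dim(image)))
    stop("mask and image must be matrices of identical size", call. = FALSE)
  if (exposure_s <= 0) stop("exposure_s must be > 0", call. = FALSE)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (is.null(area_um2)) area_um2 <- sum(mask) * pixel_size_um^2
  raw <- max(0, sum(image[mask] - background))
  list(raw = raw, normalized = raw / area_um2 / exposure_s / gain)
}

#' Measure all accepted cells of a segmented field
#'
#' Applies [measure_cell()] to every accepted object on each measurement
#' channel, using the object's own local background estimate from
#' segmentation. The segmentation mask from the marker channel is reused on
#' every channel, so normalized intensities are comparable across channels
#' and exposures.
#'
#' @param objects a filtered `segmented_objects` table (from
#'   [segment_field()] or [filter_neurons()]).
#' @param images named list of channel matrices.
#' @param exposure_s exposure used for those images, seconds.
#' @param condition condition label recorded for every cell.
#' @param culture optional culture/well identifier.
#' @param field_id optional field identifier used in cell ids.
#' @param gain detector gain passed to [measure_cell()].
#' @param include_rejected also measure rejected objects (kept flagged).
#' @return A `data.frame` of cell records: ids, condition, geometry, and for
#'   every channel `raw_<channel>` and `intensity_<channel>`.
#' @export
measure_field <- function(objects, images, exposure_s,
                          condition = "control", culture = NA,
                          field_id = 1L, gain = 1,
                          include_rejected = FALSE) {
  lab <- attr(objects, "labels")
  params <- attr(objects, "params")
  if (is.null(lab) || is.null(params))
    stop("objects must come from detect_objects()", call. = FALSE)
  if (is.null(objects$accepted))
    stop("objects must be filtered first; see filter_neurons()",
         call. = FALSE)
  rows <- if (include_rejected) seq_len(nrow(objects)) else
    which(objects$accepted)
  rec <- objects[rows, c("label", "area_um2", "equivalent_diameter_um",
                         "centroid_x", "centroid_y", "accepted",
                         "rejection_reasons")]
  rec <- cbind(data.frame(cell_id = sprintf("f%03d_obj%04d", field_id,
                                            objects$label[rows]),
                          condition = condition, culture = culture,
                          field_id = field_id,
                          exposure_s = exposure_s),
               rec)
  for (ch in names(images)) {
    raw <- numeric(length(rows)); norm <- numeric(length(rows))
    for (k in seq_along(rows)) {
      i <- rows[k]
      m <- lab == objects$label[i]
      v <- measure_cell(m, images[[ch]], exposure_s,
                        background = objects$local_background[i],
                        area_um2 = objects$area_um2[i],
                        pixel_size_um = params$pixel_size_um, gain = gain)
      raw[k] <- v$raw; norm[k] <- v$normalized
    }
    rec[[paste0("raw_", ch)]] <- raw
    rec[[paste0("intensity_", ch)]] <- norm
  }
  rownames(rec) <- NULL
  rec
}

#' Rescale intensities to a control-condition mean of one
#'
#' Divides every `intensity_*` column by the mean of that column over the
#' control condition, so the control mean becomes exactly 1 and treatment
#' intensities read as fold-of-control. Applying the operation twice is a
#' no-op.
#'
#' @param cells a cell table with a `condition` column and one or more
#'   `intensity_<channel>` columns.
#' @param control_condition condition label of the control.
#' @param channels channels to rescale; default all `intensity_*` columns.
#' @param condition_col name of the condition column.
#' @return The rescaled table; scaling factors are attached as attribute
#'   `"control_means"`.
#' @export
normalize_to_control <- function(cells, control_condition = "control",
                                 channels = NULL,
                                 condition_col = "condition") {
  if (!condition_col %in% names(cells))
    stop("no '", condition_col, "' column in cells", call. = FALSE)
  ctrl <- cells[[condition_col]] == control_condition
  if (!any(ctrl)) stop("control condition '", control_condition,
                       "' is empty", call. = FALSE)
  cols <- if (is.null(channels)) grep("^intensity_", names(cells),
                                      value = TRUE) else
    paste0("intensity_", channels)
  if (!length(cols)) stop("no intensity columns to normalize", call. = FALSE)
  means <- numeric(0)
  for (cl in cols) {
    m <- mean(cells[[cl]][ctrl])
    if (!is.finite(m) || m == 0)
      stop("control mean of ", cl, " is zero or undefined", call. = FALSE)
    cells[[cl]] <- cells[[cl]] / m
    means[cl] <- m
  }
  attr(cells, "control_means") <- means
  cells
}
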