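#' Assemble and validate a pipeline run configuration
#'
#' A run configuration selects a contiguous subset of the pipeline stages
#' (`simulate`, `segment`, `quantify`, `classify`, `wells`) and carries the
#' stage parameters: the synthetic-culture scenario, field spec, detection
#' parameters, classification settings and virtual-well settings. It can be
#' built from R lists or read from a YAML file. Unknown keys are rejected,
#' listing the offending names.
#'
#' @param config named list, or path to a YAML file with the same structure.
#'   Recognized keys: `stages`, `seed`, `conditions`, `exposure_s`,
#'   `scenario`, `field`, `detection`, `classify`, `wells`, `input`,
#'   `log_level`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  known <- c("stages", "seed", "conditions", "exposure_s", "scenario",
             "field", "detection", "classify", "wells", "input", "log_level")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  all_stages <- c("simulate", "segment", "quantify", "classify", "wells")
  stages <- config$stages %||% all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "), call. = FALSE)
  idx <- sort(match(stages, all_stages))
  if (length(idx) && !all(diff(idx) == 1))
    stop("stages must form a contiguous subset of: ",
         paste(all_stages, collapse = " -> "), call. = FALSE)

  cfg <- list(
    stages = all_stages[idx],
    seed = config$seed %||% 1L,
    conditions = config$conditions %||% c("control", "stimulated"),
    exposure_s = config$exposure_s %||% 0.96,
    scenario = do.call(scenario_config, config$scenario %||% list()),
    field = do.call(field_spec, config$field %||% list()),
    detection = do.call(detection_params, config$detection %||% list()),
    classify = utils::modifyList(list(channel = "perk", n_bins = 100,
                                      scale = "log", min_cells = 250),
                                 config$classify %||% list()),
    wells = utils::modifyList(list(n_per_well = c(250, 1000, 5000),
                                   n_wells = 2000, replacement = FALSE,
                                   channel = "perk", k = 2),
                              config$wells %||% list()),
    input = config$input %||% list(),
    log_level = config$log_level %||% "info")
  if (!all(cfg$conditions %in% c("control", "stimulated")))
    stop("conditions must be a subset of control/stimulated", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the quantification pipeline
#'
#' Executes the configured stages in order — simulate a ground-truthed
#' culture, render and segment the marker channel, quantify accepted cells
#' on every channel and condition, normalize to the control mean, classify
#' responders by histogram intersection, and run the virtual-well
#' sensitivity analysis — writing one CSV per artifact plus a JSON manifest
#' with versions, seeds, parameters and file checksums. A rerun with the
#' same configuration produces byte-identical tables.
#'
#' Stages later in the chain can run alone when `config$input$cells` points
#' to a previously written cell table; a missing upstream artifact is an
#' error naming the required stage.
#'
#' @param config a [run_config()] (or list / YAML path coerced by it).
#' @param out_dir output directory.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  note <- function(...) if (config$log_level != "quiet")
    message(sprintf(...))
  artifacts <- character()
  keep <- function(path) artifacts <<- c(artifacts, path)

  pop <- NULL; cells <- NULL; rendered <- list(); objects_all <- NULL

  if ("simulate" %in% config$stages) {
    note("simulate: %d cells", config$scenario$n_cells)
    sc <- config$scenario
    sc$seed <- sc$seed %||% config$seed
    need_layout <- any(c("segment", "quantify") %in% config$stages)
    pop <- generate_population(sc, config$field, layout = need_layout)
    p <- file.path(out_dir, "population.csv")
    utils::write.csv(as.data.frame(pop), p, row.names = FALSE)
    keep(p)
  }

  if ("segment" %in% config$stages) {
    if (is.null(pop))
      stop("segment requires the simulate stage (no population available)",
           call. = FALSE)
    for (cond in config$conditions) {
      rendered[[cond]] <- render_fields(
        pop, config$field, config$exposure_s,
        condition = if (cond == "control") "baseline" else "stimulated",
        noise = TRUE, seed = config$seed)
    }
    ref <- rendered[[config$conditions[1]]]
    objects_all <- lapply(ref, function(f)
      segment_field(f$images$marker, config$detection))
    n_acc <- sum(vapply(objects_all, function(o) sum(o$accepted), numeric(1)))
    note("segment: %d fields, %d accepted objects", length(ref), n_acc)
    obj_df <- do.call(rbind, lapply(seq_along(objects_all), function(i)
      cbind(field_id = ref[[i]]$field_id,
            as.data.frame(objects_all[[i]]))))
    p <- file.path(out_dir, "objects.csv")
    utils::write.csv(obj_df, p, row.names = FALSE)
    keep(p)
  }

  if ("quantify" %in% config$stages) {
    if (is.null(objects_all))
      stop("quantify requires the segment stage (no objects available)",
           call. = FALSE)
    recs <- list()
    for (cond in config$conditions) {
      flds <- rendered[[cond]]
      for (i in seq_along(flds)) {
        recs[[paste(cond, i)]] <- measure_field(
          objects_all[[i]], flds[[i]]$images,
          exposure_s = config$exposure_s, condition = cond,
          culture = sprintf("culture_%s", cond),
          field_id = flds[[i]]$field_id, gain = config$field$gain)
      }
    }
    cells <- do.call(rbind, recs)
    rownames(cells) <- NULL
    if ("control" %in% cells$condition)
      cells <- normalize_to_control(cells, "control",
                                    channels = config$classify$channel)
    p <- file.path(out_dir, "cells.csv")
    write_cells(cells, p)
    keep(p)
    note("quantify: %d cell records", nrow(cells))
  }

  if (is.null(cells) && length(config$input$cells %||% character())) {
    if (!file.exists(config$input$cells))
      stop("input cell table not found: ", config$input$cells, call. = FALSE)
    cells <- read_cells(config$input$cells)
  }

  if ("classify" %in% config$stages) {
    if (is.null(cells))
      stop("classify requires the quantify stage or input$cells",
           call. = FALSE)
    cl <- config$classify
    res <- classify_responders(cells, "control", "stimulated",
                               channel = cl$channel, n_bins = cl$n_bins,
                               scale = cl$scale, min_cells = cl$min_cells)
    note("classify: cutoff %.4g, %.1f%% responders", res$cutoff,
         100 * res$fraction)
    p <- file.path(out_dir, "responders.csv")
    utils::write.csv(res$labels, p, row.names = FALSE)
    keep(p)
    p2 <- file.path(out_dir, "cutoff.csv")
    utils::write.csv(data.frame(
      cutoff = res$cutoff, side = res$side, diagnostic = res$diagnostic,
      fraction_positive_test = res$fraction_positive_test,
      fraction_positive_control = res$fraction_positive_control),
      p2, row.names = FALSE)
    keep(p2)
  }

  if ("wells" %in% config$stages) {
    if (is.null(cells))
      stop("wells requires the quantify stage or input$cells", call. = FALSE)
    w <- config$wells
    col <- paste0("intensity_", w$channel)
    pool <- cells[[col]][cells$condition == "control"]
    if (!length(pool)) pool <- cells[[col]]
    rows <- lapply(w$n_per_well[w$n_per_well <= length(pool) |
                                  w$replacement], function(n) {
      vw <- sample_virtual_wells(pool, n, w$n_wells, w$replacement,
                                 seed = config$seed + n)
      de <- detectable_effect(vw, k = w$k)
      data.frame(n_per_well = n, n_wells = w$n_wells,
                 mean_of_means = vw$mean_of_means,
                 sd_of_means = vw$sd_of_means,
                 sd_closed_form = vw$sd_closed_form,
                 detectable_effect_percent = de$whole_culture_percent)
    })
    wt <- do.call(rbind, rows)
    p <- file.path(out_dir, "wells.csv")
    utils::write.csv(wt, p, row.names = FALSE)
    keep(p)
    note("wells: %d well sizes", nrow(wt))
  }

  manifest <- list(
    package = "quamr",
    version = as.character(utils::packageVersion("quamr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = "run",  # timestamps omitted so reruns are byte-identical
    seed = config$seed,
    stages = config$stages,
    parameters = list(
      scenario = unclass(config$scenario),
      field = unclass(config$field),
      detection = unclass(config$detection),
      exposure_s = config$exposure_s,
      classify = config$classify, wells = config$wells),
    files = lapply(stats::setNames(artifacts, basename(artifacts)),
                   function(p) list(md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a cell table CSV
#'
#' Cell tables are plain CSV with one row per cell and documented columns:
#' `cell_id`, `condition`, `culture`, `field_id`, `exposure_s`, geometry
#' (`area_um2`, `equivalent_diameter_um`, centroid), acceptance flags, and
#' per channel `raw_<channel>` / `intensity_<channel>`.
#'
#' @param cells cell table.
#' @param path CSV path.
#' @return `write_cells` invisibly returns the path; `read_cells` returns
#'   the `data.frame`.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
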