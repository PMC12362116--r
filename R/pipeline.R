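#' Validate a sensitivity-record table
#'
#' Type- and range-checks a table of microperimetry records before it enters
#' the pipeline: required columns present, sensitivities inside the device
#' range, non-negative visit months, scotoma rows recorded as 0 dB, and no
#' duplicated (participant, visit, locus) keys. Every violation is reported
#' with its row number and field.
#'
#' @param records Data frame or path to a CSV with columns
#'   `participant_id`, `visit_month`, `locus_id`, `sensitivity_db`,
#'   `scotoma` (and optionally `axis`, `axis_orientation`).
#' @param db_range Allowed sensitivity range (default `c(0, 20)`).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_records <- function(records, db_range = c(0, 20)) {
  if (is.character(records)) records <- utils::read.csv(records, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records))
  need <- c("participant_id", "visit_month", "locus_id", "sensitivity_db", "scotoma")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (is.character(records$scotoma))
    records$scotoma <- toupper(records$scotoma) %in% c("TRUE", "T", "1")

  problems <- character()
  bad <- function(rows, field, what) {
    if (length(rows))
      sprintf("row %d: %s %s", rows, field, what)
    else character()
  }
  problems <- c(problems,
    bad(which(!is.finite(records$sensitivity_db)), "sensitivity_db", "is not numeric"),
    bad(which(records$sensitivity_db < db_range[1] |
                records$sensitivity_db > db_range[2]), "sensitivity_db",
        sprintf("outside [%g, %g]", db_range[1], db_range[2])),
    bad(which(!is.finite(records$visit_month) | records$visit_month < 0),
        "visit_month", "must be >= 0"),
    bad(which(records$scotoma & records$sensitivity_db != 0), "scotoma",
        "flagged but sensitivity_db != 0"))
  key <- paste(records$participant_id, records$visit_month, records$locus_id)
  dup <- which(duplicated(key))
  problems <- c(problems,
                bad(dup, "(participant_id, visit_month, locus_id)", "is duplicated"))
  if (length(problems))
    stop(errorCondition(
      paste0("record validation failed:\n  ", paste(problems, collapse = "\n  ")),
      class = c("perisense_validation_error", "error", "condition")))
  invisible(records)
}

#' Pipeline configuration
#'
#' Reads (or builds) the single configuration object that drives
#' [run_pipeline()]. Configuration may come from a YAML/JSON file or be
#' given as a list; unspecified keys take the defaults below. All
#' randomness in a run flows from `seed`.
#'
#' @param config Path to a YAML (or JSON) file, or a named list.
#' @return A list of class `pipeline_config` with keys `seed`, `out_dir`,
#'   `simulate` (NULL or a list of [simulation_config()] overrides),
#'   `records_csv`, `masks_dir`, `grid` (arm lengths and spacing),
#'   `exclude_intralesional`, `loess` (span, degree, n_grid, stratify),
#'   `model` (knot_range, knot_step, foveal_covariate).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    out_dir = "perisense_out",
    simulate = NULL,
    records_csv = NULL,
    masks_dir = NULL,
    grid = list(temporal_deg = 15, superior_deg = 12, inferior_deg = 12,
                spacing_deg = 1),
    exclude_intralesional = TRUE,
    loess = list(span = 0.5, degree = 1, n_grid = 200,
                 stratify = c("none", "visit")),
    model = list(knot_range = c(0.25, 8), knot_step = 0.25,
                 foveal_covariate = FALSE))
  cfg <- utils::modifyList(defaults, config)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full simulate-annotate-smooth-fit pipeline
#'
#' Orchestrates the analysis end to end: obtain records and masks (either by
#' simulation or from `records_csv` + `masks_dir`), validate, annotate with
#' per-visit GA distances, draw smoothed curves, fit the segmented mixed
#' model, and write every artifact plus a run manifest (config echo, seed,
#' package version, and row counts after each filtering step) to `out_dir`.
#' Runs are deterministic given the same config and inputs; partial outputs
#' are removed if a stage fails.
#'
#' @param config A [pipeline_config()], a list of overrides, or a YAML path.
#' @return Invisibly, a list with `annotated`, `curves`, `fit`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  if (!is.null(cfg$records_csv) && normalizePath(dirname(cfg$records_csv), mustWork = FALSE) ==
      normalizePath(out, mustWork = FALSE))
    stop("out_dir must be distinct from the input directory")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  started <- list.files(out, full.names = TRUE)
  on_fail <- function(e) {
    new <- setdiff(list.files(out, full.names = TRUE), started)
    unlink(new, recursive = TRUE)
    stop(e)
  }
  tryCatch(run_pipeline_impl(cfg, out), error = on_fail)
}

run_pipeline_impl <- function(cfg, out) {
  grid <- do.call(build_t_grid, cfg$grid)
  counts <- list()

  if (!is.null(cfg$simulate) || is.null(cfg$records_csv)) {
    sim_args <- if (is.list(cfg$simulate)) cfg$simulate else list()
    sim_args$rng_seed <- cfg$seed
    sim_args$grid <- grid
    scfg <- do.call(simulation_config, sim_args)
    cohort <- simulate_cohort(scfg)
    records <- cohort$records
    masks <- cohort$masks
    counts$simulated <- nrow(records)
    write_records_csv(records, file.path(out, "records.csv"))
    mask_dir <- file.path(out, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (k in names(masks))
      write_mask(masks[[k]], file.path(mask_dir, paste0(gsub("[@]", "_", k), ".png")))
  } else {
    records <- utils::read.csv(cfg$records_csv, stringsAsFactors = FALSE)
    counts$simulated <- NA
    mask_files <- list.files(cfg$masks_dir, pattern = "\\.(png|txt)$",
                             full.names = TRUE)
    masks <- lapply(mask_files, read_mask)
  }

  records <- validate_records(records)
  counts$validated <- nrow(records)
  message("validated ", counts$validated, " records")

  annotated <- annotate_dataset(records, masks, grid)
  counts$annotated <- nrow(annotated)
  counts$extralesional <- sum(!annotated$inside_ga)
  message("annotated ", counts$annotated, " points (",
          counts$extralesional, " extralesional)")
  write_annotated_csv(annotated, file.path(out, "annotated.csv"))

  for (strat in cfg$loess$stratify) {
    cv <- curves_by_stratum(annotated, stratify_by = strat,
                            span = cfg$loess$span, degree = cfg$loess$degree,
                            n_grid = cfg$loess$n_grid)
    write_curves_csv(cv, file.path(out, sprintf("curves_%s.csv", strat)))
  }

  model_input <- if (cfg$exclude_intralesional)
    annotated[!annotated$inside_ga, , drop = FALSE] else annotated
  counts$modeled <- nrow(model_input)
  fit <- fit_segmented(model_input,
                       foveal_covariate = isTRUE(cfg$model$foveal_covariate),
                       knot_range = as.numeric(cfg$model$knot_range),
                       knot_step = cfg$model$knot_step,
                       exclude_intralesional = cfg$exclude_intralesional)
  write_fit_report(fit, file.path(out, "fit_report.csv"),
                   file.path(out, "fit_report.json"))
  pc <- predicted_curves(fit, months = sort(unique(annotated$visit_month)))
  utils::write.csv(pc, file.path(out, "predicted_curves.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("perisense")),
    seed = cfg$seed,
    config = unclass(cfg)[setdiff(names(cfg), "grid")],
    grid = cfg$grid,
    counts = counts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(annotated = annotated, fit = fit, manifest = manifest,
                 out_dir = out))
}
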