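# Metadata schema, readers/writers, run configuration and the
# end-to-end orchestrator.
#
# The assay's full per-target metadata schema is proprietary-sized (tens
# of fields); this package validates a documented minimal core and
# preserves every unknown column as an extension field.

.META_REQUIRED <- c("experiment_id", "target_id", "treatment", "dose",
                    "dose_units", "group_role", "assay_kind")

#' Read and validate an experiment metadata CSV
#'
#' One row per target (a micro-tumor or a slice). Required columns:
#' `experiment_id`, `target_id`, `treatment`, `dose`, `dose_units`,
#' `group_role` (`negative_control` / `positive_control` / `treated`),
#' `assay_kind` (`tumor_toxicity` / `obsc_toxicity`). Any other columns
#' are preserved as extension fields. Validation rejects duplicate target
#' ids, negative doses, non-zero-dose negative controls, and more than
#' nine non-control dose groups.
#'
#' @param path CSV file path.
#' @return data frame of target rows with attribute `dose_ladder` (sorted
#'   unique doses) and `extension_fields` (names of preserved extra
#'   columns).
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.META_REQUIRED, names(df))
  if (length(miss)) {
    stop("missing required metadata columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$target_id)) stop("duplicate target_id values")
  if (any(df$dose < 0)) stop("negative doses")
  if (any(df$group_role == "negative_control" & df$dose != 0)) {
    stop("negative controls must have dose 0")
  }
  treated_doses <- sort(unique(df$dose[df$group_role == "treated"]))
  if (length(treated_doses) > 9L) {
    stop("at most nine non-control dose groups are supported (found ",
         length(treated_doses), ")")
  }
  structure(df,
            dose_ladder = sort(unique(df$dose)),
            extension_fields = setdiff(names(df), .META_REQUIRED))
}

#' Write / read a survival record CSV
#'
#' The interchange schema of the pipeline: columns `target_id`, `dose`,
#' `dose_units`, `group_role`, `survival_pct`.
#'
#' @param data data frame containing at least these columns.
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_survival_csv <- function(data, path) {
  cols <- c("target_id", "dose", "dose_units", "group_role", "survival_pct")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("target_id", "dose", "dose_units", "group_role", "survival_pct")
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Run configuration with assay defaults
#'
#' Collects every tunable constant of the pipeline, defaulting to the
#' assay's standard values, so every run is reproducible and auditable
#' from its configuration alone.
#'
#' @param grid_rows,grid_cols well grid dimensions.
#' @param thresholds heuristic/plausibility thresholds
#'   ([heuristic_thresholds()]).
#' @param weights DSS window weights ([dss_weights()]).
#' @param bp_alpha significance level of the biphasic ANOVA.
#' @param seed integer seed for all stochastic steps.
#' @param normalization_mode `"d4_only"` (default) or `"d4_over_d1"`
#'   (per-tumor baseline ratio before control normalization).
#' @param tga_use_fitted read TGA/IK from the fitted curve (default) or
#'   observed means.
#' @param n_starts optimizer starts per model fit.
#' @return a `run_config` list.
#' @export
run_config <- function(grid_rows = 2L, grid_cols = 3L,
                       thresholds = heuristic_thresholds(),
                       weights = dss_weights(), bp_alpha = 0.05,
                       seed = 1L,
                       normalization_mode = c("d4_only", "d4_over_d1"),
                       tga_use_fitted = TRUE, n_starts = 5L) {
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(grid_rows >= 1, grid_cols >= 1, bp_alpha > 0, bp_alpha < 1,
            abs(sum(weights) - 100) < 1e-9)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 thresholds = thresholds, weights = weights,
                 bp_alpha = bp_alpha, seed = as.integer(seed),
                 normalization_mode = normalization_mode,
                 tga_use_fitted = isTRUE(tga_use_fitted),
                 n_starts = as.integer(n_starts)),
            class = "run_config")
}

#' Save / load a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (load).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$weights <- as.list(out$weights)     # keep names through YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(grid_rows = raw$grid_rows, grid_cols = raw$grid_cols,
             thresholds = do.call(heuristic_thresholds, raw$thresholds),
             weights = unlist(raw$weights), bp_alpha = raw$bp_alpha,
             seed = raw$seed, normalization_mode = raw$normalization_mode,
             tga_use_fitted = raw$tga_use_fitted, n_starts = raw$n_starts)
}

#' Serialize a selected model to JSON
#'
#' Family, estimates, fixed parameters, fit statistics, category and the
#' thresholds used — the audit record of one model selection.
#'
#' @param fit an `obsc_drm` fit (ideally from [select_drm()]).
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "obsc_drm"))
  out <- list(family = fit$family, estimates = as.list(fit$coef),
              fixed = as.list(fit$fixed), rss = fit$rss, n = fit$n,
              p = fit$p, aic = fit$aic, lof = fit$lof, cc = fit$cc,
              plausible = fit$plausible, category = fit$category,
              thresholds = fit$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run a paired experiment end to end
#'
#' From replicate survival data (or raw signals) to the Drug Sensitivity
#' Score: normalizes raw signals when needed, selects a dose-response
#' model for the tumor and the slice response, computes the eleven
#' windows and the DSS, and (optionally) writes the full result bundle —
#' survival CSVs, model JSONs, DSS JSON, waterfall CSV and a log — to a
#' directory. Fully deterministic given the configuration seed.
#'
#' @param tumor_data,obsc_data data frames with `dose` and either
#'   `survival_pct` (already normalized) or `raw_signal` plus
#'   `group_role` (normalized here via [tumor_survival()] /
#'   [obsc_survival()]).
#' @param config a [run_config()].
#' @param out_dir optional output directory for the result bundle.
#' @return list with `tumor_fit`, `obsc_fit`, `dss`, `config`, and
#'   `paths` (when written).
#' @export
run_experiment <- function(tumor_data, obsc_data, config = run_config(),
                           out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  norm <- function(d, role) {
    if ("survival_pct" %in% names(d)) return(d)
    if (!"raw_signal" %in% names(d)) {
      stop(role, " data needs survival_pct or raw_signal [stage: survival]")
    }
    if (role == "tumor") tumor_survival(d) else obsc_survival(d)
  }
  tumor <- norm(tumor_data, "tumor")
  obsc <- norm(obsc_data, "obsc")

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(what, " stage failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tumor_fit <- stage("tumor model selection",
    select_drm(survival_pct ~ dose, tumor, thresholds = config$thresholds,
               n_starts = config$n_starts, seed = config$seed))
  obsc_fit <- stage("slice model selection",
    select_drm(survival_pct ~ dose, obsc, thresholds = config$thresholds,
               n_starts = config$n_starts, seed = config$seed + 500L))
  dss <- stage("DSS",
    dss_score(tumor_fit, obsc_fit, tumor_data = tumor,
              max_dose = max(tumor$dose), weights = config$weights,
              alpha = config$bp_alpha,
              tga_use_fitted = config$tga_use_fitted))

  out <- list(tumor_fit = tumor_fit, obsc_fit = obsc_fit, dss = dss,
              tumor_data = tumor, obsc_data = obsc, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(tumor_survival = file.path(out_dir, "tumor_survival.csv"),
               obsc_survival = file.path(out_dir, "obsc_survival.csv"),
               tumor_model = file.path(out_dir, "tumor_model.json"),
               obsc_model = file.path(out_dir, "obsc_model.json"),
               dss = file.path(out_dir, "dss.json"),
               waterfall = file.path(out_dir, "waterfall.csv"),
               log = file.path(out_dir, "run_log.txt"))
    if (all(c("target_id", "dose_units") %in% names(tumor))) {
      write_survival_csv(tumor, paths[["tumor_survival"]])
    }
    if (all(c("target_id", "dose_units") %in% names(obsc))) {
      write_survival_csv(obsc, paths[["obsc_survival"]])
    }
    write_model_json(tumor_fit, paths[["tumor_model"]])
    write_model_json(obsc_fit, paths[["obsc_model"]])
    jsonlite::write_json(
      list(windows = as.list(dss$windows), weights = as.list(dss$weights),
           contributions = as.list(dss$contributions),
           undefined = dss$undefined, total = dss$total),
      paths[["dss"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(dss_waterfall(dss), paths[["waterfall"]],
                     row.names = FALSE)
    log <- c(
      sprintf("category (tumor): %s", tumor_fit$category),
      sprintf("category (slice): %s", obsc_fit$category),
      "tumor candidate ranking:",
      utils::capture.output(print(tumor_fit$candidates)),
      "slice candidate ranking:",
      utils::capture.output(print(obsc_fit$candidates)),
      sprintf("undefined windows: %s",
              paste(dss$undefined, collapse = ", ")),
      sprintf("total DSS: %.4f", dss$total))
    writeLines(log, paths[["log"]])
    out$paths <- paths
  }
  out
}

#' Validate automated survival results against manual measurements
#'
#' Matches automated and manual per-target percent-survival tables on
#' `target_id`, computes the Bland-Altman agreement summary
#' ([bland_altman()]) and flags every target whose absolute difference
#' exceeds the agreement threshold (10 % survival by default).
#'
#' @param auto,manual data frames with columns `target_id` and
#'   `survival_pct` (identical id sets).
#' @param threshold agreement threshold, percent survival.
#' @return list with `agreement` (a `bland_altman`), `n_within`,
#'   `n_outside`, and `report` (per-target table with `within` flags).
#' @export
validate_against_manual <- function(auto, manual, threshold = 10) {
  stopifnot(all(c("target_id", "survival_pct") %in% names(auto)),
            all(c("target_id", "survival_pct") %in% names(manual)))
  if (!setequal(auto$target_id, manual$target_id) ||
      anyDuplicated(auto$target_id) || anyDuplicated(manual$target_id)) {
    stop("target ids must match one-to-one")
  }
  m <- manual[match(auto$target_id, manual$target_id), ]
  ba <- bland_altman(auto$survival_pct, m$survival_pct,
                     threshold = threshold)
  report <- data.frame(target_id = auto$target_id,
                       auto = auto$survival_pct,
                       manual = m$survival_pct,
                       difference = auto$survival_pct - m$survival_pct)
  report$within <- abs(report$difference) <= threshold
  list(agreement = ba, n_within = sum(report$within),
       n_outside = sum(!report$within), report = report)
}
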