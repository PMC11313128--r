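#' Run the full simulate-filter-estimate-design pipeline
#'
#' Orchestrates the package end to end: generate (or load) multilevel
#' observation data, apply the two-valid-day inclusion filter, estimate
#' per-year-group ICCs, estimate and pool the cluster and individual
#' autocorrelations, and size the candidate trial designs. Every stage
#' writes its inputs/outputs as CSV or JSON into `out_dir`, and progress
#' (row counts, rows removed by the valid-day filter, schools removed by
#' the minimum-pupil filter, convergence flags) is logged via `message()`.
#' A fixed seed gives byte-identical outputs. If the design block supplies
#' `icc`, `cac` and `iac` directly and no simulation/data block is present,
#' the estimation stages are skipped.
#'
#' @param config A named list, or path to a YAML file, with optional blocks
#'   `simulation` (arguments for [sim_config()]), `estimation` (`outcome`,
#'   `stratify_by_gender`, `min_valid_days`, `include_study`),
#'   `autocorrelation` (`min_pupils`, `method`, `bin_by_followup`),
#'   `design` (`delta`, `alpha`, `power`, `m`, `steps`, `cac`, `iac`,
#'   `icc`, `icc_upper`, `sd_total`), a `paths` block (`data` to load an
#'   existing observation CSV), and a global `seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with elements `data`, `icc`, `icc_overall`,
#'   `autocorrelation_records`, `autocorrelation_pooled`, `design` (those
#'   produced), plus `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log <- function(stage, ...) message("[", stage, "] ", ...)
  result <- list(out_dir = out_dir)

  est_cfg <- config$estimation %||% list()
  out_col <- est_cfg$outcome %||% "mvpa_weekday"
  design_cfg <- config$design %||% list()
  user_params <- !is.null(design_cfg$icc) && !is.null(design_cfg$cac) &&
    !is.null(design_cfg$iac) && !is.null(design_cfg$sd_total)
  have_data_source <- !is.null(config$simulation) ||
    !is.null(config$paths$data)

  data <- NULL
  if (have_data_source) {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      scfg <- do.call(sim_config, sim_args)
      data <- generate_population(scfg)
      log("simulate", nrow(data), " observation rows (seed ", scfg$seed, ")")
    } else {
      data <- read_observations(config$paths$data)
      log("load", nrow(data), " observation rows from ", config$paths$data)
    }
    min_days <- est_cfg$min_valid_days %||% 2
    data <- withCallingHandlers(
      filter_valid(data, min_days),
      message = function(m) invokeRestart("muffleMessage")
    )
    log("filter", attr(data, "n_removed"), " row(s) removed by the ",
      min_days, "-valid-day rule; ", nrow(data), " retained")
    write_observations(data, file.path(out_dir, "data.csv"))
    result$data <- data
  }

  run_estimation <- !is.null(data) && !user_params
  if (run_estimation) {
    icc_tab <- tryCatch(
      estimate_iccs(data, out_col,
        stratify_by_gender = isTRUE(est_cfg$stratify_by_gender),
        include_study = isTRUE(est_cfg$include_study)
      ),
      error = function(e) stop("stage 'icc' failed: ", conditionMessage(e),
        call. = FALSE)
    )
    overall_vc <- fit_variance_components(data, out_col)
    overall <- icc_from_components(overall_vc,
      include_study = isTRUE(est_cfg$include_study))
    overall$outcome <- out_col
    log("icc", nrow(icc_tab), " year-group estimate(s); overall ICC ",
      round(overall$icc, 3), " (converged: ", overall_vc$converged, ")")
    utils::write.csv(icc_tab, file.path(out_dir, "icc_estimates.csv"),
      row.names = FALSE)
    jsonlite::write_json(icc_tab, file.path(out_dir, "icc_estimates.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    result$icc <- icc_tab
    result$icc_overall <- overall

    ac_cfg <- config$autocorrelation %||% list()
    ac <- tryCatch(
      {
        recs <- estimate_autocorrelations(data, out_col,
          min_pupils = ac_cfg$min_pupils %||% 5)
        pooled <- pool_correlations(recs,
          bin_by_followup = isTRUE(ac_cfg$bin_by_followup),
          method = ac_cfg$method %||% "DL")
        list(records = recs, pooled = pooled)
      },
      error = function(e) {
        log("autocorr", "skipped: ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(ac)) {
      log("autocorr", nrow(ac$records), " record(s) pooled into ",
        nrow(ac$pooled), " estimate(s)")
      utils::write.csv(ac$records,
        file.path(out_dir, "autocorrelation_records.csv"), row.names = FALSE)
      utils::write.csv(ac$pooled,
        file.path(out_dir, "autocorrelation.csv"), row.names = FALSE)
      result$autocorrelation_records <- ac$records
      result$autocorrelation_pooled <- ac$pooled
    }
  } else if (!is.null(design_cfg$icc)) {
    log("icc", "user-supplied design parameters; estimation stages skipped")
  }

  if (length(design_cfg)) {
    params <- tryCatch(
      .design_params(design_cfg, result),
      error = function(e) stop("stage 'design' failed: ",
        conditionMessage(e), call. = FALSE)
    )
    tab <- planning_table(
      populations = params$populations,
      icc_cols = params$icc_cols,
      delta = design_cfg$delta %||% 5,
      alpha = design_cfg$alpha %||% 0.05,
      power = design_cfg$power %||% 0.8,
      cac = params$cac, iac = params$iac,
      steps = design_cfg$steps %||% c(2, 3)
    )
    log("design", nrow(tab), " design cell(s) computed")
    utils::write.csv(tab, file.path(out_dir, "design.csv"), row.names = FALSE)
    result$design <- tab
  }

  invisible(result)
}

# Resolve the design inputs: user-supplied values win, otherwise the
# pipeline's own overall ICC estimate and pooled autocorrelations are used.
.design_params <- function(design_cfg, result) {
  icc <- design_cfg$icc
  icc_upper <- design_cfg$icc_upper
  sd_total <- design_cfg$sd_total
  cac <- design_cfg$cac
  iac <- design_cfg$iac
  if (is.null(icc)) {
    if (is.null(result$icc_overall)) {
      stop("no ICC available: supply design$icc or an estimation stage")
    }
    icc <- result$icc_overall$icc
    icc_upper <- icc_upper %||% result$icc_overall$ci_high
    sd_total <- sd_total %||% result$icc_overall$total_sd
  }
  if (is.null(cac) || is.null(iac)) {
    pooled <- result$autocorrelation_pooled
    if (is.null(pooled)) {
      stop("no CAC/IAC available: supply design$cac and design$iac or an ",
        "estimable autocorrelation stage")
    }
    if (is.null(cac)) cac <- pooled$r[pooled$level == "school"][1]
    if (is.null(iac)) iac <- pooled$r[pooled$level == "pupil"][1]
  }
  if (is.null(sd_total)) stop("design$sd_total is required")
  pops <- data.frame(
    label = design_cfg$label %||% "population",
    sd_total = sd_total,
    m = design_cfg$m %||% 25,
    icc_point = icc,
    stringsAsFactors = FALSE
  )
  icc_cols <- "icc_point"
  if (!is.null(icc_upper) && !is.na(icc_upper)) {
    pops$icc_upper <- icc_upper
    icc_cols <- c("icc_point", "icc_upper")
  }
  list(populations = pops, icc_cols = icc_cols, cac = cac, iac = iac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
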