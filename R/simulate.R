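#' Simulation configuration for multilevel physical-activity data
#'
#' Builds and validates the configuration object used by
#' [generate_population()]. The generator emulates accelerometer-measured
#' physical activity of pupils nested in schools nested in studies, measured
#' at repeated waves. Outcomes follow a Gaussian variance-component model
#' with study, school, pupil and residual levels; school and pupil effects
#' are exchangeable (compound-symmetric) across waves with correlations
#' `cac` and `iac` respectively, so the cluster and individual
#' autocorrelations of the generated data are known in closed form
#' (see [theoretical_moments()]).
#'
#' Phase-specific defaults are calibrated so that, for weekday
#' moderate-to-vigorous physical activity (MVPA):
#' * the model-based total SD (school + pupil + residual) is 23.2 min
#'   (primary) or 27.5 min (secondary), with school-level ICC 0.08 / 0.05;
#' * the marginal mean (SD) is about 55.8 (24.8) min for primary and
#'   54.7 (28.1) min for secondary pupils;
#' * the observable school-mean autocorrelation between waves is 0.60 and
#'   the observable pupil-level autocorrelation is 0.46 at the default
#'   pupils-per-school (25 primary, 50 secondary). Because observed school
#'   means contain pupil-level sampling noise, the latent school-effect
#'   correlation `cac` needed to achieve an observable value of 0.60 is
#'   slightly larger (about 0.67).
#'
#' @param phase `"primary"` or `"secondary"`; selects calibration defaults
#'   and the school-year ladder (Y1-Y6 vs Y7-Y11).
#' @param n_studies,schools_per_study,pupils_per_school Structure counts.
#' @param waves Numeric vector of follow-up offsets in years; strictly
#'   increasing with first element 0.
#' @param grand_mean Mean outcome in minutes for the reference pupil.
#' @param year_group_effects Named numeric vector of additive year-group
#'   effects (minutes) on the phase's year groups.
#' @param gender_effect Male-minus-female difference in minutes (applied as
#'   +/- half around `grand_mean`).
#' @param wear_time_mean,wear_time_sd Accelerometer wear time distribution
#'   (minutes/day), Gaussian truncated at 0.
#' @param wear_time_slope Outcome change per minute of (centred) wear time.
#' @param var_study,var_school,var_pupil,var_resid Variance components
#'   (minutes squared).
#' @param cac Exchangeable correlation of a school's effect across waves.
#' @param iac Exchangeable correlation of a pupil's effect across waves.
#' @param missing_rate Probability that any one outcome cell is missing
#'   (missing completely at random), in `[0, 1)`.
#' @param min_valid_days_distribution Named probability vector for the
#'   number of valid accelerometer days per pupil-wave (names are day
#'   counts). Used by the two-valid-day inclusion filter,
#'   [filter_valid()].
#' @param seed Integer seed; identical config and seed give a bit-identical
#'   dataset.
#'
#' @return A validated list of class `"pa_sim_config"`.
#' @seealso [generate_population()], [theoretical_moments()]
#' @export
sim_config <- function(phase = c("primary", "secondary"),
                       n_studies = 5L,
                       schools_per_study = 8L,
                       pupils_per_school = NULL,
                       waves = c(0, 1),
                       grand_mean = NULL,
                       year_group_effects = NULL,
                       gender_effect = 8,
                       wear_time_mean = 780,
                       wear_time_sd = 60,
                       wear_time_slope = 0,
                       var_study = NULL,
                       var_school = NULL,
                       var_pupil = NULL,
                       var_resid = NULL,
                       cac = NULL,
                       iac = NULL,
                       missing_rate = 0.05,
                       min_valid_days_distribution = c(
                         "1" = 0.05, "2" = 0.10, "3" = 0.15,
                         "4" = 0.30, "5" = 0.40
                       ),
                       seed = 1L) {
  phase <- match.arg(phase)
  def <- .phase_defaults(phase)
  if (is.null(pupils_per_school)) pupils_per_school <- def$m
  if (is.null(grand_mean)) grand_mean <- def$grand_mean
  if (is.null(year_group_effects)) year_group_effects <- def$year_group_effects
  if (is.null(var_study)) var_study <- def$var_study
  if (is.null(var_school)) var_school <- def$var_school
  if (is.null(var_pupil)) var_pupil <- def$var_pupil
  if (is.null(var_resid)) var_resid <- def$var_resid
  if (is.null(cac)) cac <- def$cac
  if (is.null(iac)) iac <- def$iac

  cfg <- list(
    phase = phase,
    n_studies = as.integer(n_studies),
    schools_per_study = as.integer(schools_per_study),
    pupils_per_school = as.integer(pupils_per_school),
    waves = as.numeric(waves),
    grand_mean = grand_mean,
    year_group_effects = year_group_effects,
    gender_effect = gender_effect,
    wear_time_mean = wear_time_mean,
    wear_time_sd = wear_time_sd,
    wear_time_slope = wear_time_slope,
    var_study = var_study,
    var_school = var_school,
    var_pupil = var_pupil,
    var_resid = var_resid,
    cac = cac,
    iac = iac,
    missing_rate = missing_rate,
    min_valid_days_distribution = min_valid_days_distribution,
    seed = as.integer(seed)
  )
  class(cfg) <- "pa_sim_config"
  validate_sim_config(cfg)
  cfg
}

# Calibration defaults by school phase.  Variance components are chosen so
# that (i) school/(school+pupil+resid) equals the target ICC at the target
# model total SD and (ii) the observable wave-pair correlations of school
# means and of pupil outcomes at the default cluster size equal 0.60 and
# 0.46 (see theoretical_moments()); the study variance and the fixed-effect
# spread then top the marginal SD up to the sample value.
.phase_defaults <- function(phase) {
  if (phase == "primary") {
    list(
      m = 25L, grand_mean = 55.8,
      year_group_effects = c("Y1&4" = 1, "Y5" = 0, "Y6" = -4),
      var_study = 57.5,
      var_school = 43.0592, var_pupil = 437.2303, var_resid = 57.9505,
      cac = 0.672938, iac = 0.5
    )
  } else {
    list(
      m = 50L, grand_mean = 54.7,
      year_group_effects = c("Y7" = 4, "Y8&9" = 1, "Y10&11" = -3),
      var_study = 10,
      var_school = 37.8125, var_pupil = 646.0536, var_resid = 72.3839,
      cac = 0.657141, iac = 0.5
    )
  }
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid simulation config: field '", field, "' ", why, call. = FALSE)
  }
  for (f in c("n_studies", "schools_per_study", "pupils_per_school")) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      bad(f, "must be a positive count")
    }
  }
  if (length(cfg$waves) < 1 || cfg$waves[1] != 0) bad("waves", "must start at 0")
  if (length(cfg$waves) > 1 && any(diff(cfg$waves) <= 0)) {
    bad("waves", "must be strictly increasing")
  }
  for (f in c("var_study", "var_school", "var_pupil", "var_resid")) {
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      bad(f, "must be a non-negative variance")
    }
  }
  for (f in c("cac", "iac")) {
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      bad(f, "must be a correlation in [0, 1]")
    }
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    bad("missing_rate", "must be in [0, 1)")
  }
  p <- cfg$min_valid_days_distribution
  if (is.null(names(p)) || any(is.na(suppressWarnings(as.integer(names(p))))) ||
      any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    bad("min_valid_days_distribution", "must be named day-count probabilities summing to 1")
  }
  if (cfg$wear_time_sd < 0) bad("wear_time_sd", "must be non-negative")
  yg <- .year_groups_for(cfg$phase)
  if (!all(names(cfg$year_group_effects) %in% yg)) {
    bad("year_group_effects", paste0(
      "names must be among ", paste(yg, collapse = ", ")
    ))
  }
  invisible(cfg)
}

# School-year ladder: integer years 1-11 bucketed into the reporting groups.
.year_groups_for <- function(phase) {
  if (phase == "primary") c("Y1&4", "Y5", "Y6") else c("Y7", "Y8&9", "Y10&11")
}

.year_to_group <- function(year) {
  cut(year,
    breaks = c(0, 4, 5, 6, 7, 9, 11),
    labels = c("Y1&4", "Y5", "Y6", "Y7", "Y8&9", "Y10&11")
  )
}

#' Closed-form moments of the generating model
#'
#' Returns the quantities the simulated data are expected to reproduce,
#' used as the oracle in parameter-recovery checks: the school-level ICC
#' and model total SD, the latent school/pupil autocorrelations, and the
#' *observable* wave-pair correlations. School means of `m` pupils carry
#' pupil-level sampling noise, so the expected Pearson correlation of
#' same-school means between two waves is
#' \deqn{(\pi \sigma^2_s + \tau \sigma^2_p / m) /
#'       (\sigma^2_s + (\sigma^2_p + \sigma^2_e) / m)}
#' and the expected pupil-level correlation (same school at both waves) is
#' \deqn{(\pi \sigma^2_s + \tau \sigma^2_p) /
#'       (\sigma^2_s + \sigma^2_p + \sigma^2_e).}
#'
#' @param config A [sim_config()] object.
#' @return List with `icc`, `total_sd`, `cac`, `iac`, `cac_observed`,
#'   `iac_observed`.
#' @export
theoretical_moments <- function(config) {
  validate_sim_config(config)
  vs <- config$var_school
  vp <- config$var_pupil
  vr <- config$var_resid
  total <- vs + vp + vr
  if (total == 0) {
    stop("ICC undefined: school, pupil and residual variances are all zero",
      call. = FALSE
    )
  }
  m <- config$pupils_per_school
  list(
    icc = vs / total,
    total_sd = sqrt(total),
    cac = config$cac,
    iac = config$iac,
    cac_observed = (config$cac * vs + config$iac * vp / m) /
      (vs + (vp + vr) / m),
    iac_observed = (config$cac * vs + config$iac * vp) / total
  )
}

#' Generate a multilevel longitudinal physical-activity dataset
#'
#' Simulates one pooled multi-study dataset of pupil-wave observations. The
#' weekday MVPA outcome follows
#' `grand_mean + year-group effect + gender effect + wear-time slope +
#' study + school + pupil + residual`, with Gaussian effects; school and
#' pupil effects are exchangeable across waves with correlations `cac` and
#' `iac`. Year groups advance deterministically with years since baseline;
#' a pupil crossing from Y6 into Y7 is reassigned to a (new) secondary
#' school, which is what makes the same-school restriction of the cluster
#' autocorrelation estimator testable. Pupils ageing beyond Y11 drop out of
#' the sampling frame. The whole-week MVPA and sedentary outcomes are
#' derived from the same latent signal with phase-calibrated means, SDs and
#' correlations. Outcome cells are then blanked missing-completely-at-random
#' at `missing_rate`, and negative simulated minutes are truncated at zero.
#'
#' @param config A [sim_config()] object.
#' @return A `data.frame` with columns `study_id, school_id, school_phase,
#'   pupil_id, wave_index, years_since_baseline, year_group, gender,
#'   wear_min, valid_days, mvpa_weekday, mvpa_week, sed_weekday, sed_week`.
#' @export
generate_population <- function(config) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  n_pupils <- cfg$n_studies * cfg$schools_per_study * cfg$pupils_per_school
  study <- rep(seq_len(cfg$n_studies),
    each = cfg$schools_per_study * cfg$pupils_per_school
  )
  school <- rep(rep(seq_len(cfg$schools_per_study), each = cfg$pupils_per_school),
    times = cfg$n_studies
  )
  pupil <- seq_len(n_pupils)

  base_years <- if (cfg$phase == "primary") 1:6 else 7:11
  base_year <- sample(base_years, n_pupils, replace = TRUE)
  gender <- sample(c("F", "M"), n_pupils, replace = TRUE)
  # destination secondary school if/when the pupil leaves primary
  sec_school <- sample(seq_len(cfg$schools_per_study), n_pupils, replace = TRUE)

  n_waves <- length(cfg$waves)
  rows <- data.frame(
    study = rep(study, times = n_waves),
    school0 = rep(school, times = n_waves),
    pupil = rep(pupil, times = n_waves),
    base_year = rep(base_year, times = n_waves),
    gender = rep(gender, times = n_waves),
    sec_school = rep(sec_school, times = n_waves),
    wave_index = rep(seq_len(n_waves), each = n_pupils),
    years_since_baseline = rep(cfg$waves, each = n_pupils)
  )
  rows$year <- rows$base_year + round(rows$years_since_baseline)
  rows <- rows[rows$year <= 11, , drop = FALSE]

  in_secondary <- rows$year >= 7
  prefix <- formatC(rows$study, width = 2, flag = "0")
  rows$school_phase <- ifelse(in_secondary, "secondary", "primary")
  rows$school_id <- ifelse(
    in_secondary & cfg$phase == "primary",
    sprintf("S%s_sec%02d", prefix, rows$sec_school),
    sprintf(
      "S%s_%s%02d", prefix,
      ifelse(cfg$phase == "primary", "pri", "sec"), rows$school0
    )
  )
  rows$study_id <- sprintf("S%s", prefix)
  rows$pupil_id <- sprintf("S%s_p%05d", prefix, rows$pupil)

  # random effects: exchangeable across waves via shared + wave-specific parts
  study_eff <- stats::rnorm(cfg$n_studies, 0, sqrt(cfg$var_study))

  sch_ids <- sort(unique(rows$school_id))
  sch_shared <- stats::setNames(stats::rnorm(length(sch_ids)), sch_ids)
  sch_wave <- matrix(stats::rnorm(length(sch_ids) * n_waves),
    nrow = length(sch_ids), dimnames = list(sch_ids, NULL)
  )
  s_idx <- match(rows$school_id, sch_ids)
  school_eff <- sqrt(cfg$var_school) * (
    sqrt(cfg$cac) * sch_shared[s_idx] +
      sqrt(1 - cfg$cac) * sch_wave[cbind(s_idx, rows$wave_index)]
  )

  pup_shared <- stats::rnorm(n_pupils)
  pup_wave <- matrix(stats::rnorm(n_pupils * n_waves), nrow = n_pupils)
  pupil_eff <- sqrt(cfg$var_pupil) * (
    sqrt(cfg$iac) * pup_shared[rows$pupil] +
      sqrt(1 - cfg$iac) * pup_wave[cbind(rows$pupil, rows$wave_index)]
  )

  resid <- stats::rnorm(nrow(rows), 0, sqrt(cfg$var_resid))
  wear <- pmax(0, stats::rnorm(nrow(rows), cfg$wear_time_mean, cfg$wear_time_sd))

  rows$year_group <- as.character(.year_to_group(rows$year))
  yg_eff <- cfg$year_group_effects[rows$year_group]
  yg_eff[is.na(yg_eff)] <- 0
  gender_eff <- ifelse(rows$gender == "M", 0.5, -0.5) * cfg$gender_effect

  mvpa <- cfg$grand_mean + as.numeric(yg_eff) + gender_eff +
    cfg$wear_time_slope * (wear - cfg$wear_time_mean) +
    study_eff[rows$study] + school_eff + pupil_eff + resid
  mvpa <- pmax(0, mvpa)

  # companion outcomes share the latent signal at calibrated mean/SD/corr
  z <- as.numeric(scale(mvpa))
  targets <- if (cfg$phase == "primary") {
    list(
      mvpa_week = c(54.3, 24.0, 0.90),
      sed_weekday = c(418.3, 117.6, -0.35),
      sed_week = c(406.4, 116.0, -0.35)
    )
  } else {
    list(
      mvpa_week = c(50.9, 26.1, 0.90),
      sed_weekday = c(425.0, 96.0, -0.35),
      sed_week = c(412.3, 91.0, -0.35)
    )
  }
  derive <- function(t) {
    pmax(0, t[1] + t[2] * (t[3] * z + sqrt(1 - t[3]^2) * stats::rnorm(length(z))))
  }

  days <- as.integer(names(cfg$min_valid_days_distribution))
  valid_days <- sample(days, nrow(rows),
    replace = TRUE,
    prob = cfg$min_valid_days_distribution
  )

  out <- data.frame(
    study_id = rows$study_id,
    school_id = rows$school_id,
    school_phase = rows$school_phase,
    pupil_id = rows$pupil_id,
    wave_index = rows$wave_index,
    years_since_baseline = rows$years_since_baseline,
    year_group = rows$year_group,
    gender = rows$gender,
    wear_min = wear,
    valid_days = valid_days,
    mvpa_weekday = mvpa,
    mvpa_week = derive(targets$mvpa_week),
    sed_weekday = derive(targets$sed_weekday),
    sed_week = derive(targets$sed_week),
    stringsAsFactors = FALSE
  )

  if (cfg$missing_rate > 0) {
    for (col in c("mvpa_weekday", "mvpa_week", "sed_weekday", "sed_week")) {
      out[[col]][stats::runif(nrow(out)) < cfg$missing_rate] <- NA_real_
    }
  }
  rownames(out) <- NULL
  out
}

#' Apply the valid-wear-days inclusion filter
#'
#' Keeps pupil-wave rows with at least `min_valid_days` days of valid
#' accelerometer data (default two), preserving row order. The number of
#' rows removed is attached as attribute `"n_removed"` and reported via
#' `message()`.
#'
#' @param data Observation table with a `valid_days` column.
#' @param min_valid_days Minimum number of valid days required.
#' @return The filtered table (possibly empty), with attribute `n_removed`.
#' @export
filter_valid <- function(data, min_valid_days = 2) {
  if (!"valid_days" %in% names(data)) {
    stop("'data' must contain a 'valid_days' column", call. = FALSE)
  }
  keep <- data$valid_days >= min_valid_days
  out <- data[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  message(sum(!keep), " row(s) removed by the ", min_valid_days,
    "-valid-day filter")
  out
}

#' Write / read the observation CSV dialect
#'
#' The on-disk format is a plain CSV with the fixed column order
#' `study_id,...,sed_week` and missing outcome cells written as empty
#' fields.
#'
#' @param data Observation table.
#' @param path File path.
#' @return `read_observations()` returns the observation `data.frame`.
#' @export
write_observations <- function(data, path) {
  cols <- .observation_columns()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("observation table lacks column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(data[cols], path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(.observation_columns(), names(out))
  if (length(missing_cols)) {
    stop("observation file lacks column(s): ",
      paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

.observation_columns <- function() {
  c(
    "study_id", "school_id", "school_phase", "pupil_id", "wave_index",
    "years_since_baseline", "year_group", "gender", "wear_min",
    "valid_days", "mvpa_weekday", "mvpa_week", "sed_weekday", "sed_week"
  )
}
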