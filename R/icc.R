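#' Fit the three-level variance-component model
#'
#' Fits a linear mixed model with random intercepts for study and pupil and
#' a school-level random term, by REML, and extracts the variance
#' components together with an approximate covariance matrix of the
#' variance estimates (from the numerically differentiated REML criterion,
#' i.e. the observed information). Fixed effects default to school year
#' group and accelerometer wear time; wear time is centred at its sample
#' mean before fitting. With `by_yeargroup = TRUE` the school term carries
#' an independent variance for every year group present (diagonal random
#' coefficients), matching the convention of reporting a separate
#' school-level ICC per year group.
#'
#' The study intercept is dropped (variance reported as 0, with a warning)
#' when the data contain a single study; the pupil intercept is included
#' only when some pupil has repeated rows, since with one observation per
#' pupil the pupil and residual variances are not separable (their sum is,
#' which is all the ICC needs).
#'
#' @param data Observation table (the [generate_population()] /
#'   [read_observations()] layout).
#' @param outcome Name of the outcome column.
#' @param fixed Character vector of fixed-effect columns; `"wear_min"` is
#'   replaced by its centred version, and factors with a single observed
#'   level are dropped.
#' @param by_yeargroup Estimate a separate school variance per year group?
#' @param compute_vcov Compute the covariance of the variance estimates
#'   (needed for confidence intervals; skip in large replicate loops where
#'   only point estimates are used)?
#' @return An object of class `"pa_varcomp"`: a list with `var_study`,
#'   `var_school` (named by year group, or `"all"`), `var_pupil`,
#'   `var_resid`, `vcov` (variance-scale covariance of the estimates),
#'   `n_schools`, `n_pupils`, `n_obs`, `converged`, and the underlying
#'   `lme4` fit.
#' @export
fit_variance_components <- function(data,
                                    outcome = "mvpa_weekday",
                                    fixed = c("year_group", "wear_min"),
                                    by_yeargroup = FALSE,
                                    compute_vcov = TRUE) {
  needed <- c(outcome, "study_id", "school_id", "pupil_id")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE)
  }
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if ("wear_min" %in% fixed) d <- d[!is.na(d$wear_min), , drop = FALSE]
  if (nrow(d) < 10) stop("fewer than 10 non-missing outcome rows", call. = FALSE)
  if (length(unique(d$school_id)) < 2) {
    stop("at least 2 schools are required", call. = FALSE)
  }

  d$.y <- d[[outcome]]
  fixed_terms <- character(0)
  for (f in fixed) {
    if (f == "wear_min") {
      d$.wear_c <- d$wear_min - mean(d$wear_min)
      fixed_terms <- c(fixed_terms, ".wear_c")
    } else if (length(unique(d[[f]])) > 1) {
      fixed_terms <- c(fixed_terms, f)
    }
  }

  multi_study <- length(unique(d$study_id)) > 1
  if (!multi_study) {
    warning("single study: study-level variance not estimable, reported as 0")
  }
  has_repeats <- anyDuplicated(d$pupil_id) > 0

  ygs <- NULL
  if (by_yeargroup) {
    ygs <- sort(unique(d$year_group))
    if (length(ygs) < 2) {
      by_yeargroup <- FALSE
    } else {
      for (i in seq_along(ygs)) {
        d[[paste0(".yg", i)]] <- as.numeric(d$year_group == ygs[i])
      }
    }
  }
  school_term <- if (by_yeargroup) {
    paste0("(0 + ", paste0(".yg", seq_along(ygs), collapse = " + "),
      " || school_id)")
  } else {
    "(1 | school_id)"
  }
  rhs <- c(
    if (length(fixed_terms)) fixed_terms else "1",
    if (multi_study) "(1 | study_id)",
    school_term,
    if (has_repeats) "(1 | pupil_id)"
  )
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))

  fit <- lme4::lmer(form, data = d, REML = TRUE)
  converged <- length(fit@optinfo$conv$lme4$messages) == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  # label each variance parameter
  lab <- character(nrow(vc))
  for (i in seq_len(nrow(vc))) {
    if (vc$grp[i] == "Residual") {
      lab[i] <- "resid"
    } else if (startsWith(vc$grp[i], "study_id")) {
      lab[i] <- "study"
    } else if (startsWith(vc$grp[i], "pupil_id")) {
      lab[i] <- "pupil"
    } else if (by_yeargroup) {
      k <- as.integer(sub("^\\.yg", "", vc$var1[i]))
      lab[i] <- paste0("school:", ygs[k])
    } else {
      lab[i] <- "school:all"
    }
  }
  est_var <- stats::setNames(vc$vcov, lab)

  vcov_var <- if (compute_vcov) {
    .varcomp_vcov(fit, lab)
  } else {
    matrix(NA_real_, length(lab), length(lab), dimnames = list(lab, lab))
  }

  school <- est_var[startsWith(lab, "school:")]
  names(school) <- sub("^school:", "", names(school))

  out <- list(
    var_study = if (multi_study) unname(est_var["study"]) else 0,
    var_school = school,
    var_pupil = if (has_repeats) unname(est_var["pupil"]) else 0,
    var_resid = unname(est_var["resid"]),
    pupil_separable = has_repeats,
    vcov = vcov_var,
    n_schools = length(unique(d$school_id)),
    n_pupils = length(unique(d$pupil_id)),
    n_obs = nrow(d),
    converged = converged,
    fit = fit
  )
  class(out) <- "pa_varcomp"
  out
}

# Covariance of the REML variance estimates: numerical Hessian of the
# profiled REML criterion on the SD scale (lme4::devfun2), transformed to
# the variance scale.  Returns an all-NA matrix when the curvature is not
# positive definite (typically a boundary fit).
.varcomp_vcov <- function(fit, labels) {
  n_par <- length(labels)
  na_mat <- matrix(NA_real_, n_par, n_par, dimnames = list(labels, labels))
  sds <- tryCatch(
    {
      vc <- as.data.frame(lme4::VarCorr(fit))
      vc$sdcor
    },
    error = function(e) NULL
  )
  if (is.null(sds)) return(na_mat)
  hess <- tryCatch(
    {
      dd <- lme4::devfun2(fit, useSc = TRUE, signames = FALSE)
      pracma::hessian(dd, sds)
    },
    error = function(e) NULL
  )
  if (is.null(hess) || any(!is.finite(hess))) return(na_mat)
  ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) {
    cov_sd <- 2 * pracma::pinv(hess)
  } else {
    cov_sd <- 2 * solve(hess)
  }
  jac <- diag(2 * sds, n_par)
  out <- jac %*% cov_sd %*% t(jac)
  dimnames(out) <- list(labels, labels)
  out
}

#' School-level ICC from fitted variance components
#'
#' The ICC is the school share of the within-study outcome variance,
#' `var_school / (var_school + var_pupil + var_resid)`. The study-level
#' variance is excluded from the denominator by default because a trial is
#' designed within a single study context; set `include_study = TRUE` for
#' the alternative convention. The standard error is propagated from the
#' covariance of the variance estimates by the delta method applied to the
#' ratio.
#'
#' @param vc A `"pa_varcomp"` object from [fit_variance_components()].
#' @param year_group Year group whose school variance to use; omit for a
#'   fit with a single common school variance.
#' @param include_study Include the study-level variance in the denominator?
#' @param level Confidence level for the logit-scale delta interval.
#' @return A one-row `data.frame` (class `"pa_icc"`) with `year_group`,
#'   `stratum`, `outcome`, `icc`, `se_icc`, `ci_low`, `ci_high`,
#'   `adjusted_for_baseline`, `total_sd` and bookkeeping counts.
#' @export
icc_from_components <- function(vc, year_group = NULL,
                                include_study = FALSE, level = 0.95) {
  stopifnot(inherits(vc, "pa_varcomp"))
  if (is.null(year_group)) {
    if (length(vc$var_school) != 1) {
      stop("fit has per-year-group school variances; supply 'year_group'",
        call. = FALSE)
    }
    year_group <- names(vc$var_school)
  }
  if (!year_group %in% names(vc$var_school)) {
    stop("no school variance estimated for year group '", year_group, "'",
      call. = FALSE)
  }
  vs <- vc$var_school[[year_group]]
  parts <- c(paste0("school:", if (year_group == "all") "all" else year_group),
    if (vc$pupil_separable) "pupil", "resid",
    if (include_study && vc$var_study > 0) "study")
  denom <- vs + vc$var_pupil + vc$var_resid +
    if (include_study) vc$var_study else 0
  if (denom <= 0) stop("ICC undefined: total variance is zero", call. = FALSE)
  icc <- vs / denom

  se <- NA_real_
  if (all(parts %in% rownames(vc$vcov)) && !anyNA(vc$vcov[parts, parts])) {
    grad <- stats::setNames(rep(-vs / denom^2, length(parts)), parts)
    grad[1] <- (denom - vs) / denom^2
    se <- sqrt(max(0, drop(t(grad) %*% vc$vcov[parts, parts] %*% grad)))
  }

  if (!is.na(se) && icc > 0 && icc < 1) {
    ci <- logit_delta_ci(icc, se, level)
  } else if (icc == 0 && !is.na(se)) {
    # boundary: one-sided upper bound on the raw scale
    ci <- c(0, min(1, stats::qnorm(level) * se))
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  out <- data.frame(
    year_group = year_group,
    stratum = "all",
    outcome = NA_character_,
    icc = unname(icc),
    se_icc = se,
    ci_low = ci[1],
    ci_high = ci[2],
    adjusted_for_baseline = FALSE,
    total_sd = sqrt(denom),
    n_schools = vc$n_schools,
    n_pupils = vc$n_pupils,
    n_obs = vc$n_obs,
    converged = vc$converged,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pa_icc", "data.frame")
  out
}

#' Delta-method confidence interval for an ICC on the logit scale
#'
#' Transfers the standard error of an ICC estimate to the logit scale
#' (`se / (icc * (1 - icc))`), forms a normal interval there and
#' back-transforms, which guarantees an interval inside (0, 1).
#'
#' @param icc Point estimate, strictly between 0 and 1.
#' @param se_icc Standard error of the ICC (raw scale), non-negative.
#' @param level Confidence level (default 0.95, i.e. z = 1.959964).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
logit_delta_ci <- function(icc, se_icc, level = 0.95) {
  if (!is.finite(icc) || icc <= 0 || icc >= 1) {
    stop("logit interval needs 0 < icc < 1; for a boundary estimate use a ",
      "one-sided bound on the raw scale", call. = FALSE)
  }
  if (!is.finite(se_icc) || se_icc < 0) {
    stop("se_icc must be a non-negative number", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  lg <- log(icc / (1 - icc))
  se_lg <- se_icc / (icc * (1 - icc))
  lo <- lg - z * se_lg
  hi <- lg + z * se_lg
  c(1 / (1 + exp(-lo)), 1 / (1 + exp(-hi)))
}

#' Per-year-group ICC estimates, optionally stratified by gender
#'
#' Fits the three-level model (per stratum) with year-group-specific school
#' variances and returns one ICC row per year group and stratum. If the
#' joint diagonal random-coefficient fit fails, the function falls back to
#' refitting within each year-group subset.
#'
#' @inheritParams fit_variance_components
#' @param stratify_by_gender Also produce separate estimates for girls and
#'   boys? Strata with fewer than 2 schools are skipped with a warning.
#' @param include_study Passed to [icc_from_components()].
#' @param level Confidence level.
#' @return A `data.frame` of class `"pa_icc"`, one row per year group (and
#'   stratum).
#' @export
estimate_iccs <- function(data, outcome = "mvpa_weekday",
                          stratify_by_gender = FALSE,
                          fixed = c("year_group", "wear_min"),
                          include_study = FALSE, level = 0.95) {
  strata <- if (stratify_by_gender) c("all", "girls", "boys") else "all"
  res <- list()
  for (s in strata) {
    d <- switch(s,
      all = data,
      girls = data[data$gender == "F", , drop = FALSE],
      boys = data[data$gender == "M", , drop = FALSE]
    )
    if (length(unique(d$school_id[!is.na(d[[outcome]])])) < 2) {
      warning("stratum '", s, "' has fewer than 2 schools; skipped")
      next
    }
    rows <- tryCatch(
      {
        vc <- fit_variance_components(d, outcome, fixed, by_yeargroup = TRUE)
        lapply(names(vc$var_school), function(yg) {
          icc_from_components(vc, yg, include_study, level)
        })
      },
      error = function(e) {
        # fallback: independent refit within each year group
        lapply(sort(unique(d$year_group)), function(yg) {
          di <- d[d$year_group == yg, , drop = FALSE]
          vc <- fit_variance_components(di, outcome,
            fixed = setdiff(fixed, "year_group"), by_yeargroup = FALSE)
          r <- icc_from_components(vc, NULL, include_study, level)
          r$year_group <- yg
          r
        })
      }
    )
    for (r in rows) {
      r$stratum <- s
      r$outcome <- outcome
      res[[length(res) + 1]] <- r
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("pa_icc", "data.frame")
  out
}

#' Baseline-adjusted ICC
#'
#' Re-estimates the school-level ICC for follow-up measurements with each
#' pupil's previous measurement of the same outcome added as a fixed
#' covariate (the ANCOVA convention for baseline-adjusted cluster trials).
#' Because adjustment absorbs the persistent pupil (and part of the school)
#' variation, both the adjusted total SD and, typically, the adjusted ICC
#' are smaller than the unadjusted ones; the adjusted pair is what a
#' baseline-adjusted trial design should be sized with. No year-group
#' breakdown is attempted (follow-up subsets are much smaller).
#'
#' @inheritParams fit_variance_components
#' @param include_study,level Passed to [icc_from_components()].
#' @return A one-row `"pa_icc"` data frame with
#'   `adjusted_for_baseline = TRUE`; `total_sd` is the baseline-adjusted
#'   total SD.
#' @export
baseline_adjusted_icc <- function(data, outcome = "mvpa_weekday",
                                  fixed = c("year_group", "wear_min"),
                                  include_study = FALSE, level = 0.95) {
  d <- data[!is.na(data[[outcome]]), , drop = FALSE]
  d <- d[order(d$pupil_id, d$wave_index), , drop = FALSE]
  prev <- c(NA_real_, d[[outcome]][-nrow(d)])
  same <- c(FALSE, d$pupil_id[-1] == d$pupil_id[-nrow(d)])
  d$.baseline <- ifelse(same, prev, NA_real_)
  d <- d[!is.na(d$.baseline), , drop = FALSE]
  if (nrow(d) < 10) {
    stop("no (or too few) repeated measurements: baseline adjustment needs ",
      "at least two waves per pupil for a non-trivial subset", call. = FALSE)
  }
  vc <- fit_variance_components(d, outcome,
    fixed = c(fixed, ".baseline"), by_yeargroup = FALSE)
  out <- icc_from_components(vc, NULL, include_study, level)
  out$year_group <- "all"
  out$outcome <- outcome
  out$adjusted_for_baseline <- TRUE
  out
}
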