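#' Design effect for a two-arm cluster RCT
#'
#' The classical variance inflation for equal clusters of size `m` with
#' intra-cluster correlation `icc`: `1 + (m - 1) * icc`.
#'
#' @param m Pupils measured per school.
#' @param icc Intra-cluster correlation, in `[0, 1)`.
#' @return The design effect (a scalar factor).
#' @export
design_effect_crct <- function(m, icc) {
  stopifnot(m >= 1, icc >= 0, icc < 1)
  1 + (m - 1) * icc
}

#' Required schools for a two-arm cluster RCT
#'
#' Finds the smallest per-arm number of schools `k` such that a two-sided
#' t test (degrees of freedom `2(k - 1)`, i.e. the cluster-level analysis)
#' attains the target power for a mean difference `delta`, when the
#' variance of the difference in arm means is
#' `2 * sd_total^2 * DE / (k * m)` with `DE = 1 + (m - 1) * icc`. The
#' critical value and the noncentral-t power both depend on `k`, so the
#' search iterates; power from the negligible opposite-tail rejection
#' region is ignored. Total schools returned is `2k`.
#'
#' @param delta Target difference in minutes (must be > 0).
#' @param sd_total Total outcome SD in minutes.
#' @param icc Intra-cluster correlation used for planning.
#' @param m Pupils per school.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Object of class `"pa_samplesize"`: list with `total_schools`,
#'   `allocation` (schools per arm), `achieved_power`, `design_effect`,
#'   `design`.
#' @export
required_schools_crct <- function(delta, sd_total, icc, m,
                                  alpha = 0.05, power = 0.8) {
  stopifnot(delta > 0, sd_total > 0, m >= 1, alpha > 0, alpha < 1,
    power > 0, power < 1)
  if (icc >= 1) stop("infeasible: icc must be < 1", call. = FALSE)
  de <- design_effect_crct(m, icc)
  k <- 2L
  repeat {
    pw <- .crct_power(k, delta, sd_total, icc, m, alpha)
    if (pw >= power) break
    k <- k + 1L
  }
  structure(
    list(
      design = "crct",
      total_schools = 2L * k,
      allocation = c(control = k, intervention = k),
      achieved_power = pw,
      design_effect = de
    ),
    class = "pa_samplesize"
  )
}

.crct_power <- function(k, delta, sd_total, icc, m, alpha) {
  de <- design_effect_crct(m, icc)
  se <- sqrt(2 * sd_total^2 * de / (k * m))
  df <- 2 * (k - 1)
  1 - stats::pt(stats::qt(1 - alpha / 2, df), df, ncp = delta / se)
}

#' Required schools for a baseline-adjusted (ANCOVA) cluster RCT
#'
#' Identical algorithm to [required_schools_crct()], applied to
#' baseline-adjusted inputs: the caller supplies the total SD and ICC from
#' a model adjusted for each pupil's previous measurement (e.g. from
#' [baseline_adjusted_icc()]). Both the SD and the ICC must come from the
#' adjusted model; mixing adjusted and unadjusted quantities mis-states the
#' variance a baseline-adjusted analysis will see.
#'
#' @param delta Target difference in minutes.
#' @param sd_adjusted Baseline-adjusted total SD.
#' @param icc_adjusted Baseline-adjusted ICC.
#' @inheritParams required_schools_crct
#' @return As [required_schools_crct()], with `design = "crct_ancova"`.
#' @export
required_schools_ancova <- function(delta, sd_adjusted, icc_adjusted, m,
                                    alpha = 0.05, power = 0.8) {
  out <- required_schools_crct(delta, sd_adjusted, icc_adjusted, m,
    alpha, power)
  out$design <- "crct_ancova"
  out
}

#' Cluster-period variance decomposition with CAC and IAC
#'
#' Decomposes the variance of an observed cluster-period mean (of `m`
#' pupils) into a component shared across all periods of the same school
#' and a component independent across periods, given the school-level ICC
#' `rho`, the cluster autocorrelation `cac` (correlation of the school's
#' underlying mean across periods) and, for closed-cohort designs, the
#' individual autocorrelation `iac`:
#' \deqn{v_b = \pi\rho\sigma^2 + [\mathrm{cohort}]\ \tau(1-\rho)\sigma^2/m}
#' \deqn{v_w = (1-\pi)\rho\sigma^2 + (1 - [\mathrm{cohort}]\tau)(1-\rho)\sigma^2/m}
#' With `cac = 1` and a cross-sectional sample this reduces to the
#' classical exchangeable model (`v_b = rho * sigma^2`,
#' `v_w = (1 - rho) * sigma^2 / m`).
#'
#' @param sd_total Total outcome SD (sigma).
#' @param icc School-level ICC (rho).
#' @param cac Cluster autocorrelation (pi).
#' @param iac Individual autocorrelation (tau); only used when
#'   `cohort = TRUE`.
#' @param m Pupils per school per period.
#' @param cohort Closed cohort (same pupils each period)?
#' @return Named numeric vector `c(v_between, v_within_period)` in minutes
#'   squared.
#' @export
cluster_period_variances <- function(sd_total, icc, cac, iac = 0, m,
                                     cohort = FALSE) {
  stopifnot(sd_total > 0, icc >= 0, icc < 1, cac >= 0, cac <= 1,
    iac >= 0, iac <= 1, m >= 1)
  s2 <- sd_total^2
  tau <- if (cohort) iac else 0
  c(
    v_between = cac * icc * s2 + tau * (1 - icc) * s2 / m,
    v_within_period = (1 - cac) * icc * s2 + (1 - tau) * (1 - icc) * s2 / m
  )
}

#' Hussey-Hughes treatment-effect variance for a complete stepped wedge
#'
#' Closed-form generalized-least-squares variance of the treatment effect
#' under the exchangeable cluster-period-mean model: `I` schools split
#' equally over `S` sequences, `T = S + 1` periods, all sequences start in
#' control and sequence `s` switches to intervention from period `s + 1`.
#' With treatment indicators `X[i, t]`, `U = sum(X)`,
#' `W = sum over t of colsum(X)^2`, `V = sum over i of rowsum(X)^2`,
#' and per-period mean variances `v_w` (independent) and `v_b` (shared):
#' \deqn{Var(\hat\theta) = \frac{I v_w (v_w + T v_b)}
#'   {(IU - W) v_w + (U^2 + ITU - TW - IV) v_b}}
#'
#' @param n_schools Total schools `I`; must be divisible by `steps`.
#' @param steps Number of steps `S` (sequences).
#' @param v_between,v_within_period Cluster-period variance components, as
#'   from [cluster_period_variances()].
#' @return Variance of the treatment-effect estimator (minutes squared).
#' @export
hh_treatment_variance <- function(n_schools, steps, v_between,
                                  v_within_period) {
  stopifnot(steps >= 2, v_between >= 0, v_within_period > 0)
  if (n_schools %% steps != 0) {
    stop("allocation error: n_schools (", n_schools,
      ") must be divisible by steps (", steps, ")", call. = FALSE)
  }
  X <- sw_design_matrix(n_schools, steps)
  I <- n_schools
  T <- steps + 1
  U <- sum(X)
  W <- sum(colSums(X)^2)
  V <- sum(rowSums(X)^2)
  vw <- v_within_period
  vb <- v_between
  I * vw * (vw + T * vb) /
    ((I * U - W) * vw + (U^2 + I * T * U - T * W - I * V) * vb)
}

#' Treatment-indicator matrix of a complete stepped wedge
#'
#' @inheritParams hh_treatment_variance
#' @return `n_schools x (steps + 1)` 0/1 matrix.
#' @export
sw_design_matrix <- function(n_schools, steps) {
  if (n_schools %% steps != 0) {
    stop("allocation error: n_schools must be divisible by steps",
      call. = FALSE)
  }
  per_seq <- n_schools / steps
  T <- steps + 1
  X <- matrix(0, n_schools, T)
  for (s in seq_len(steps)) {
    X[((s - 1) * per_seq + 1):(s * per_seq), (s + 1):T] <- 1
  }
  X
}

#' Required schools for a stepped wedge design
#'
#' Smallest total number of schools, a multiple of the number of steps
#' (equal allocation across sequences), whose two-sided
#' normal-approximation power at effect `delta` with the
#' [hh_treatment_variance()] reaches the target. A candidate size is
#' accepted as soon as computed power is greater than or equal to the
#' target (non-strict), which decides near-ties.
#'
#' @inheritParams required_schools_crct
#' @param cac Cluster autocorrelation.
#' @param iac Individual autocorrelation (cohort designs).
#' @param steps Number of steps.
#' @param cohort Closed cohort (`TRUE`) or cross-sectional (`FALSE`)
#'   sampling.
#' @param max_schools Search cap; exceeding it signals infeasibility.
#' @return `"pa_samplesize"` list with `total_schools`, `allocation`
#'   (schools per sequence), `achieved_power` and the variance components
#'   used.
#' @export
required_schools_sw <- function(delta, sd_total, icc, cac, iac = 0, m,
                                steps, cohort = FALSE,
                                alpha = 0.05, power = 0.8,
                                max_schools = 100000L) {
  stopifnot(delta > 0, steps >= 2)
  v <- cluster_period_variances(sd_total, icc, cac, iac, m, cohort)
  total <- steps
  repeat {
    pw <- .sw_power(total, steps, v, delta, alpha)
    if (pw >= power) break
    total <- total + steps
    if (total > max_schools) {
      stop("infeasible: no design up to ", max_schools,
        " schools reaches the target power", call. = FALSE)
    }
  }
  structure(
    list(
      design = if (cohort) "sw_cohort" else "sw_cross_sectional",
      steps = steps,
      total_schools = total,
      allocation = stats::setNames(rep(total / steps, steps),
        paste0("seq", seq_len(steps))),
      achieved_power = pw,
      v_between = unname(v[1]),
      v_within_period = unname(v[2])
    ),
    class = "pa_samplesize"
  )
}

.sw_power <- function(total, steps, v, delta, alpha) {
  va <- hh_treatment_variance(total, steps, v[1], v[2])
  stats::pnorm(delta / sqrt(va) - stats::qnorm(1 - alpha / 2))
}

#' Achieved power of a sized design, optionally under a different true ICC
#'
#' Evaluates the power of a given total number of schools. The planning
#' family determines the test: the cluster-RCT family uses the two-sided
#' t test with `2(k - 1)` degrees of freedom, the stepped wedge family the
#' normal approximation with the Hussey-Hughes variance. Passing
#' `true_icc` different from the ICC a design was sized with quantifies
#' the cost of ICC mis-specification (an under-estimated ICC yields an
#' under-powered study).
#'
#' @param design `"crct"`, `"crct_ancova"`, `"sw_cross_sectional"` or
#'   `"sw_cohort"`.
#' @param total_schools Total schools of the candidate design.
#' @param true_icc ICC at which to evaluate power (defaults to `icc`).
#' @inheritParams required_schools_sw
#' @return Power as a proportion in (0, 1); equals approximately `alpha`
#'   at `delta = 0`.
#' @export
achieved_power <- function(design = c("crct", "crct_ancova",
                             "sw_cross_sectional", "sw_cohort"),
                           total_schools, delta, sd_total, icc,
                           cac = NULL, iac = 0, m, steps = NULL,
                           alpha = 0.05, true_icc = NULL) {
  design <- match.arg(design)
  rho <- if (is.null(true_icc)) icc else true_icc
  if (design %in% c("crct", "crct_ancova")) {
    if (total_schools %% 2 != 0) {
      stop("allocation error: total_schools must be even for a two-arm ",
        "design", call. = FALSE)
    }
    if (delta == 0) {
      return(alpha)
    }
    .crct_power(total_schools / 2, delta, sd_total, rho, m, alpha)
  } else {
    if (is.null(steps) || is.null(cac)) {
      stop("stepped wedge power needs 'steps' and 'cac'", call. = FALSE)
    }
    if (delta == 0) {
      return(alpha)
    }
    v <- cluster_period_variances(sd_total, rho, cac, iac, m,
      cohort = design == "sw_cohort")
    .sw_power(total_schools, steps, v, delta, alpha)
  }
}

#' Planning table across designs, ICC values and populations
#'
#' Computes required school counts for the grid of designs typically
#' reported when planning a school-based physical-activity trial: two-arm
#' cluster RCT, optional baseline-adjusted cluster RCT, and cross-sectional
#' and cohort stepped wedges with the requested numbers of steps, each at
#' every supplied ICC value (e.g. the point estimate and the upper 95%
#' bound).
#'
#' @param populations `data.frame` with one row per target population and
#'   columns `label`, `sd_total`, `m`, plus one column per ICC scenario
#'   named in `icc_cols` (default `icc_point`, `icc_upper`). Optional
#'   columns `adj_sd`, `adj_icc_point`, `adj_icc_upper` enable the
#'   baseline-adjusted row.
#' @param icc_cols Names of the ICC scenario columns.
#' @param delta,alpha,power Effect size and error rates.
#' @param cac,iac Autocorrelations used by the stepped wedge designs.
#' @param steps Step counts for the stepped wedges.
#' @return Long `data.frame`: `population`, `design`, `steps`,
#'   `icc_scenario`, `icc`, `total_schools`, `achieved_power`.
#' @export
planning_table <- function(populations,
                           icc_cols = c("icc_point", "icc_upper"),
                           delta = 5, alpha = 0.05, power = 0.8,
                           cac = 0.6, iac = 0.5, steps = c(2, 3)) {
  rows <- list()
  add <- function(pop, design, st, scen, icc, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      population = pop, design = design,
      steps = if (is.null(st)) NA_integer_ else st,
      icc_scenario = scen, icc = icc,
      total_schools = res$total_schools,
      achieved_power = res$achieved_power,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(populations))) {
    p <- populations[i, ]
    for (scen in icc_cols) {
      icc <- p[[scen]]
      add(p$label, "crct", NULL, scen, icc,
        required_schools_crct(delta, p$sd_total, icc, p$m, alpha, power))
      adj_col <- sub("^icc", "adj_icc", scen)
      if (!is.null(p$adj_sd) && adj_col %in% names(p) &&
          !is.na(p[[adj_col]]) && !is.na(p$adj_sd)) {
        add(p$label, "crct_ancova", NULL, scen, p[[adj_col]],
          required_schools_ancova(delta, p$adj_sd, p[[adj_col]], p$m,
            alpha, power))
      }
      for (st in steps) {
        add(p$label, "sw_cross_sectional", st, scen, icc,
          required_schools_sw(delta, p$sd_total, icc, cac, 0, p$m, st,
            cohort = FALSE, alpha = alpha, power = power))
        add(p$label, "sw_cohort", st, scen, icc,
          required_schools_sw(delta, p$sd_total, icc, cac, iac, p$m, st,
            cohort = TRUE, alpha = alpha, power = power))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pa_samplesize <- function(x, ...) {
  cat("Design:", x$design,
    if (!is.null(x$steps)) paste0("(", x$steps, " steps)"), "\n")
  cat("Total schools:", x$total_schools, "\n")
  cat("Allocation:", paste(names(x$allocation), x$allocation,
    sep = "=", collapse = ", "), "\n")
  cat(sprintf("Achieved power: %.1f%%\n", 100 * x$achieved_power))
  invisible(x)
}
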