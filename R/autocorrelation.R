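#' Paired school-period means for the cluster autocorrelation
#'
#' For a pair of waves, computes each school's mean outcome at both waves,
#' keeping only schools with at least `min_pupils` contributing pupils at
#' each wave. Only same-school data are eligible: a pupil observed at both
#' waves under different school identifiers (e.g. across the
#' primary-secondary transition) is excluded from both waves before the
#' means are taken, mirroring the restriction used when estimating the
#' cluster autocorrelation across school phases.
#'
#' @param data Observation table.
#' @param wave_pair Integer vector of two `wave_index` values.
#' @param outcome Outcome column name.
#' @param min_pupils Minimum pupils per school per wave (default 5).
#' @return A `data.frame` with `school_id`, `mean_1`, `mean_2`, `n_1`,
#'   `n_2`; attribute `"n_excluded"` counts schools dropped by the pupil
#'   filter.
#' @export
school_period_means <- function(data, wave_pair, outcome = "mvpa_weekday",
                                min_pupils = 5) {
  stopifnot(length(wave_pair) == 2)
  d <- data[data$wave_index %in% wave_pair & !is.na(data[[outcome]]), ,
    drop = FALSE]
  if (!all(wave_pair %in% d$wave_index)) {
    return(structure(
      data.frame(school_id = character(), mean_1 = numeric(),
        mean_2 = numeric(), n_1 = integer(), n_2 = integer()),
      n_excluded = 0L
    ))
  }
  # drop pupils observed at both waves under different schools
  w1 <- d[d$wave_index == wave_pair[1], c("pupil_id", "school_id")]
  w2 <- d[d$wave_index == wave_pair[2], c("pupil_id", "school_id")]
  both <- merge(w1, w2, by = "pupil_id", suffixes = c("_1", "_2"))
  movers <- unique(both$pupil_id[both$school_id_1 != both$school_id_2])
  d <- d[!d$pupil_id %in% movers, , drop = FALSE]

  agg <- function(w) {
    di <- d[d$wave_index == w, , drop = FALSE]
    out <- stats::aggregate(di[[outcome]], by = list(school_id = di$school_id),
      FUN = mean)
    out$n <- as.integer(table(di$school_id)[out$school_id])
    names(out)[2] <- "mean"
    out
  }
  a1 <- agg(wave_pair[1])
  a2 <- agg(wave_pair[2])
  m <- merge(a1, a2, by = "school_id", suffixes = c("_1", "_2"))
  keep <- m$n_1 >= min_pupils & m$n_2 >= min_pupils
  out <- m[keep, c("school_id", "mean_1", "mean_2", "n_1", "n_2")]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Empirical cluster autocorrelation for one study and wave pair
#'
#' Pearson correlation of same-school mean outcomes between two waves
#' (schools with fewer than `min_pupils` pupils at either wave excluded).
#' Note the raw correlation of observed school means is attenuated relative
#' to the latent school-effect correlation by the pupil-level sampling
#' noise in each mean; it is reported uncorrected, as is conventional.
#'
#' @param data Observation table.
#' @param study `study_id` to use.
#' @param wave_pair Integer vector of two `wave_index` values.
#' @param outcome Outcome column name.
#' @param min_pupils Minimum pupils per school per wave.
#' @return One-row `data.frame`: `study_id`, `level = "school"`,
#'   `follow_up` (years between the waves), `r`, `n_units`.
#' @export
empirical_cac <- function(data, study, wave_pair, outcome = "mvpa_weekday",
                          min_pupils = 5) {
  d <- data[data$study_id == study, , drop = FALSE]
  pairs <- school_period_means(d, wave_pair, outcome, min_pupils)
  if (nrow(pairs) < 4) {
    stop("insufficient data: fewer than 4 qualifying schools for study '",
      study, "'", call. = FALSE)
  }
  data.frame(
    study_id = study,
    level = "school",
    follow_up = .follow_up_years(d, wave_pair),
    r = stats::cor(pairs$mean_1, pairs$mean_2),
    n_units = nrow(pairs),
    stringsAsFactors = FALSE
  )
}

#' Empirical individual autocorrelation for one study and wave pair
#'
#' Pearson correlation over pupils of their outcome at the two waves.
#' Pupils who changed school between the waves are retained: the
#' individual-level correlation uses all measurements across schools.
#'
#' @inheritParams empirical_cac
#' @return One-row `data.frame` with `level = "pupil"` and `n_units` the
#'   number of pupils with both measurements.
#' @export
empirical_iac <- function(data, study, wave_pair, outcome = "mvpa_weekday") {
  d <- data[data$study_id == study & data$wave_index %in% wave_pair &
    !is.na(data[[outcome]]), , drop = FALSE]
  w1 <- d[d$wave_index == wave_pair[1], c("pupil_id", outcome)]
  w2 <- d[d$wave_index == wave_pair[2], c("pupil_id", outcome)]
  m <- merge(w1, w2, by = "pupil_id", suffixes = c("_1", "_2"))
  if (nrow(m) < 4) {
    stop("insufficient data: fewer than 4 pupils with both measurements ",
      "for study '", study, "'", call. = FALSE)
  }
  data.frame(
    study_id = study,
    level = "pupil",
    follow_up = .follow_up_years(d, wave_pair),
    r = stats::cor(m[[2]], m[[3]]),
    n_units = nrow(m),
    stringsAsFactors = FALSE
  )
}

.follow_up_years <- function(d, wave_pair) {
  y <- vapply(wave_pair, function(w) {
    u <- unique(d$years_since_baseline[d$wave_index == w])
    if (length(u) != 1) stop("wave_index ", w, " maps to several follow-up ",
      "times", call. = FALSE)
    u
  }, numeric(1))
  abs(diff(y))
}

#' Fisher z transformation and its inverse
#'
#' `fisher_z()` is `atanh(r)`; `fisher_z_inv()` is `tanh(z)`. Under
#' approximate normality, a correlation from `n` units has variance
#' `1 / (n - 3)` on the z scale.
#'
#' @param r Correlation(s), strictly inside (-1, 1).
#' @param z z-scale value(s).
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Pool correlation records by meta-analysis on the Fisher z scale
#'
#' Each record (one study / wave-pair correlation) is transformed with
#' [fisher_z()] and given inverse-variance weight `n_units - 3`. Records
#' are pooled per level (school / pupil) and, optionally, per follow-up bin
#' (follow-up under one year is kept as its own `"<1"` bin; longer
#' follow-ups are rounded to the nearest whole year). Pooling is
#' random-effects DerSimonian-Laird by default (between-record variance
#' floored at zero), with fixed-effect pooling as an option; both are
#' computed via [metafor::rma()]. Pooled values and interval endpoints are
#' back-transformed to the correlation scale, so they always lie in
#' (-1, 1).
#'
#' @param records `data.frame` with columns `level`, `follow_up`, `r`,
#'   `n_units` (as produced by [empirical_cac()] / [empirical_iac()]).
#' @param bin_by_followup Pool within follow-up bins (`TRUE`) or across all
#'   follow-ups per level (`FALSE`).
#' @param method `"DL"` (random effects) or `"FE"` (fixed effect).
#' @param level Confidence level.
#' @return `data.frame` with one row per level (x bin): `level`,
#'   `follow_up_bin`, `r`, `ci_low`, `ci_high`, `k_records`, `tau2`, `Q`.
#' @export
pool_correlations <- function(records, bin_by_followup = TRUE,
                              method = c("DL", "FE"), level = 0.95) {
  method <- match.arg(method)
  if (any(records$n_units < 4)) {
    stop("every record needs n_units >= 4 so that the Fisher variance ",
      "1/(n-3) is defined", call. = FALSE)
  }
  records$bin <- if (bin_by_followup) {
    ifelse(records$follow_up < 1, "<1", as.character(round(records$follow_up)))
  } else {
    "all"
  }
  groups <- unique(records[c("level", "bin")])
  res <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- records[records$level == groups$level[i] &
      records$bin == groups$bin[i], , drop = FALSE]
    fit <- metafor::rma(
      yi = atanh(g$r), vi = 1 / (g$n_units - 3),
      method = method, level = 100 * level
    )
    res[[i]] <- data.frame(
      level = groups$level[i],
      follow_up_bin = groups$bin[i],
      r = tanh(as.numeric(fit$beta)),
      ci_low = tanh(fit$ci.lb),
      ci_high = tanh(fit$ci.ub),
      k_records = nrow(g),
      tau2 = fit$tau2,
      Q = fit$QE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' All CAC and IAC records for a dataset
#'
#' Convenience wrapper: loops over every study and every wave pair within
#' it, collecting [empirical_cac()] and [empirical_iac()] records; studies
#' or pairs with insufficient data are skipped with a warning.
#'
#' @inheritParams empirical_cac
#' @return `data.frame` of correlation records.
#' @export
estimate_autocorrelations <- function(data, outcome = "mvpa_weekday",
                                      min_pupils = 5) {
  res <- list()
  for (s in sort(unique(data$study_id))) {
    d <- data[data$study_id == s, , drop = FALSE]
    waves <- sort(unique(d$wave_index))
    if (length(waves) < 2) next
    for (i in seq_len(length(waves) - 1)) {
      for (j in (i + 1):length(waves)) {
        wp <- c(waves[i], waves[j])
        for (f in list(
          function() empirical_cac(data, s, wp, outcome, min_pupils),
          function() empirical_iac(data, s, wp, outcome)
        )) {
          rec <- tryCatch(f(), error = function(e) {
            warning(conditionMessage(e), call. = FALSE)
            NULL
          })
          if (!is.null(rec)) res[[length(res) + 1]] <- rec
        }
      }
    }
  }
  if (!length(res)) {
    stop("no estimable CAC/IAC records in the data", call. = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
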