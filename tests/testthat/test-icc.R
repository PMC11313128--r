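make_vc <- function(school, pupil, resid, study = 0,
                    vcov = NULL, pupil_separable = pupil > 0) {
  lab <- c("school:all", if (pupil_separable) "pupil", "resid")
  if (is.null(vcov)) {
    vcov <- matrix(NA_real_, length(lab), length(lab),
      dimnames = list(lab, lab))
  }
  structure(
    list(
      var_study = study, var_school = c(all = school), var_pupil = pupil,
      var_resid = resid, pupil_separable = pupil_separable, vcov = vcov,
      n_schools = 10, n_pupils = 100, n_obs = 100, converged = TRUE
    ),
    class = "pa_varcomp"
  )
}

test_that("ICC from components is the school share of within-study variance", {
  expect_equal(icc_from_components(make_vc(8, 46, 46))$icc, 0.08)
  expect_equal(icc_from_components(make_vc(0, 50, 50))$icc, 0)
  # study variance excluded by default, included on request
  vc <- make_vc(8, 46, 46, study = 100)
  expect_equal(icc_from_components(vc)$icc, 0.08)
  expect_equal(icc_from_components(vc, include_study = TRUE)$icc, 8 / 200)
  expect_error(icc_from_components(make_vc(0, 0, 0)), "undefined")
})

test_that("logit-scale delta interval matches its closed form", {
  expect_equal(logit_delta_ci(0.5, 0), c(0.5, 0.5))
  # direct evaluation of inv-logit(logit(0.08) +/- 1.959964 * se_logit)
  ci <- logit_delta_ci(0.08, 0.013)
  expect_equal(ci, c(0.0579468, 0.1094708), tolerance = 1e-5)
  expect_all_in_unit(logit_delta_ci(0.999, 0.005))
  expect_all_in_unit(logit_delta_ci(0.001, 0.005))
  expect_error(logit_delta_ci(0, 0.01), "one-sided")
  expect_error(logit_delta_ci(1, 0.01), "one-sided")
  expect_error(logit_delta_ci(0.5, -1), "se_icc")
})

test_that("REML fit recovers the generating variance components", {
  cfg <- sim_config("primary",
    n_studies = 5, schools_per_study = 20, pupils_per_school = 15,
    waves = c(0, 1), var_study = 40, var_school = 43.06,
    var_pupil = 247.6, var_resid = 247.6, cac = 1, iac = 1,
    missing_rate = 0, seed = 20
  )
  # cac = iac = 1: constant school/pupil effects, so the random-intercept
  # model is exactly the generating model
  d <- generate_population(cfg)
  vc <- fit_variance_components(d)
  for (comp in c("school:all", "pupil", "resid", "study")) {
    est <- switch(comp,
      `school:all` = vc$var_school[["all"]],
      pupil = vc$var_pupil, resid = vc$var_resid, study = vc$var_study
    )
    truth <- switch(comp,
      `school:all` = 43.06, pupil = 247.6, resid = 247.6, study = 40
    )
    se <- sqrt(vc$vcov[comp, comp])
    if (comp == "study") {
      # with few studies the model-based SE conditions on a noisy point
      # estimate; use the theoretical sampling SD of a 5-draw variance
      se <- max(se, truth * sqrt(2 / 4))
    }
    expect_lt(abs(est - truth), 3 * se)
  }
  expect_true(vc$converged)
  expect_equal(vc$n_obs, nrow(d))
})

test_that("single-study data report zero study variance with a warning", {
  d <- generate_population(quick_config(n_schools = 20, m = 10, seed = 21))
  expect_warning(vc <- fit_variance_components(d), "single study")
  expect_equal(vc$var_study, 0)
  # single wave: pupil and residual variances are pooled
  expect_false(vc$pupil_separable)
  expect_equal(vc$var_pupil, 0)
})

test_that("data generated without school variance hit the boundary at zero", {
  cfg <- quick_config(n_schools = 40, m = 15, seed = 22)
  cfg$var_school <- 0
  d <- generate_population(cfg)
  suppressWarnings(vc <- fit_variance_components(d))
  expect_lt(vc$var_school[["all"]], 2)
  r <- icc_from_components(vc)
  expect_lt(r$icc, 0.01)
  expect_true(is.na(r$ci_low) || r$ci_low >= 0)
})

test_that("ICC is invariant to shifting and rescaling the outcome", {
  d <- generate_population(quick_config(n_schools = 40, m = 12, seed = 23))
  suppressWarnings(base <- icc_from_components(fit_variance_components(d)))
  d2 <- d
  d2$mvpa_weekday <- 3.7 * d2$mvpa_weekday + 100
  suppressWarnings(tr <- icc_from_components(fit_variance_components(d2)))
  expect_equal(tr$icc, base$icc, tolerance = 1e-4)
  expect_equal(tr$ci_low, base$ci_low, tolerance = 1e-3)
})

test_that("confidence intervals tighten as schools accumulate", {
  w <- sapply(c(50, 500), function(k) {
    d <- generate_population(quick_config(n_schools = k, m = 10, seed = 24))
    suppressWarnings(r <- icc_from_components(fit_variance_components(d)))
    expect_all_in_unit(c(r$ci_low, r$ci_high))
    r$ci_high - r$ci_low
  })
  expect_lt(w[2], w[1])
})

test_that("gender stratification recovers stratum-specific ICCs", {
  # girls and boys generated with the same components: equal ICCs
  mk <- function(seed, gender, vs = 43.06, vpr = 495.2) {
    cfg <- quick_config(n_schools = 150, m = 10, seed = seed)
    cfg$var_school <- vs
    cfg$var_pupil <- 0.8 * vpr
    cfg$var_resid <- 0.2 * vpr
    d <- generate_population(cfg)
    d$gender <- gender
    d$school_id <- paste0(gender, "_", d$school_id)
    d$pupil_id <- paste0(gender, "_", d$pupil_id)
    d
  }
  sym <- rbind(mk(30, "F"), mk(31, "M"))
  suppressWarnings(tab <- estimate_iccs(sym, stratify_by_gender = TRUE))
  g <- tab$icc[tab$stratum == "girls"]
  b <- tab$icc[tab$stratum == "boys"]
  expect_equal(mean(g), mean(b), tolerance = 0.35)

  # inflating the boys' pupil-level variance at fixed school variance
  # lowers the boys' ICC (theoretical 0.080 vs 0.055)
  asym <- rbind(mk(32, "F"), mk(33, "M", vpr = 1.5 * 495.2))
  suppressWarnings(tab2 <- estimate_iccs(asym, stratify_by_gender = TRUE))
  expect_lt(
    mean(tab2$icc[tab2$stratum == "boys"]),
    mean(tab2$icc[tab2$stratum == "girls"])
  )

  # combined ICC lies between the stratum ICCs when the strata differ
  mixed <- rbind(mk(34, "F", vs = 0.05 * 538.24, vpr = 0.95 * 538.24),
    mk(35, "M", vs = 0.10 * 538.24, vpr = 0.90 * 538.24))
  suppressWarnings(vc_all <- fit_variance_components(mixed,
    fixed = c("year_group", "wear_min")))
  icc_all <- icc_from_components(vc_all)$icc
  expect_gt(icc_all, 0.04)
  expect_lt(icc_all, 0.11)
})

test_that("stratum with too few schools is skipped with a warning", {
  d <- generate_population(quick_config(n_schools = 10, m = 12, seed = 36))
  d$gender <- "F"
  d$gender[d$school_id == d$school_id[1]] <- "M"
  d$mvpa_weekday[d$gender == "M"][1:5] <- NA
  w <- testthat::capture_warnings(
    tab <- estimate_iccs(d, stratify_by_gender = TRUE)
  )
  expect_true(any(grepl("fewer than 2 schools", w)))
  expect_false("boys" %in% tab$stratum)
})

test_that("baseline adjustment shrinks total variation when pupils track", {
  # independent pupil effects: baseline uninformative, estimates unchanged
  cfg0 <- longitudinal_config(n_studies = 3, n_schools = 15, m = 25,
    seed = 40, missing_rate = 0, iac = 0, cac = 1)
  d0 <- generate_population(cfg0)
  unadj0 <- icc_from_components(fit_variance_components(d0))
  adj0 <- baseline_adjusted_icc(d0)
  expect_true(adj0$adjusted_for_baseline)
  expect_equal(adj0$total_sd, unadj0$total_sd, tolerance = 0.05)
  expect_equal(adj0$icc, unadj0$icc, tolerance = 0.5)

  # autocorrelated pupils: adjusted total SD and ICC drop
  cfg1 <- longitudinal_config(n_studies = 3, n_schools = 15, m = 25,
    seed = 41, missing_rate = 0, iac = 0.5, cac = 0.6)
  d1 <- generate_population(cfg1)
  unadj1 <- icc_from_components(fit_variance_components(d1))
  adj1 <- baseline_adjusted_icc(d1)
  expect_lt(adj1$total_sd, unadj1$total_sd)
  expect_lt(adj1$icc, unadj1$icc + 0.01)

  expect_error(
    baseline_adjusted_icc(generate_population(quick_config(seed = 42))),
    "repeated"
  )
})
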