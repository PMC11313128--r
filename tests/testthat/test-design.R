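# Brute-force GLS oracle: invert the full IT x IT block covariance of the
# cluster-period means and read off the treatment-effect variance.
gls_sw_variance <- function(n_schools, steps, vb, vw) {
  X <- sw_design_matrix(n_schools, steps)
  T <- steps + 1
  I <- n_schools
  # columns: period effects (T), then treatment
  Z <- cbind(
    do.call(rbind, replicate(I, diag(T), simplify = FALSE)),
    as.vector(t(X))
  )
  Vb <- vw * diag(T) + vb * matrix(1, T, T)
  Vinv <- solve(Vb)
  blocks <- replicate(I, Vinv, simplify = FALSE)
  Vfull_inv <- as.matrix(Matrix::bdiag(blocks))
  info <- t(Z) %*% Vfull_inv %*% Z
  solve(info)[T + 1, T + 1]
}

# Monte-Carlo power of the cluster-level t test for a two-arm cRCT
simulate_crct_power <- function(k, delta, sd_total, icc, m, alpha = 0.05,
                                n_sim = 20000, seed = 1) {
  set.seed(seed)
  var_mean <- sd_total^2 * (1 + (m - 1) * icc) / m
  hits <- replicate(n_sim, {
    a <- rnorm(k, 0, sqrt(var_mean))
    b <- rnorm(k, delta, sqrt(var_mean))
    abs(t.test(a, b, var.equal = TRUE)$statistic) >
      qt(1 - alpha / 2, 2 * (k - 1))
  })
  mean(hits)
}

test_that("design effect follows 1 + (m - 1) * icc", {
  expect_equal(design_effect_crct(25, 0.08), 2.92)
  expect_equal(design_effect_crct(1, 0.5), 1)
  expect_equal(design_effect_crct(50, 0.05), 3.45)
})

test_that("cRCT sizing matches Monte-Carlo power at and below the answer", {
  res <- required_schools_crct(5, 23.2, 0.08, 25)
  k <- res$total_schools / 2
  expect_equal(res$allocation, c(control = k, intervention = k))
  p_at <- simulate_crct_power(k, 5, 23.2, 0.08, 25, seed = 60)
  p_below <- simulate_crct_power(k - 1, 5, 23.2, 0.08, 25, seed = 61)
  mc3 <- 3 * sqrt(0.8 * 0.2 / 20000)
  expect_gt(p_at, 0.8 - mc3)
  expect_lt(p_below, 0.8 + mc3)
})

test_that("with one pupil per school the cRCT reduces to the two-sample t", {
  for (prm in list(c(5, 23.2), c(10, 27.5), c(3, 8))) {
    res <- required_schools_crct(prm[1], prm[2], 0, 1)
    oracle <- ceiling(power.t.test(
      delta = prm[1], sd = prm[2],
      power = 0.8, sig.level = 0.05
    )$n)
    expect_equal(res$total_schools / 2, oracle)
  }
})

test_that("baseline-adjusted sizing reduces to the cRCT and is monotone", {
  plain <- required_schools_crct(5, 23.2, 0.08, 25)
  same <- required_schools_ancova(5, 23.2, 0.08, 25)
  expect_equal(same$total_schools, plain$total_schools)
  expect_equal(same$design, "crct_ancova")
  smaller_sd <- required_schools_ancova(5, 0.9 * 23.2, 0.08, 25)
  expect_lte(smaller_sd$total_schools, plain$total_schools)
})

test_that("cluster-period variances reduce to the exchangeable model at
           CAC = 1 and match direct arithmetic", {
  s2 <- 23.2^2
  v <- cluster_period_variances(23.2, 0.08, cac = 1, m = 25)
  expect_equal(unname(v), c(0.08 * s2, 0.92 * s2 / 25))

  v2 <- cluster_period_variances(23.2, 0.08, cac = 0.6, m = 25)
  expect_equal(unname(v2), c(25.83552, 37.03091), tolerance = 1e-6)
  v3 <- cluster_period_variances(23.2, 0.08, cac = 0.6, iac = 0.5, m = 25,
    cohort = TRUE)
  expect_equal(unname(v3), c(35.73914, 27.12730), tolerance = 1e-6)
})

test_that("Hussey-Hughes variance agrees with explicit GLS inversion", {
  # fixed small cases
  expect_equal(hh_treatment_variance(2, 2, 0, 3.5), 2 * 3.5,
    tolerance = 1e-10)
  expect_equal(
    hh_treatment_variance(62, 2, 25.84, 37.03),
    gls_sw_variance(62, 2, 25.84, 37.03),
    tolerance = 1e-10
  )
  expect_equal(sqrt(hh_treatment_variance(62, 2, 25.84, 37.03)), 1.757,
    tolerance = 2e-3)

  # randomized small designs
  set.seed(62)
  for (i in 1:25) {
    S <- sample(2:3, 1)
    I <- S * sample(1:4, 1)
    vb <- runif(1, 0, 50)
    vw <- runif(1, 0.5, 50)
    hh <- hh_treatment_variance(I, S, vb, vw)
    expect_equal(hh, gls_sw_variance(I, S, vb, vw), tolerance = 1e-8)
  }

  # homogeneity of degree one in the variance components
  expect_equal(hh_treatment_variance(12, 3, 8, 6) * 2,
    hh_treatment_variance(12, 3, 16, 12), tolerance = 1e-10)

  expect_error(hh_treatment_variance(7, 2, 1, 1), "divisible")
})

test_that("stepped wedge sizing reproduces the published grid and is
           minimal and monotone", {
  grid <- expand.grid(
    sd = c(23.2, 27.5), icc_kind = c("point", "upper"),
    steps = c(2, 3), cohort = c(FALSE, TRUE)
  )
  expected <- c( # printed school counts, primary/secondary x point/upper
    62, 50, 68, 64,   39, 30, 42, 39,   48, 40, 54, 54,   30, 24, 33, 33
  )
  i <- 0
  for (cohort in c(FALSE, TRUE)) {
    for (steps in c(2, 3)) {
      for (kind in c("point", "upper")) {
        for (sd in c(23.2, 27.5)) {
          i <- i + 1
          icc <- if (sd == 23.2) {
            if (kind == "point") 0.08 else 0.10
          } else {
            if (kind == "point") 0.05 else 0.08
          }
          m <- if (sd == 23.2) 25 else 50
          res <- required_schools_sw(5, sd, icc, 0.6, 0.5, m, steps,
            cohort = cohort)
          expect_equal(res$total_schools, expected[i],
            info = sprintf("cohort=%s steps=%d %s sd=%.1f",
              cohort, steps, kind, sd))
          # minimality: one sequence-width fewer fails the target
          if (res$total_schools > steps) {
            expect_lt(
              achieved_power(res$design, res$total_schools - steps,
                5, sd, icc, cac = 0.6, iac = 0.5, m = m, steps = steps),
              0.8
            )
          }
          expect_gte(res$achieved_power, 0.8)
        }
      }
    }
  }

  # monotone in ICC
  sizes <- sapply(c(0.02, 0.05, 0.08, 0.12), function(r) {
    required_schools_sw(5, 23.2, r, 0.6, 0.5, 25, 2)$total_schools
  })
  expect_true(all(diff(sizes) >= 0))

  # cohort never needs more schools than cross-sectional when IAC > 0
  for (icc in c(0.05, 0.08, 0.10)) {
    for (steps in c(2, 3)) {
      cs <- required_schools_sw(5, 23.2, icc, 0.6, 0, 25, steps)
      coh <- required_schools_sw(5, 23.2, icc, 0.6, 0.5, 25, steps,
        cohort = TRUE)
      expect_lte(coh$total_schools, cs$total_schools)
    }
  }
})

test_that("cRCT sizing is minimal and monotone in ICC", {
  for (icc in c(0.02, 0.05, 0.08)) {
    res <- required_schools_crct(5, 23.2, icc, 25)
    expect_gte(res$achieved_power, 0.8)
    expect_lt(
      achieved_power("crct", res$total_schools - 2, 5, 23.2, icc, m = 25),
      0.8
    )
  }
  sizes <- sapply(c(0, 0.02, 0.04, 0.08, 0.12), function(r) {
    required_schools_crct(5, 23.2, r, 25)$total_schools
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("null effect size yields power equal to the significance level", {
  expect_equal(achieved_power("crct", 40, 0, 23.2, 0.08, m = 25), 0.05)
  expect_equal(
    achieved_power("sw_cohort", 40, 0, 23.2, 0.08,
      cac = 0.6, iac = 0.5, m = 25, steps = 2),
    0.05
  )
})

test_that("planning table covers the grid and responds to m and ICC", {
  pops <- data.frame(
    label = c("primary", "secondary"),
    sd_total = c(23.2, 27.5), m = c(25, 50),
    icc_point = c(0.08, 0.05), icc_upper = c(0.10, 0.08)
  )
  tab <- planning_table(pops)
  expect_equal(nrow(tab), 2 * 2 * 5) # 2 pops x 2 ICCs x (crct + 4 SW)
  # upper-bound ICC never needs fewer schools than the point estimate
  merged <- merge(
    tab[tab$icc_scenario == "icc_point", ],
    tab[tab$icc_scenario == "icc_upper", ],
    by = c("population", "design", "steps")
  )
  expect_true(all(merged$total_schools.y >= merged$total_schools.x))

  # more pupils per school never increases the school count
  pops50 <- transform(pops[1, ], m = 50)
  tab50 <- planning_table(pops50)
  cmp <- merge(tab[tab$population == "primary", ], tab50,
    by = c("design", "steps", "icc_scenario"))
  expect_true(all(cmp$total_schools.y <= cmp$total_schools.x))

  # baseline-adjusted row appears when adjusted inputs are supplied
  pops_adj <- pops
  pops_adj$adj_sd <- c(20.9, 25.4)
  pops_adj$adj_icc_point <- c(0.06, 0.04)
  pops_adj$adj_icc_upper <- c(0.09, 0.06)
  tab_adj <- planning_table(pops_adj)
  expect_true("crct_ancova" %in% tab_adj$design)
  expect_equal(nrow(tab_adj), 2 * 2 * 6)
})

test_that("infeasible requests fail loudly", {
  expect_error(required_schools_crct(5, 23.2, 1, 25), "icc")
  expect_error(required_schools_crct(-5, 23.2, 0.05, 25))
})
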