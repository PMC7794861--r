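# Meta-analysis: fixed-effect and DerSimonian-Laird pooling, OR reporting.

test_that("fixed-effect pooling matches closed forms and metafor", {
  # single estimate returned unchanged
  one <- tibble::tibble(beta = 0.3, se = 0.1)
  f1 <- meta_fixed(one)
  expect_equal(f1$pooled$beta, 0.3)
  expect_equal(f1$pooled$se, 0.1)

  # two equal-SE estimates: arithmetic mean, se / sqrt(2)
  two <- tibble::tibble(beta = c(0.1, 0.3), se = c(0.2, 0.2))
  f2 <- meta_fixed(two)
  expect_equal(f2$pooled$beta, 0.2)
  expect_equal(f2$pooled$se, 0.2 / sqrt(2))

  # random 5-study set against the closed-form oracle and metafor
  set.seed(20)
  d <- tibble::tibble(beta = rnorm(5, 0.2, 0.1), se = runif(5, 0.05, 0.2))
  f <- meta_fixed(d)
  w <- 1 / d$se^2
  expect_equal(f$pooled$beta, sum(w * d$beta) / sum(w), tolerance = 1e-12)
  expect_equal(f$pooled$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  rma <- metafor::rma(yi = d$beta, sei = d$se, method = "FE")
  expect_equal(f$pooled$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(f$pooled$se, rma$se, tolerance = 1e-8)
  expect_equal(f$q, rma$QE, tolerance = 1e-8)
  expect_error(meta_fixed(d[0, ]), "at least")
})

test_that("DerSimonian-Laird pooling matches the textbook formula and metafor", {
  set.seed(21)
  d <- tibble::tibble(beta = rnorm(8, 0.2, 0.15), se = runif(8, 0.05, 0.2))
  r <- meta_dl(d)
  # textbook oracle
  w <- 1 / d$se^2
  bf <- sum(w * d$beta) / sum(w)
  q <- sum(w * (d$beta - bf)^2)
  tau2 <- max(0, (q - 7) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (d$se^2 + tau2)
  expect_equal(r$tau_squared, tau2, tolerance = 1e-12)
  expect_equal(r$pooled$beta, sum(wr * d$beta) / sum(wr), tolerance = 1e-12)
  rma <- metafor::rma(yi = d$beta, sei = d$se, method = "DL")
  expect_equal(r$pooled$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(r$tau_squared, rma$tau2, tolerance = 1e-8)
  expect_equal(r$i_squared, max(0, (r$q - r$df) / r$q))

  # Q <= df collapses to fixed effect
  tight <- tibble::tibble(beta = c(0.2, 0.201, 0.199), se = rep(0.2, 3))
  dl <- meta_dl(tight)
  fe <- meta_fixed(tight)
  expect_equal(dl$tau_squared, 0)
  expect_equal(dl$pooled$beta, fe$pooled$beta)
  expect_equal(dl$pooled$se, fe$pooled$se)

  # identical studies: pooled equals the common value
  same <- tibble::tibble(beta = rep(0.4, 4), se = rep(0.1, 4))
  expect_equal(meta_dl(same)$pooled$beta, 0.4)
  expect_equal(meta_dl(same)$tau_squared, 0)
  expect_error(meta_dl(one <- tibble::tibble(beta = 1, se = 1)), "at least 2")
})

test_that("tau^2 estimates centre near the true between-study variance", {
  set.seed(22)
  tau2_hat <- replicate(200, {
    k <- 30
    truth <- rnorm(k, 0.1, sd = 0.1)    # between-study SD 0.1
    se <- runif(k, 0.04, 0.08)
    obs <- rnorm(k, truth, se)
    meta_dl(tibble::tibble(beta = obs, se = se))$tau_squared
  })
  mc_se <- sd(tau2_hat) / sqrt(length(tau2_hat))
  expect_lt(abs(mean(tau2_hat) - 0.01), 4 * mc_se)
})

test_that("study constructor and OR report round-trip published values", {
  studies <- tibble::tibble(
    label = c("a", "b"), or = c(1.20, 1.08),
    ci_low = c(1.11, 1.00), ci_high = c(1.30, 1.16)
  )
  e <- study_estimates(studies)
  expect_equal(exp(e$beta), studies$or)
  # CI reconstruction round-trips within rounding
  # printed CIs are rounded and slightly asymmetric; agreement to ~1%
  z <- qnorm(0.975)
  expect_equal(exp(e$beta - z * e$se), studies$ci_low, tolerance = 0.01)
  expect_equal(exp(e$beta + z * e$se), studies$ci_high, tolerance = 0.01)

  rep1 <- or_table_report(meta_fixed(e[1, ]))
  expect_equal(rep1$or, 1.20)
  expect_equal(rep1$or_ci_low, 1.11, tolerance = 0.01)
  expect_equal(or_table_report(meta_fixed(tibble::tibble(beta = 0, se = 1)))$or, 1)
  expect_error(study_estimates(dplyr::mutate(studies, ci_low = 0)), "ci_low")
})

test_that("pooled CI excludes 1 exactly when p < 0.05", {
  set.seed(23)
  for (i in 1:20) {
    d <- tibble::tibble(beta = rnorm(4, 0, 0.2), se = runif(4, 0.05, 0.3))
    rep <- or_table_report(meta_fixed(d))
    excludes <- rep$or_ci_low > 1 || rep$or_ci_high < 1
    expect_equal(excludes, rep$pvalue < 0.05)
  }
})

test_that("pooling respects ordering, dominance and width invariants", {
  set.seed(24)
  d <- tibble::tibble(beta = rnorm(6, 0.1, 0.2), se = runif(6, 0.05, 0.3))
  # permutation invariance
  perm <- d[sample(6), ]
  expect_equal(meta_fixed(d)$pooled, meta_fixed(perm)$pooled)
  expect_equal(meta_dl(d)$pooled, meta_dl(perm)$pooled)
  # pooled fixed SE never exceeds the smallest input SE
  expect_lte(meta_fixed(d)$pooled$se, min(d$se))
  # DL CI at least as wide as fixed CI
  expect_gte(meta_dl(d)$pooled$se, meta_fixed(d)$pooled$se)
})

test_that("grouped pooling returns one tidy row per stratum", {
  studies <- tibble::tibble(
    label = paste0("s", 1:6),
    or = c(1.05, 1.08, 1.19, 1.20, 1.1, 1.15),
    ci_low = c(0.94, 1.00, 0.95, 1.11, 0.9, 1.02),
    ci_high = c(1.19, 1.16, 1.49, 1.30, 1.3, 1.28),
    group = rep(c("adult_overweight", "child_obese"), each = 3)
  )
  pooled <- meta_pool(study_estimates(studies), model = "random")
  expect_equal(nrow(pooled), 2)
  expect_setequal(pooled$group, unique(studies$group))
  expect_true(all(pooled$k == 3))
})
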