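# independent oracles ---------------------------------------------------------

# zero-intercept weighted least squares via lm(); unscaled coefficient se
wls_no_intercept <- function(inst) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = inst,
                   weights = 1 / inst$se_out^2)
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)[1]),
       se_unscaled = sm$coefficients[1, 2] / sm$sigma)
}

# weighted regression with intercept, exposure-positive orientation
wls_with_intercept <- function(inst) {
  flip <- ifelse(inst$beta_exp < 0, -1, 1)
  d <- data.frame(x = inst$beta_exp * flip, y = inst$beta_out * flip,
                  w = 1 / inst$se_out^2)
  fit <- stats::lm(y ~ x, data = d, weights = d$w)
  sm <- summary(fit)
  list(intercept = unname(stats::coef(fit)[1]), slope = unname(stats::coef(fit)[2]),
       se_intercept_unscaled = sm$coefficients[1, 2] / sm$sigma,
       se_slope_unscaled = sm$coefficients[2, 2] / sm$sigma,
       sigma = sm$sigma)
}

# weighted median by scanning cumulative weight midpoints (no approx())
wm_oracle <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  k <- max(which(p <= 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

# tests ------------------------------------------------------------------------

test_that("the Wald ratio divides effects and scales the se by |beta_exp|", {
  inst <- make_instruments(0.1, 0.02, 0.05, 0.01)
  res <- mr_wald_ratio(inst)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$std.error, 0.1)
  expect_equal(mr_wald_ratio(make_instruments(0.1, 0.02, 0, 0.01))$estimate, 0)
  # allele-frame flip leaves the ratio unchanged
  flipped <- make_instruments(-0.1, 0.02, -0.05, 0.01)
  expect_equal(mr_wald_ratio(flipped)$estimate, 0.5)
  expect_error(mr_wald_ratio(make_instruments(0, 0.02, 0.05, 0.01)), "nonzero")
})

test_that("IVW reduces to the Wald ratio for one variant and is exact when ratios agree", {
  one <- make_instruments(0.1, 0.02, 0.05, 0.01)
  ivw1 <- mr_ivw(one)
  wald <- mr_wald_ratio(one)
  expect_equal(ivw1$estimate, wald$estimate)
  expect_equal(ivw1$std.error, wald$std.error)
  expect_true(is.na(ivw1$q))

  equal_r <- make_instruments(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.1, 0.2), 0.01)
  res <- mr_ivw(equal_r)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$q, 0)
  expect_equal(res$q_pval, 1)
})

test_that("fixed-effect IVW and Egger match the brute-force WLS oracle on random instances", {
  withr::with_seed(17, seeds <- sample.int(1e6, 100))
  for (s in seeds) {
    m <- 5 + (s %% 16)
    inst <- random_instruments(m, s)
    fix <- mr_ivw(inst, model = "fixed")
    oracle <- wls_no_intercept(inst)
    expect_equal(fix$estimate, oracle$beta, tolerance = 1e-10)
    expect_equal(fix$std.error, oracle$se_unscaled, tolerance = 1e-10)

    egger <- mr_egger(inst)
    o2 <- wls_with_intercept(inst)
    expect_equal(egger$estimate[egger$method == "egger_slope"], o2$slope,
                 tolerance = 1e-10)
    expect_equal(egger$estimate[egger$method == "egger_intercept"], o2$intercept,
                 tolerance = 1e-10)
    phi <- max(1, o2$sigma)
    expect_equal(egger$std.error[egger$method == "egger_slope"],
                 o2$se_slope_unscaled * phi, tolerance = 1e-10)
    expect_equal(egger$std.error[egger$method == "egger_intercept"],
                 o2$se_intercept_unscaled * phi, tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the fixed se exactly when Q exceeds its df", {
  for (s in 1:20) {
    inst <- random_instruments(4 + s, s * 31)
    fix <- mr_ivw(inst, model = "fixed")
    ran <- mr_ivw(inst, model = "multiplicative_random")
    expect_gte(ran$std.error, fix$std.error)
    if (ran$q <= ran$q_df) expect_equal(ran$std.error, fix$std.error)
    else expect_equal(ran$std.error, fix$std.error * sqrt(ran$q / ran$q_df))
  }
})

test_that("the weighted median interpolates cumulative weights at one half", {
  inst <- make_instruments(c(1, 1, 1), 0.01, c(0.1, 0.5, 0.9), 0.01)
  res <- mr_weighted_median(inst, n_boot = 50, seed = 1)
  expect_equal(res$estimate, 0.5)

  # identical ratios: estimate is that ratio, se -> 0 with instrument noise
  tight <- make_instruments(c(0.1, 0.2, 0.3), 1e-6, c(0.07, 0.14, 0.21), 1e-6)
  res_t <- mr_weighted_median(tight, n_boot = 100, seed = 2)
  expect_equal(res_t$estimate, 0.7)
  expect_lt(res_t$std.error, 1e-4)

  # random instances against the scanning oracle
  for (s in 1:25) {
    inst <- random_instruments(7, 1000 + s)
    r <- inst$beta_out / inst$beta_exp
    w <- inst$beta_exp^2 / inst$se_out^2
    est <- mr_weighted_median(inst, n_boot = 10, seed = s)$estimate
    expect_equal(est, wm_oracle(r, w), tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(make_instruments(1, 0.1, 1, 0.1), seed = 1),
               "at least 3")
})

test_that("weighted median attains the 50% breakdown bound as noise vanishes", {
  # 60% of weight on valid instruments (ratio = 0.3), 40% arbitrary
  beta_exp <- c(1, 1, 1, 1, 1)
  beta_out <- c(0.3, 0.3, 0.3, 5, -7)
  se_out <- c(0.01, 0.01, 0.01, 0.0123, 0.0123)  # valid weight share ~ 60%
  inst <- make_instruments(beta_exp, 1e-8, beta_out, se_out)
  w <- beta_exp^2 / se_out^2
  expect_gt(sum(w[1:3]) / sum(w), 0.5)
  expect_equal(mr_weighted_median(inst, n_boot = 10, seed = 3)$estimate, 0.3)
})

test_that("Egger recovers exact linear and affine relationships", {
  x <- c(0.05, 0.1, 0.2, 0.35)
  exact <- make_instruments(x, 0.01, 0.3 * x, c(0.01, 0.02, 0.01, 0.03))
  res <- mr_egger(exact)
  expect_equal(res$estimate[res$method == "egger_slope"], 0.3, tolerance = 1e-12)
  expect_equal(res$estimate[res$method == "egger_intercept"], 0, tolerance = 1e-12)

  affine <- make_instruments(x, 0.01, 0.02 + 0.3 * x, 0.015)
  res2 <- mr_egger(affine)
  expect_equal(res2$estimate[res2$method == "egger_slope"], 0.3, tolerance = 1e-12)
  expect_equal(res2$estimate[res2$method == "egger_intercept"], 0.02,
               tolerance = 1e-12)

  degenerate <- make_instruments(c(0.1, 0.1, -0.1), 0.01, c(0.1, 0.2, 0.3), 0.01)
  expect_error(mr_egger(degenerate), "singular|constant")
})

test_that("every estimator is invariant to flipping an instrument's allele frame", {
  inst <- random_instruments(9, 77)
  flip <- rep(1, 9); flip[c(2, 5, 8)] <- -1
  inst_f <- inst
  inst_f$beta_exp <- inst$beta_exp * flip
  inst_f$beta_out <- inst$beta_out * flip
  expect_equal(mr_ivw(inst_f), mr_ivw(inst))
  expect_equal(mr_weighted_median(inst_f, n_boot = 200, seed = 4)$estimate,
               mr_weighted_median(inst, n_boot = 200, seed = 4)$estimate)
  expect_equal(mr_egger(inst_f), mr_egger(inst))
})

test_that("leave-one-out flags sign instability and returns one row per variant", {
  stable <- make_instruments(c(0.1, 0.2, 0.3, 0.4), 0.01,
                             c(0.05, 0.1, 0.15, 0.2), 0.01)
  loo <- mr_leave_one_out(stable)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$estimate, rep(0.5, 4))
  expect_false(loo_sign_change(loo))

  # one dominant variant drives a positive estimate; without it the sign flips
  dom <- make_instruments(c(1, 0.05, 0.05, 0.05), 0.001,
                          c(0.5, -0.01, -0.012, -0.009), c(0.01, 0.001, 0.001, 0.001))
  full <- mr_ivw(dom)$estimate
  without <- mr_ivw(dom[-1, ])$estimate
  expect_true(sign(full) != sign(without))  # constructed via the IVW oracle
  expect_true(loo_sign_change(mr_leave_one_out(dom)))
})

test_that("scatter data carries one point per variant and origin-anchored lines", {
  inst <- random_instruments(3, 5)
  fit <- mr_fit(inst, n_boot = 50, seed = 6)
  sd <- mr_scatter_data(inst, generics::tidy(fit))
  expect_equal(nrow(sd$points), 3)
  expect_equal(nrow(sd$lines), 3)
  expect_equal(sd$lines$intercept[sd$lines$method == "ivw"], 0)
  expect_equal(sd$lines$intercept[sd$lines$method == "weighted_median"], 0)
  egger_fit <- mr_egger(inst)
  expect_equal(sd$lines$intercept[sd$lines$method == "egger"],
               egger_fit$estimate[egger_fit$method == "egger_intercept"])
})

test_that("estimators agree on clean strong-instrument data", {
  s <- sim_scenario(m_snps = 50, beta_causal = 0.15, exposure_r2_total = 0.1,
                    n_exposure = 1e6, n_outcome = 1e6, seed = 123)
  inst <- sim_instruments(simulate_pair(s))
  fit <- mr_fit(inst, n_boot = 200, seed = 123)
  est <- generics::tidy(fit)
  core <- est[est$method %in% c("ivw", "weighted_median", "egger_slope"), ]
  # all within 3 standard errors of the truth and of each other
  expect_true(all(abs(core$estimate - 0.15) < 3 * core$std.error))
  expect_lt(max(core$estimate) - min(core$estimate), 3 * max(core$std.error))
})

test_that("tidy and glance summarize an MR fit in broom shape", {
  inst <- random_instruments(8, 11)
  fit <- mr_fit(inst, n_boot = 100, seed = 2)
  td <- generics::tidy(fit)
  expect_named(td, c("method", "estimate", "std.error", "statistic",
                     "p.value", "n_snps"))
  expect_setequal(td$method, c("ivw", "weighted_median", "egger_slope",
                               "egger_intercept"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_snps, 8)
  expect_false(is.na(gl$q_pval))
})
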