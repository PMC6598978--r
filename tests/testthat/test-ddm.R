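test_that("density is zero before the non-decision time and continuous after", {
  p <- ddm_params(v = 1, a = 2, ndt = 0.3)
  expect_equal(wfpt_density(0.29, "upper", p), 0)
  expect_equal(wfpt_density(0.3, "upper", p), 0)
  near <- wfpt_density(c(0.3005, 0.301, 0.31), "upper", p)
  expect_true(all(is.finite(near)) && all(near >= 0))
  expect_gt(wfpt_density(0.6, "upper", p), 0)
})

test_that("upper and lower defective densities integrate to one", {
  for (v in c(-2, 0, 1, 3)) {
    for (a in c(0.8, 1.5, 2.5)) {
      p <- ddm_params(v = v, a = a, ndt = 0.25)
      up <- integrate(function(t) wfpt_density(t, "upper", p), p$ndt, Inf,
                      rel.tol = 1e-9)$value
      lo <- integrate(function(t) wfpt_density(t, "lower", p), p$ndt, Inf,
                      rel.tol = 1e-9)$value
      expect_equal(up + lo, 1, tolerance = 1e-4)
    }
  }
})

test_that("closed-form choice probability equals the upper-density integral", {
  for (v in c(-1.5, 0, 0.5, 2)) {
    for (a in c(1, 2)) {
      p <- ddm_params(v = v, a = a, ndt = 0.2)
      up <- integrate(function(t) wfpt_density(t, "upper", p), p$ndt, Inf,
                      rel.tol = 1e-9)$value
      expect_equal(choice_prob_upper(v, a), up, tolerance = 1e-4)
    }
  }
  expect_equal(choice_prob_upper(0, 2), 0.5)
  expect_equal(choice_prob_upper(50, 2), 1, tolerance = 1e-8)
  expect_error(choice_prob_upper(1, -1), class = "rlddm_parameter_error")
})

test_that("density is invariant to joint shifts of t and ndt", {
  t <- seq(0.35, 2, by = 0.05)
  d1 <- wfpt_density(t, "upper", ddm_params(1.2, 1.8, 0.3))
  d2 <- wfpt_density(t + 0.17, "upper", ddm_params(1.2, 1.8, 0.47))
  expect_equal(d1, d2)
})

test_that("upper density under drift v equals lower density under -v", {
  t <- seq(0.25, 3, by = 0.05)
  expect_equal(wfpt_density(t, "upper", ddm_params(1.3, 2, 0.2)),
               wfpt_density(t, "lower", ddm_params(-1.3, 2, 0.2)))
})

test_that("simulated choice fractions and passage times match theory", {
  set.seed(421)
  p <- ddm_params(v = 0, a = 2, ndt = 0.3)
  s <- simulate_ddm(2e4, p, dt = 1e-3)
  expect_true(all(s$rt >= p$ndt, na.rm = TRUE))
  frac <- mean(s$boundary == "upper", na.rm = TRUE)
  mc_se <- sqrt(0.25 / 2e4)
  expect_lt(abs(frac - 0.5), 3 * mc_se)
})

test_that("halving the Euler step leaves the upper fraction unchanged", {
  p <- ddm_params(v = 1, a = 1.5, ndt = 0.2)
  set.seed(99)
  f1 <- mean(simulate_ddm(2e4, p, dt = 2e-3)$boundary == "upper", na.rm = TRUE)
  f2 <- mean(simulate_ddm(2e4, p, dt = 1e-3)$boundary == "upper", na.rm = TRUE)
  # two independent binomial estimates of the same limit
  se <- sqrt(2 * 0.25 / 2e4)
  expect_lt(abs(f1 - f2), 4 * se)
})

test_that("log-likelihood is an empty-sum zero, additive, and -Inf past ndt", {
  p <- ddm_params(v = 1, a = 2, ndt = 0.3)
  expect_identical(wfpt_loglik(numeric(0), character(0), p), 0)
  rt <- c(0.5, 0.8, 1.1, 0.6)
  b <- c("upper", "lower", "upper", "upper")
  llA <- wfpt_loglik(rt[1:2], b[1:2], p)
  llB <- wfpt_loglik(rt[3:4], b[3:4], p)
  expect_equal(wfpt_loglik(rt, b, p), llA + llB)
  expect_identical(wfpt_loglik(c(0.5, 0.2), c("upper", "upper"), p), -Inf)
})

test_that("the generating drift beats +/-50% perturbations in likelihood", {
  set.seed(7)
  p <- ddm_params(v = 1, a = 2, ndt = 0.3)
  s <- simulate_ddm(1e4, p, dt = 5e-4)
  keep <- !is.na(s$rt)
  ll <- function(v) wfpt_loglik(s$rt[keep], s$boundary[keep],
                                ddm_params(v, p$a, p$ndt))
  expect_gt(ll(1), ll(0.5))
  expect_gt(ll(1), ll(1.5))
})
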