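test_that("the sampler reproduces a conjugate-normal posterior", {
  # y ~ N(mu, 1), mu ~ N(0, 1): posterior N(n*ybar/(n+1), 1/(n+1))
  set.seed(12)
  y <- rnorm(60, 0.8, 1)
  n <- length(y)
  post_mean <- n * mean(y) / (n + 1)
  post_sd <- sqrt(1 / (n + 1))
  lp <- function(th) sum(dnorm(y, th[["mu"]], 1, log = TRUE)) +
    dnorm(th[["mu"]], 0, 1, log = TRUE)
  d <- mcmc_mwg(lp, c(mu = 0),
                default_settings(chains = 4, iter = 3000, warmup = 1000,
                                 seed = 5))
  x <- extract_draws(d, "mu")
  expect_equal(mean(x), post_mean, tolerance = 0.02)
  expect_equal(sd(x), post_sd, tolerance = 0.05)
  expect_lt(as.numeric(rhat(d, "mu")), 1.01)
})

test_that("draws are bitwise identical under the same seed", {
  lp <- function(th) dnorm(th[["x"]], 0, 1, log = TRUE)
  s <- default_settings(chains = 2, iter = 200, warmup = 100, seed = 77)
  d1 <- mcmc_mwg(lp, c(x = 0), s)
  d2 <- mcmc_mwg(lp, c(x = 0), s)
  expect_identical(d1$draws, d2$draws)
})

test_that("retained draws equal chains x (iter - warmup)", {
  lp <- function(th) dnorm(th[["x"]], 0, 1, log = TRUE)
  d <- mcmc_mwg(lp, c(x = 0),
                default_settings(chains = 4, iter = 500, warmup = 250))
  expect_equal(dim(d$draws)[1], 250)
  expect_equal(dim(d$draws)[2], 4)
  expect_equal(length(extract_draws(d, "x")), 4 * 250)
})

test_that("initialization fails after 100 non-finite draws", {
  lp <- function(th) -Inf
  expect_error(mcmc_mwg(lp, function() c(x = rnorm(1)),
                        default_settings(chains = 1, iter = 10, warmup = 5)),
               class = "rlddm_initialization_error")
})

test_that("rhat is near 1 for iid chains and large for a shifted chain", {
  set.seed(3)
  m <- matrix(rnorm(4 * 10000), 10000, 4)
  r <- rhat(m)
  expect_lt(as.numeric(r), 1.01)
  expect_true(attr(r, "converged"))
  m_bad <- m
  m_bad[, 1] <- m_bad[, 1] + 10
  r_bad <- rhat(m_bad)
  expect_gt(as.numeric(r_bad), 2)
  expect_false(attr(r_bad, "converged"))
  expect_error(rhat(m[, 1, drop = FALSE]), class = "rlddm_parameter_error")
})

test_that("credible intervals match analytic quantiles", {
  set.seed(4)
  x <- rnorm(1e6)
  ci <- bci(x)
  expect_equal(ci[["low"]], -1.96, tolerance = 0.01)
  expect_equal(ci[["high"]], 1.96, tolerance = 0.01)
  # symmetric draws give a symmetric interval
  xs <- c(x, -x)
  cis <- bci(xs)
  expect_equal(cis[["low"]], -cis[["high"]], tolerance = 1e-10)
  # degenerate draws collapse the interval
  expect_equal(unname(bci(rep(2.5, 100))), c(2.5, 2.5))
  expect_error(bci(numeric(0)), class = "rlddm_parameter_error")
  # interval endpoints are ordered and finite by construction
  ci2 <- bci(rexp(1000))
  expect_true(is.finite(ci2[["low"]]) && is.finite(ci2[["high"]]))
  expect_lte(ci2[["low"]], ci2[["high"]])
})
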