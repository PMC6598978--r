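test_that("condition coding uses reward-partial as the reference cell", {
  expect_equal(unlist(encode_condition("reward", "partial")),
               c(valence = 0L, feedback = 0L, interaction = 0L))
  expect_equal(unlist(encode_condition("punishment", "complete")),
               c(valence = 1L, feedback = 1L, interaction = 1L))
  expect_equal(unlist(encode_condition("punishment", "partial")),
               c(valence = 1L, feedback = 0L, interaction = 0L))
  expect_equal(unlist(encode_condition("reward", "complete")),
               c(valence = 0L, feedback = 1L, interaction = 0L))
  expect_error(encode_condition("gain", "partial"),
               class = "rlddm_validation_error")
})

test_that("null slopes decode to identical parameters in all conditions", {
  cf <- factorial_coeffs(v = c(1.2, 0, 0, 0), a = c(log(2), 0, 0, 0),
                         ndt = c(log(0.3), 0, 0, 0))
  cells <- expand.grid(valence = c("reward", "punishment"),
                       feedback = c("partial", "complete"),
                       stringsAsFactors = FALSE)
  ps <- lapply(seq_len(4), function(i) {
    condition_ddm_params(cf, encode_condition(cells$valence[i],
                                              cells$feedback[i]))
  })
  for (p in ps) {
    expect_equal(p$v, 1.2)
    expect_equal(p$a, 2)
    expect_equal(p$ndt, 0.3)
  }
})

test_that("decoded thresholds and NDTs are positive for any coefficients", {
  set.seed(6)
  for (i in 1:20) {
    cf <- factorial_coeffs(rnorm(4, 0, 2), rnorm(4, 0, 2), rnorm(4, 0, 2))
    p <- condition_ddm_params(cf, encode_condition("punishment", "complete"))
    expect_gt(p$a, 0)
    expect_gt(p$ndt, 0)
  }
})

test_that("the (1,1,1) cell sums all four coefficients on each link scale", {
  cf <- factorial_coeffs(v = c(0.5, 0.1, -0.2, 0.3),
                         a = c(0.6, -0.1, 0.2, 0.05),
                         ndt = c(-1.2, 0.15, -0.1, 0.02))
  p <- condition_ddm_params(cf, encode_condition("punishment", "complete"))
  expect_equal(p$v, sum(cf["v", ]))
  expect_equal(p$a, exp(sum(cf["a", ])))
  expect_equal(p$ndt, exp(sum(cf["ndt", ])))
})

test_that("factorial fitting recovers slope signs for effects >= 0.2", {
  truth <- factorial_coeffs(
    v = c(1.2, 0, 0.4, 0),
    a = c(log(1.8), 0.25, 0.2, 0),
    ndt = c(log(0.3), 0.25, -0.2, 0)
  )
  cohort <- simulate_factorial_cohort(truth, n_participants = 20,
                                      trials_per_condition = 40, seed = 21)
  fit <- fit_factorial_ddm(cohort,
                           settings = default_settings(chains = 2,
                                                       iter = 1500,
                                                       warmup = 750,
                                                       seed = 22))
  gs <- summary(fit, which = "group")
  est <- function(p) gs$mean[gs$parameter == paste0("mu_", p)]
  expect_gt(est("v_feedback"), 0)
  expect_gt(est("a_valence"), 0)
  expect_gt(est("a_feedback"), 0)
  expect_gt(est("ndt_valence"), 0)
  expect_lt(est("ndt_feedback"), 0)
  # intercepts land near the generating values
  expect_equal(est("v_intercept"), 1.2, tolerance = 0.35)
  expect_equal(est("ndt_intercept"), log(0.3), tolerance = 0.2)
})
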