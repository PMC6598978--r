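test_that("the dataset log-likelihood is additive over participants", {
  cohort <- simulate_cohort(make_design("exp1"), n_participants = 3, seed = 14)
  parts <- attr(cohort, "participants")
  ll_all <- dataset_loglik("rlddm", cohort, parts)
  expect_true(is.finite(ll_all))
  ll_sum <- 0
  for (id in parts$participant_id) {
    sub <- validate_trial_table(cohort[cohort$participant_id == id, ])
    ll_sum <- ll_sum + dataset_loglik("rlddm", sub,
                                      parts[parts$participant_id == id, ])
  }
  expect_equal(ll_all, ll_sum)
})

test_that("generating parameters beat 50% drift perturbations in likelihood", {
  cohort <- simulate_cohort(make_design("exp2"), n_participants = 10,
                            seed = 15)  # 10 x 288 trials
  parts <- attr(cohort, "participants")
  ll_true <- dataset_loglik("rlddm", cohort, parts)
  up <- dplyr::mutate(parts, v_coeff = v_coeff * 1.5)
  down <- dplyr::mutate(parts, v_coeff = v_coeff * 0.5)
  expect_gt(ll_true, dataset_loglik("rlddm", cohort, up))
  expect_gt(ll_true, dataset_loglik("rlddm", cohort, down))
})

test_that("an NDT pushed past the fastest response yields -Inf, not an error", {
  cohort <- simulate_cohort(make_design("exp1"), n_participants = 2, seed = 16)
  parts <- attr(cohort, "participants")
  bad <- dplyr::mutate(parts, ndt_int = log(10))
  expect_identical(dataset_loglik("rlddm", cohort, bad), -Inf)
})

test_that("hierarchical fits retain chains x (iter - warmup) draws", {
  cohort <- simulate_cohort(make_design("custom", n_sessions = 1,
                                        trials_per_session = 40,
                                        response_window = 3),
                            n_participants = 4, seed = 17)
  fit <- fit_rlddm(cohort, settings = default_settings(chains = 2, iter = 60,
                                                       warmup = 30, seed = 18))
  expect_equal(dim(fit$draws$draws)[1:2], c(30L, 2L))
  # 4 participants x 8 + 8 group means + 8 group SDs
  expect_equal(dim(fit$draws$draws)[3], 4L * 8L + 16L)
  # bitwise reproducibility under the same seed
  fit2 <- fit_rlddm(cohort, settings = default_settings(chains = 2, iter = 60,
                                                        warmup = 30,
                                                        seed = 18))
  expect_identical(fit$draws$draws, fit2$draws$draws)
  # dispatcher returns the same model type
  fit3 <- sample_posterior("rlddm", cohort,
                           settings = default_settings(chains = 2, iter = 60,
                                                       warmup = 30, seed = 18))
  expect_s3_class(fit3, "rlddm_fit")
  expect_identical(fit3$draws$draws, fit$draws$draws)
})

test_that("group credible intervals shrink as trials per participant grow", {
  widths <- vapply(c(24, 96, 288), function(tps) {
    cohort <- simulate_cohort(make_design("custom", n_sessions = 1,
                                          trials_per_session = tps,
                                          response_window = 3),
                              n_participants = 8, seed = 19)
    fit <- fit_rlddm(cohort, settings = default_settings(chains = 2,
                                                         iter = 500,
                                                         warmup = 250,
                                                         seed = 20))
    gs <- summary(fit, which = "group")
    mean(gs$bci_high[gs$parameter == "mu_v_coeff"] -
           gs$bci_low[gs$parameter == "mu_v_coeff"])
  }, 0)
  expect_lt(widths[3], widths[1])
})
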