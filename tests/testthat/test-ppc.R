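make_small_rlddm_fit <- function() {
  design <- make_design("custom", n_sessions = 1, trials_per_session = 48,
                        response_window = 3)
  cohort <- simulate_cohort(design, n_participants = 5, seed = 40)
  fit <- fit_rlddm(cohort, settings = default_settings(chains = 2, iter = 300,
                                                       warmup = 150,
                                                       seed = 41))
  list(design = design, cohort = cohort, fit = fit)
}

test_that("learning-model predictive cells are context x bin x experiment", {
  sm <- make_small_rlddm_fit()
  ppc <- posterior_predictive(sm$fit, design = sm$design, n_rep = 15,
                              n_bins = 3, seed = 42)
  acc <- ppc[ppc$stat == "accuracy", ]
  expect_setequal(unique(acc$bin), 1:3)
  expect_setequal(unique(paste(acc$context_valence, acc$context_feedback)),
                  c("reward partial", "reward complete", "punishment partial",
                    "punishment complete"))
  expect_true(all(c("experiment_id", "context_valence", "context_feedback",
                    "bin", "stat", "observed", "pred_mean", "pred_low",
                    "pred_high", "inside") %in% names(ppc)))
  expect_true(all(acc$pred_low >= 0 & acc$pred_high <= 1))
  expect_true(all(ppc$pred_low <= ppc$pred_high))
  rts <- ppc[ppc$stat == "rt", ]
  expect_true(all(rts$pred_low > 0))
  expect_error(posterior_predictive(sm$fit, n_rep = 0),
               class = "rlddm_parameter_error")
})

test_that("factorial predictive RT quantiles are ordered in quantile level", {
  truth <- factorial_coeffs(v = c(1.2, 0, 0.3, 0),
                            a = c(log(1.8), 0.1, 0.1, 0),
                            ndt = c(log(0.3), 0.1, -0.05, 0))
  cohort <- simulate_factorial_cohort(truth, n_participants = 6,
                                      trials_per_condition = 25, seed = 43)
  fit <- fit_factorial_ddm(cohort,
                           settings = default_settings(chains = 2, iter = 300,
                                                       warmup = 150,
                                                       seed = 44))
  ppc <- posterior_predictive(fit, n_rep = 15, seed = 45)
  acc <- ppc[ppc$stat == "accuracy", ]
  expect_true(all(acc$observed >= 0 & acc$observed <= 1))
  for (cell in split(ppc, paste(ppc$context_valence, ppc$context_feedback))) {
    for (resp in c("correct", "error")) {
      qs <- cell[grepl(paste0("_", resp, "$"), cell$stat), ]
      if (nrow(qs) > 1) {
        ord <- order(as.numeric(sub("rt_q(\\d+)_.*", "\\1", qs$stat)))
        expect_true(all(diff(qs$observed[ord]) >= 0))
        expect_true(all(diff(qs$pred_mean[ord]) >= 0))
      }
    }
  }
})

test_that("recovery reports carry one row per group parameter", {
  rec <- parameter_recovery(
    make_design("custom", n_sessions = 1, trials_per_session = 24,
                response_window = 3),
    n_participants = 4, seed = 46,
    settings = default_settings(chains = 2, iter = 120, warmup = 60)
  )
  expect_equal(nrow(rec$group), 8)
  expect_true(all(c("parameter", "truth", "estimate", "bci_low", "bci_high",
                    "covered", "rhat") %in% names(rec$group)))
  expect_true(all(rec$group$bci_low <= rec$group$bci_high))
  expect_equal(nrow(rec$individual), 3)
})
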