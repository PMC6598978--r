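test_that("delta-rule worked examples hold exactly", {
  p <- test_relative_params(alpha_c = 0.5, alpha_u = 0.5, alpha_v = 0.5)
  # reward-partial from a zero state: R_c = 1
  r <- update_trial(list(Q_c = 0, Q_u = 0, V = 0), list(R_c = 1), "partial", p)
  expect_equal(r$errors$delta_c, 1)
  expect_equal(r$state$Q_c, 0.5)
  expect_equal(r$errors$delta_V, 0.5)  # (1 + Q_u)/2 - 0 with Q_u = 0
  expect_equal(r$state$V, 0.25)
  expect_equal(r$state$Q_u, 0)
  # complete feedback from a zero state: R_c = 1, R_u = 0
  r2 <- update_trial(list(Q_c = 0, Q_u = 0, V = 0), list(R_c = 1, R_u = 0),
                     "complete", p)
  expect_equal(r2$errors$delta_V, 0.5)  # (1 + 0)/2 - 0
  expect_equal(r2$errors$delta_u, 0)
})

test_that("the unchosen learning rate is inert under partial feedback", {
  p <- test_relative_params(alpha_u = 0.9)
  st <- list(Q_c = 0.4, Q_u = -0.2, V = 0.1)
  r <- update_trial(st, list(R_c = 1), "partial", p)
  expect_identical(r$state$Q_u, st$Q_u)
  # but active under complete feedback
  r2 <- update_trial(st, list(R_c = 1, R_u = 0), "complete", p)
  expect_false(identical(r2$state$Q_u, st$Q_u))
})

test_that("feedback/observation mismatches are rejected", {
  p <- test_relative_params()
  expect_error(update_trial(list(Q_c = 0, Q_u = 0, V = 0), list(R_c = 1),
                            "complete", p), class = "rlddm_validation_error")
  expect_error(update_trial(list(Q_c = 0, Q_u = 0, V = 0),
                            list(R_c = 1, R_u = 0), "partial", p),
               class = "rlddm_validation_error")
})

test_that("prediction errors use the pre-trial context value as reference", {
  p <- test_relative_params(alpha_c = 1, alpha_v = 1)
  st <- list(Q_c = 0, Q_u = 0, V = 0.6)
  r <- update_trial(st, list(R_c = 1), "partial", p)
  expect_equal(r$errors$delta_c, 1 - 0.6 - 0)  # V taken before its update
})

test_that("linking formulas match their closed forms", {
  p <- test_relative_params(a_int = 2, a_coeff = 1, v_coeff = 1.5,
                            ndt_int = log(0.3), ndt_coeff = 0)
  l0 <- link_trial(0, 0, 0, p)
  expect_equal(l0$conflict, 1)
  expect_equal(l0$a, 2)
  expect_equal(l0$v, 0)
  l1 <- link_trial(1, 0, 0, p)  # delta_Q = 1 -> conflict 0.5
  expect_equal(l1$a, 2 * (1 + (0.5 - 1)))
  expect_equal(l1$v, 1.5)
  # null ndt coefficient: ndt independent of V
  expect_equal(link_trial(1, 0, 5, p)$ndt, exp(log(0.3)))
  # threshold bounds and monotonicity in |delta_Q|
  p2 <- test_relative_params(a_int = 2, a_coeff = 0.6)
  dq <- seq(0, 10, by = 0.5)
  a_t <- vapply(dq, function(d) link_trial(d, 0, 0, p2)$a, 0)
  expect_true(all(diff(a_t) <= 0))
  expect_true(all(a_t <= 2 & a_t >= 2 * (1 - 0.6)))
  # ndt strictly decreasing in V for negative coefficient
  p3 <- test_relative_params(ndt_coeff = -0.5)
  ndt <- vapply(seq(-1, 1, 0.2), function(v) link_trial(0, 0, v, p3)$ndt, 0)
  expect_true(all(diff(ndt) < 0))
})

test_that("parameter constraints are enforced", {
  expect_error(test_relative_params(alpha_c = 1.2),
               class = "rlddm_parameter_error")
  expect_error(test_relative_params(a_int = -1),
               class = "rlddm_parameter_error")
  expect_error(test_relative_params(a_coeff = 1.4),
               class = "rlddm_parameter_error")
})

test_that("frozen learning keeps the latent state at zero", {
  p <- test_relative_params(alpha_c = 0, alpha_u = 0, alpha_v = 0)
  tt <- validate_trial_table(tiny_trial_table())
  tr <- forward_pass(tt, p)
  expect_true(all(tr$Q_cor == 0 & tr$Q_inc == 0 & tr$V == 0))
  expect_true(all(tr$conflict == 1))
  expect_true(all(tr$a_t == p$a_int))
  expect_true(all(tr$v_t == 0))
})

test_that("compiled sequential pass agrees with the pure-R reference", {
  set.seed(31)
  for (rep in 1:5) {
    cohort <- simulate_cohort(
      make_design("custom", n_sessions = 2, trials_per_session = 24,
                  response_window = 3),
      n_participants = 1
    )
    p <- test_relative_params(alpha_c = runif(1), alpha_u = runif(1),
                              alpha_v = runif(1))
    tr_cpp <- forward_pass(cohort, p)
    tr_r <- r_reference_trace(cohort, p)
    expect_equal(tr_cpp$Q_cor, tr_r$Q_cor)
    expect_equal(tr_cpp$Q_inc, tr_r$Q_inc)
    expect_equal(tr_cpp$V, tr_r$V)
    expect_equal(tr_cpp$v_t, tr_r$v_t)
    expect_equal(tr_cpp$a_t, tr_r$a_t)
    expect_equal(tr_cpp$ndt_t, tr_r$ndt_t)
  }
})

test_that("linked parameters depend only on past trials", {
  set.seed(55)
  cohort <- simulate_cohort(
    make_design("custom", n_sessions = 1, trials_per_session = 40,
                response_window = 3),
    n_participants = 1
  )
  p <- test_relative_params()
  full <- forward_pass(cohort, p)
  cut <- 25
  # permuting (here: reversing outcomes of) trials after the cut must not
  # change the linked parameters at or before the cut
  perturbed <- cohort
  later <- which(seq_len(nrow(cohort)) > cut)
  perturbed$outcome_chosen[later] <- rev(perturbed$outcome_chosen[later])
  tr2 <- forward_pass(perturbed, p)
  expect_equal(full[seq_len(cut), c("v_t", "a_t", "ndt_t")],
               tr2[seq_len(cut), c("v_t", "a_t", "ndt_t")])
})

test_that("latent values stay within the inductive bounds on random schedules", {
  set.seed(77)
  p_max <- 0
  for (rep in 1:20) {
    n <- 500
    trials <- tibble::tibble(
      experiment_id = "x", participant_id = "p1", session = 1L,
      trial_index = seq_len(n),
      context_valence = sample(c("reward", "punishment"), n, TRUE),
      context_feedback = sample(c("partial", "complete"), n, TRUE),
      correct = sample(0:1, n, TRUE),
      rt = runif(n, 0.3, 2.9),
      outcome_chosen = sample(c(-1, 0, 1), n, TRUE),
      response_window = 3
    )
    trials$outcome_unchosen <- ifelse(trials$context_feedback == "complete",
                                      sample(c(-1, 0, 1), n, TRUE), NA_real_)
    p <- relative_params(runif(1), runif(1), runif(1), 1, 2, runif(1),
                         log(0.3), -0.3)
    # drop the four-context requirement by building contexts directly
    tr <- forward_pass(structure(trials, class = c("trial_table",
                                                   class(trials))), p)
    expect_true(all(abs(tr$V) <= 2))
    expect_true(all(abs(tr$Q_cor) <= 3 & abs(tr$Q_inc) <= 3))
    expect_true(all(tr$conflict > 0 & tr$conflict <= 1))
  }
})
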