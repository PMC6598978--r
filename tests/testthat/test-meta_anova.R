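test_that("cell means are per-participant arithmetic means over contexts", {
  tt <- tiny_trial_table()
  tt$correct <- c(1, 1, 0, 1, 1, 0, 1, 1)
  cm <- cell_means(validate_trial_table(tt))
  expect_equal(nrow(cm), 4)  # four contexts for the single participant
  rw_p <- cm[cm$context_valence == "reward" &
               cm$context_feedback == "partial", ]
  sub <- tt[tt$context_valence == "reward" & tt$context_feedback == "partial", ]
  expect_equal(rw_p$mean_accuracy, mean(sub$correct))
  expect_equal(rw_p$mean_rt, mean(sub$rt))
})

test_that("a participant missing a context is named in the error", {
  tt1 <- tiny_trial_table()
  tt2 <- tiny_trial_table()
  tt2$participant_id <- "p02"
  tt <- rbind(tt1, tt2)
  # p02 responds in only three contexts
  drop <- tt$participant_id == "p02" & tt$context_valence == "punishment" &
    tt$context_feedback == "complete"
  tt$rt[drop] <- NA_real_
  tt$correct[drop] <- NA_real_
  tt$outcome_chosen[drop] <- NA_real_
  tt$outcome_unchosen[drop] <- NA_real_
  expect_error(cell_means(validate_trial_table(tt)), "p02",
               class = "rlddm_validation_error")
})

balanced_cells <- function(n_participants, effects = c(feedback = 0.05),
                           base = 0.7, sd_participant = 0.05,
                           sd_resid = 0.05, experiment = "exp1") {
  grid <- expand.grid(
    participant_id = sprintf("p%03d", seq_len(n_participants)),
    context_valence = c("reward", "punishment"),
    context_feedback = c("partial", "complete"),
    stringsAsFactors = FALSE
  )
  code <- encode_condition(grid$context_valence, grid$context_feedback)
  eff <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  eta <- base + eff("valence") * code$valence +
    eff("feedback") * code$feedback + eff("interaction") * code$interaction
  b <- rnorm(n_participants, 0, sd_participant)
  y <- eta + b[match(grid$participant_id, unique(grid$participant_id))] +
    rnorm(nrow(grid), 0, sd_resid)
  out <- tibble::tibble(
    participant_id = grid$participant_id, experiment_id = experiment,
    context_valence = grid$context_valence,
    context_feedback = grid$context_feedback,
    mean_accuracy = y, mean_rt = y
  )
  class(out) <- c("cell_means", class(out))
  out
}

test_that("a known feedback effect on accuracy is recovered at n = 89", {
  set.seed(30)
  cells <- balanced_cells(89, effects = c(feedback = 0.05))
  fit <- fit_effect_model(cells, response = "accuracy",
                          include = "feedback",
                          settings = default_settings(chains = 2, iter = 1200,
                                                      warmup = 600, seed = 31))
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "beta_feedback"] - 0.05), 0.02)
  expect_gt(s$bci_low[s$parameter == "beta_feedback"], 0)
})

test_that("with one experiment the fit matches the least-squares estimate", {
  set.seed(32)
  cells <- balanced_cells(40, effects = c(valence = 0.06, feedback = -0.02,
                                          interaction = -0.015))
  fit <- fit_effect_model(cells, response = "rt",
                          settings = default_settings(chains = 2, iter = 1500,
                                                      warmup = 750, seed = 33))
  code <- encode_condition(cells$context_valence, cells$context_feedback)
  ols <- coef(lm(cells$mean_rt ~ code$valence + code$feedback +
                   code$interaction))
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "beta_valence"] - ols[[2]]), 0.005)
  expect_lt(abs(s$mean[s$parameter == "beta_feedback"] - ols[[3]]), 0.005)
  expect_lt(abs(s$mean[s$parameter == "beta_interaction"] - ols[[4]]), 0.005)
})

test_that("estimates are invariant to participant row order", {
  set.seed(34)
  cells <- balanced_cells(30, effects = c(feedback = 0.05))
  fit1 <- fit_effect_model(cells, response = "accuracy",
                           include = "feedback",
                           settings = default_settings(chains = 2, iter = 800,
                                                       warmup = 400,
                                                       seed = 35))
  shuffled <- cells[sample(nrow(cells)), ]
  fit2 <- fit_effect_model(shuffled, response = "accuracy",
                           include = "feedback",
                           settings = default_settings(chains = 2, iter = 800,
                                                       warmup = 400,
                                                       seed = 35))
  expect_identical(fit1$summary$mean, fit2$summary$mean)
})

test_that("an empty effect set is rejected", {
  cells <- balanced_cells(10)
  expect_error(fit_effect_model(cells, response = "rt",
                                include = character(0)),
               class = "rlddm_parameter_error")
})
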