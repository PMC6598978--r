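#' Condition coding for the 2x2 design
#'
#' Valence is coded 0 for reward and 1 for punishment; feedback 0 for
#' partial and 1 for complete; the interaction is their product. Intercepts
#' therefore correspond to the reward-partial context.
#'
#' @param valence `"reward"` or `"punishment"` (vectorized).
#' @param feedback `"partial"` or `"complete"` (vectorized).
#' @return A tibble with integer columns `valence`, `feedback`,
#'   `interaction`.
#' @examples
#' encode_condition("reward", "partial")      # (0, 0, 0): the reference cell
#' encode_condition("punishment", "complete") # (1, 1, 1)
#' @export
encode_condition <- function(valence, feedback) {
  if (!all(valence %in% c("reward", "punishment"))) {
    abort("valence must be 'reward' or 'punishment'",
          class = "rlddm_validation_error")
  }
  if (!all(feedback %in% c("partial", "complete"))) {
    abort("feedback must be 'partial' or 'complete'",
          class = "rlddm_validation_error")
  }
  v <- as.integer(valence == "punishment")
  f <- as.integer(feedback == "complete")
  tibble::tibble(valence = v, feedback = f, interaction = v * f)
}

factorial_par_names <- as.vector(outer(
  c("intercept", "valence", "feedback", "interaction"),
  c("v", "a", "ndt"),
  function(eff, p) paste0(p, "_", eff)
))

#' Intercept + effect coefficients of the factorial DDM
#'
#' One intercept and three slopes (valence, feedback, interaction) per DDM
#' parameter, on each parameter's link scale: identity for the drift rate,
#' log for threshold and non-decision time (the log links guarantee
#' positivity for any real coefficients, so reported effects for `a` and
#' `ndt` are on the log scale).
#'
#' @param v,a,ndt Length-4 numeric vectors
#'   `(intercept, valence, feedback, interaction)` for each parameter.
#' @return A `factorial_coeffs` object (3 x 4 matrix).
#' @examples
#' factorial_coeffs(v = c(1.5, 0, 0.4, 0), a = c(log(2), 0.1, 0.1, -0.08),
#'                  ndt = c(log(0.3), 0.08, -0.07, 0))
#' @export
factorial_coeffs <- function(v, a, ndt) {
  stopifnot(length(v) == 4, length(a) == 4, length(ndt) == 4)
  m <- rbind(v = as.numeric(v), a = as.numeric(a), ndt = as.numeric(ndt))
  colnames(m) <- c("intercept", "valence", "feedback", "interaction")
  structure(m, class = c("factorial_coeffs", class(m)))
}

#' Decode condition-specific DDM parameters
#'
#' Applies the linear predictor
#' `eta_p = intercept + beta_valence * valence + beta_feedback * feedback +
#' beta_interaction * interaction` and the link inverses (`v = eta_v`,
#' `a = exp(eta_a)`, `ndt = exp(eta_ndt)`), so the decoded threshold and
#' non-decision time are strictly positive for every condition.
#'
#' @param coeffs A [factorial_coeffs()] object.
#' @param code A single-row condition code from [encode_condition()].
#' @return A [ddm_params()] object.
#' @export
condition_ddm_params <- function(coeffs, code) {
  stopifnot(inherits(coeffs, "factorial_coeffs"))
  x <- c(1, code$valence[1], code$feedback[1], code$interaction[1])
  eta <- as.numeric(coeffs %*% x)
  ddm_params(v = eta[1], a = exp(eta[2]), ndt = exp(eta[3]))
}

factorial_participant_data <- function(data) {
  ids <- unique(data$participant_id)
  lapply(ids, function(id) {
    d <- data[data$participant_id == id & !is.na(data$rt), ]
    code <- encode_condition(d$context_valence, d$context_feedback)
    list(
      id = id,
      experiment = d$experiment_id[1],
      rt = as.numeric(d$rt),
      boundary = ifelse(d$correct == 1, 1L, -1L),
      X = cbind(1, code$valence, code$feedback, code$interaction),
      min_rt = min(d$rt)
    )
  })
}

# theta: 12-vector ordered as factorial_par_names (v block, a block, ndt block)
factorial_loglik_one <- function(fd, theta) {
  v <- as.numeric(fd$X %*% theta[1:4])
  a <- exp(as.numeric(fd$X %*% theta[5:8]))
  ndt <- exp(as.numeric(fd$X %*% theta[9:12]))
  cpp_wfpt_loglik(fd$rt, fd$boundary, v, a, ndt, 0.5)
}

#' Fit the condition-coded factorial DDM
#'
#' Intercept plus valence, feedback and interaction slopes for each DDM
#' parameter, with participant coefficient vectors drawn around
#' experiment-level means and experiment-level means around dataset-level
#' means (a three-level hierarchy; with a single experiment the middle
#' level collapses and participant vectors are drawn around the dataset
#' means directly). Priors: dataset-level means normal(0, 2) for intercepts
#' and normal(0, 1) for slopes on the link scales; all SDs
#' half-normal(0, 1).
#'
#' @param data A validated [trial_table]; may span several experiments.
#' @param settings Sampler settings ([default_settings()]).
#' @return A `factorial_fit`; `summary()` reports the dataset-level effect
#'   posteriors (`mu_v_valence`, ...), on the link scales.
#' @export
fit_factorial_ddm <- function(data, settings = default_settings(chains = 4,
                                                                iter = 2000,
                                                                warmup = 1000)) {
  data <- validate_trial_table(data)
  fds <- factorial_participant_data(data)
  J <- length(fds)
  group <- vapply(fds, `[[`, "", "experiment")
  prior_sd <- rep(c(2, 1, 1, 1), times = 3)  # intercepts wide, slopes unit
  prior_mean <- rep(0, 12)
  loglik_fun <- function(j, theta) factorial_loglik_one(fds[[j]], theta)
  scan_fun <- function(j, theta_j, ll_j, gmu_row, sigma) {
    fd <- fds[[j]]
    out <- cpp_factorial_slice_scan(fd$rt, fd$boundary, fd$X, theta_j, ll_j,
                                    gmu_row, sigma, 1.5, 6L)
    list(theta = out[1:12], ll = out[13])
  }
  batch_loglik <- function(theta) cpp_factorial_loglik_batch(fds, theta)
  init_fun <- function(j) {
    c(rnorm(1, 1, 0.3), rnorm(3, 0, 0.05),                    # v block
      rnorm(1, log(1.5), 0.2), rnorm(3, 0, 0.05),             # a block
      log(0.6 * fds[[j]]$min_rt) + rnorm(1, 0, 0.1),
      rnorm(3, 0, 0.02))                                      # ndt block
  }
  draws <- fit_hierarchical_mwg(
    loglik_fun, J = J, K = 12L, group = group,
    prior_mean = prior_mean, prior_sd = prior_sd, init_fun = init_fun,
    settings = settings, par_names = factorial_par_names,
    participant_ids = vapply(fds, `[[`, "", "id"),
    scan_fun = scan_fun, batch_loglik = batch_loglik
  )
  structure(list(draws = draws, model = "factorial", data = data,
                 participant_ids = vapply(fds, `[[`, "", "id"),
                 experiments = group, par_names = factorial_par_names,
                 settings = settings),
            class = c("factorial_fit", "rlddm_model_fit"))
}

#' Simulate a cohort from known factorial coefficients
#'
#' Companion generator for factorial-model recovery studies: participant
#' coefficient vectors are drawn normally around the supplied coefficients,
#' each trial's choice/RT is sampled from the condition-decoded DDM, and
#' outcomes are filled in from the task contingencies so the result is a
#' valid [trial_table].
#'
#' @param coeffs A [factorial_coeffs()] object (group-level truth).
#' @param n_participants Number of agents.
#' @param trials_per_condition Trials per context (total = 4x this).
#' @param participant_sd SD of participant coefficients around the group
#'   values (link scale).
#' @param response_window Seconds.
#' @param seed Optional seed.
#' @param experiment_id Label for the simulated experiment.
#' @return A validated [trial_table] with attribute `coeffs`.
#' @export
simulate_factorial_cohort <- function(coeffs, n_participants = 20,
                                      trials_per_condition = 40,
                                      participant_sd = 0.15,
                                      response_window = 3, seed = NULL,
                                      experiment_id = "simfac") {
  stopifnot(inherits(coeffs, "factorial_coeffs"))
  if (!is.null(seed)) set.seed(seed)
  design <- make_design(experiment_id, n_sessions = 1,
                        trials_per_session = 4 * trials_per_condition,
                        response_window = response_window)
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    th <- as.numeric(coeffs) + rnorm(12, 0, participant_sd)
    cf_i <- factorial_coeffs(th[c(1, 4, 7, 10)], th[c(2, 5, 8, 11)],
                             th[c(3, 6, 9, 12)])
    sched <- draw_outcome_schedule(design)
    code <- encode_condition(sched$context_valence, sched$context_feedback)
    n <- nrow(sched)
    correct <- rt <- rep(NA_real_, n)
    for (cond in unique(paste(code$valence, code$feedback))) {
      idx <- which(paste(code$valence, code$feedback) == cond)
      p <- condition_ddm_params(cf_i, code[idx[1], ])
      sims <- simulate_ddm(length(idx), p, dt = 1e-3,
                           max_t = response_window + 5)
      ok <- !is.na(sims$rt) & sims$rt <= response_window
      correct[idx[ok]] <- as.numeric(sims$boundary[ok] == "upper")
      rt[idx[ok]] <- sims$rt[ok]
    }
    responded <- !is.na(rt)
    chosen <- ifelse(correct == 1, sched$outcome_best, sched$outcome_worst)
    unchosen <- ifelse(correct == 1, sched$outcome_worst, sched$outcome_best)
    rows[[i]] <- tibble::tibble(
      experiment_id = experiment_id,
      participant_id = sprintf("sim%02d", i),
      session = as.integer(sched$session),
      trial_index = as.integer(sched$trial_index),
      context_valence = sched$context_valence,
      context_feedback = sched$context_feedback,
      correct = ifelse(responded, correct, NA_real_),
      rt = rt,
      outcome_chosen = ifelse(responded, chosen, NA_real_),
      outcome_unchosen = ifelse(responded &
                                  sched$context_feedback == "complete",
                                unchosen, NA_real_),
      response_window = response_window
    )
  }
  out <- validate_trial_table(dplyr::bind_rows(rows), design = design)
  attr(out, "coeffs") <- coeffs
  out
}
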