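#' Group-level generating distributions for simulated cohorts
#'
#' Defaults describe a realistic cohort for the unit-stakes task: learning
#' rates spread around 0.2 (logit-normal), drift coefficient around 1.2,
#' threshold intercept around 2 evidence units, threshold-conflict
#' coefficient around 0.7, non-decision time around 0.3 s, and a negative
#' context-value coefficient of -0.35 on the log-NDT scale (the
#' slower-under-punishment signature). Individual parameters are drawn
#' independently per participant: logit-normal for the rates and `a_coeff`,
#' log-normal for `a_int`, normal for the remaining coefficients.
#'
#' @param means Named numeric vector of group means on the unconstrained
#'   (sampling) scale: `alpha_c`, `alpha_u`, `alpha_v` and `a_coeff` as
#'   logits, `a_int` as a log, `v_coeff`, `ndt_int` (log-seconds) and
#'   `ndt_coeff` as-is.
#' @param sds Named numeric vector of group standard deviations on the same
#'   scale.
#' @return A `generating_params` object (list with `means`, `sds`).
#' @export
generating_params <- function(means = NULL, sds = NULL) {
  default_means <- c(alpha_c = qlogis(0.2), alpha_u = qlogis(0.2),
                     alpha_v = qlogis(0.25), v_coeff = 1.2,
                     a_int = log(2), a_coeff = qlogis(0.7),
                     ndt_int = log(0.3), ndt_coeff = -0.35)
  default_sds <- c(alpha_c = 0.5, alpha_u = 0.5, alpha_v = 0.5,
                   v_coeff = 0.3, a_int = 0.1, a_coeff = 0.5,
                   ndt_int = 0.15, ndt_coeff = 0.1)
  m <- default_means
  s <- default_sds
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  structure(list(means = m, sds = s), class = "generating_params")
}

# unconstrained (sampling) scale -> natural scale, positional fast path for
# the sampler hot loop (order: alpha_c, alpha_u, alpha_v, v_coeff, a_int,
# a_coeff, ndt_int, ndt_coeff)
constrain_relative_vec <- function(th) {
  c(plogis(th[1L]), plogis(th[2L]), plogis(th[3L]), th[4L],
    exp(th[5L]), plogis(th[6L]), th[7L], th[8L])
}

# unconstrained (sampling) scale <-> natural scale
constrain_relative <- function(theta) {
  c(alpha_c = plogis(theta[["alpha_c"]]),
    alpha_u = plogis(theta[["alpha_u"]]),
    alpha_v = plogis(theta[["alpha_v"]]),
    v_coeff = theta[["v_coeff"]],
    a_int = exp(theta[["a_int"]]),
    a_coeff = plogis(theta[["a_coeff"]]),
    ndt_int = theta[["ndt_int"]],
    ndt_coeff = theta[["ndt_coeff"]])
}

#' Draw per-participant parameters from the group distributions
#'
#' @param n Number of participants.
#' @param group A [generating_params()] object.
#' @return A tibble with `participant_id` and one column per natural-scale
#'   parameter, plus matching `raw_*` columns on the unconstrained scale.
#' @export
draw_participant_params <- function(n, group = generating_params()) {
  K <- length(group$means)
  raw <- matrix(rnorm(n * K, rep(group$means, each = n),
                      rep(group$sds, each = n)), n, K,
                dimnames = list(NULL, names(group$means)))
  nat <- t(apply(raw, 1, function(r) constrain_relative(as.list(r))))
  out <- tibble::as_tibble(as.data.frame(nat))
  raw_df <- tibble::as_tibble(as.data.frame(raw))
  names(raw_df) <- paste0("raw_", names(raw_df))
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("sim%02d", seq_len(n))),
    out, raw_df
  )
}

#' Simulate a cohort of learning agents on the factorial task
#'
#' For each participant: draw an outcome schedule, run the learning model
#' forward, and sample each choice and response time from the DDM at the
#' trial's linked parameters. The chosen cue's outcome is always revealed
#' (and drives the chosen-option update); under complete feedback the
#' forgone outcome is revealed too. Decisions slower than the response
#' window are recorded as non-responses (no feedback, no update).
#'
#' @param design A [make_design()] object.
#' @param params Either a [generating_params()] object (participants drawn
#'   from the group distributions) or a tibble of per-participant
#'   natural-scale parameters as returned by [draw_participant_params()].
#' @param n_participants Number of agents (ignored when `params` is a
#'   per-participant tibble).
#' @param seed Optional integer seed (sets R's RNG).
#' @param dt Euler step for the within-trial diffusion (default 1e-4 s for a
#'   close match to the analytic likelihood used in fitting).
#' @param reset_per_session Reset learning at session boundaries (default
#'   TRUE; each session introduces new cue symbols).
#' @return A validated [trial_table] with ground-truth columns
#'   (`true_Q_cor`, `true_Q_inc`, `true_V`, `true_delta_Q`, `true_v_t`,
#'   `true_a_t`, `true_ndt_t`) and the per-participant generating
#'   parameters in `attr(, "participants")`.
#' @examples
#' cohort <- simulate_cohort(make_design("exp1"), n_participants = 2, seed = 1)
#' dplyr::count(cohort, context_valence, context_feedback)
#' @export
simulate_cohort <- function(design, params = generating_params(),
                            n_participants = 20, seed = NULL, dt = 1e-4,
                            reset_per_session = TRUE) {
  if (!inherits(design, "task_design")) {
    abort("design must be a task_design", class = "rlddm_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (inherits(params, "generating_params")) {
    participants <- draw_participant_params(n_participants, params)
  } else {
    participants <- tibble::as_tibble(params)
    if (!all(relative_param_names %in% names(participants))) {
      abort(paste0("per-participant params need columns: ",
                   paste(relative_param_names, collapse = ", ")),
            class = "rlddm_parameter_error")
    }
    if (!"participant_id" %in% names(participants)) {
      participants$participant_id <-
        sprintf("sim%02d", seq_len(nrow(participants)))
    }
  }
  rows <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    p_nat <- as_relative_params(participants[i, relative_param_names])
    sched <- draw_outcome_schedule(design)
    m <- cpp_sim_agent(
      as.integer(sched$session),
      context_index(sched$context_valence, sched$context_feedback),
      as.integer(sched$context_feedback == "complete"),
      as.numeric(sched$outcome_best),
      as.numeric(sched$outcome_worst),
      params_vec(p_nat), design$response_window, dt, reset_per_session
    )
    rows[[i]] <- tibble::tibble(
      experiment_id = design$experiment_id,
      participant_id = participants$participant_id[i],
      session = as.integer(sched$session),
      trial_index = as.integer(sched$trial_index),
      context_valence = sched$context_valence,
      context_feedback = sched$context_feedback,
      correct = m[, "correct"],
      rt = m[, "rt"],
      outcome_chosen = m[, "outcome_chosen"],
      outcome_unchosen = m[, "outcome_unchosen"],
      response_window = design$response_window,
      true_Q_cor = m[, "Q_cor"],
      true_Q_inc = m[, "Q_inc"],
      true_V = m[, "V"],
      true_delta_Q = m[, "delta_Q"],
      true_v_t = m[, "v_t"],
      true_a_t = m[, "a_t"],
      true_ndt_t = m[, "ndt_t"]
    )
  }
  out <- validate_trial_table(dplyr::bind_rows(rows), design = design)
  attr(out, "participants") <- participants
  out
}
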