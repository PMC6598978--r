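#' Parameters of the context-dependent learning + diffusion model
#'
#' The learning side carries three learning rates: `alpha_c` for the chosen
#' option (updated under both feedback regimes), `alpha_u` for the unchosen
#' option (updated only under complete feedback), and `alpha_v` for the
#' context value `V`, the learned reference point against which both option
#' prediction errors are computed. The linking side maps the latent learning
#' state to the trial's DDM parameters:
#'
#' * drift: `v_t = v_coeff * (Q_cor - Q_inc)`;
#' * threshold: `a_t = a_int * (1 + a_coeff * (conflict - 1))` with
#'   `conflict = 1 / (|Q_cor - Q_inc| + 1)`, so `a_t` ranges over
#'   `[a_int * (1 - a_coeff), a_int]`;
#' * non-decision time: `ndt_t = exp(ndt_int + ndt_coeff * V)` (log link
#'   keeps it positive; a negative `ndt_coeff` slows responding in
#'   punishment contexts, where `V` goes negative).
#'
#' @param alpha_c,alpha_u,alpha_v Learning rates in `[0, 1]`.
#' @param v_coeff Drift-rate coefficient (unconstrained).
#' @param a_int Threshold intercept, > 0.
#' @param a_coeff Threshold (conflict) coefficient in `[0, 1]`.
#' @param ndt_int Non-decision-time intercept, log-seconds.
#' @param ndt_coeff Non-decision-time (context value) coefficient.
#' @return An object of class `relative_params`.
#' @examples
#' relative_params(alpha_c = 0.2, alpha_u = 0.15, alpha_v = 0.25,
#'                 v_coeff = 1.2, a_int = 2, a_coeff = 0.7,
#'                 ndt_int = log(0.3), ndt_coeff = -0.35)
#' @export
relative_params <- function(alpha_c, alpha_u, alpha_v, v_coeff, a_int,
                            a_coeff, ndt_int, ndt_coeff) {
  rates <- c(alpha_c = alpha_c, alpha_u = alpha_u, alpha_v = alpha_v)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    abort("learning rates must lie in [0, 1]", class = "rlddm_parameter_error")
  }
  if (!is.finite(a_int) || a_int <= 0) {
    abort("a_int must be > 0", class = "rlddm_parameter_error")
  }
  if (!is.finite(a_coeff) || a_coeff < 0 || a_coeff > 1) {
    abort("a_coeff must lie in [0, 1]", class = "rlddm_parameter_error")
  }
  structure(list(alpha_c = alpha_c, alpha_u = alpha_u, alpha_v = alpha_v,
                 v_coeff = v_coeff, a_int = a_int, a_coeff = a_coeff,
                 ndt_int = ndt_int, ndt_coeff = ndt_coeff),
            class = "relative_params")
}

#' @export
print.relative_params <- function(x, ...) {
  cat("<relative_params>\n")
  cat("  learning rates: alpha_c =", format(x$alpha_c),
      " alpha_u =", format(x$alpha_u), " alpha_v =", format(x$alpha_v), "\n")
  cat("  links: v_coeff =", format(x$v_coeff), " a_int =", format(x$a_int),
      " a_coeff =", format(x$a_coeff), "\n")
  cat("         ndt_int =", format(x$ndt_int), " ndt_coeff =",
      format(x$ndt_coeff), "\n")
  invisible(x)
}

relative_param_names <- c("alpha_c", "alpha_u", "alpha_v", "v_coeff",
                          "a_int", "a_coeff", "ndt_int", "ndt_coeff")

as_relative_params <- function(x) {
  if (inherits(x, "relative_params")) return(x)
  x <- as.list(x)
  if (!all(relative_param_names %in% names(x))) {
    abort(paste0("need all of: ", paste(relative_param_names, collapse = ", ")),
          class = "rlddm_parameter_error")
  }
  do.call(relative_params, x[relative_param_names])
}

params_vec <- function(p) {
  p <- as_relative_params(p)
  unlist(p[relative_param_names], use.names = FALSE)
}

#' One learning update
#'
#' Applies the delta-rule updates for a single trial, using the *pre-trial*
#' context value `V` as the reference point for both option prediction
#' errors. The chosen option's value moves by `alpha_c * (R_c - V - Q_c)`;
#' under complete feedback the unchosen option moves by
#' `alpha_u * (R_u - V - Q_u)` and the context prediction error is
#' `(R_c + R_u)/2 - V`; under partial feedback the unchosen value is inert
#' and the unseen forgone outcome is replaced by the unchosen option's
#' current expectation, `delta_V = (R_c + Q_u)/2 - V`. Finally
#' `V <- V + alpha_v * delta_V`.
#'
#' This pure-R single-step implementation is the reference for the compiled
#' sequential pass used in fitting; the two are cross-checked in the test
#' suite.
#'
#' @param state Named list/vector with `Q_c` (chosen option value), `Q_u`
#'   (unchosen option value) and `V` (context value).
#' @param observation Named list/vector with `R_c` (chosen outcome) and,
#'   under complete feedback only, `R_u` (forgone outcome).
#' @param feedback `"partial"` or `"complete"`.
#' @param params A [relative_params()] object.
#' @return List with `state` (updated `Q_c`, `Q_u`, `V`) and `errors`
#'   (`delta_c`, `delta_u` — `NA` under partial feedback — and `delta_V`).
#' @examples
#' p <- relative_params(0.5, 0.5, 0.5, 1, 2, 0.5, log(0.3), 0)
#' update_trial(list(Q_c = 0, Q_u = 0, V = 0), list(R_c = 1), "partial", p)
#' @export
update_trial <- function(state, observation, feedback = c("partial", "complete"),
                         params) {
  feedback <- match.arg(feedback)
  params <- as_relative_params(params)
  state <- as.list(state)
  observation <- as.list(observation)
  has_ru <- !is.null(observation$R_u) && !is.na(observation$R_u)
  if (feedback == "complete" && !has_ru) {
    abort("complete feedback requires the forgone outcome R_u",
          class = "rlddm_validation_error")
  }
  if (feedback == "partial" && has_ru) {
    abort("partial feedback must not carry a forgone outcome R_u",
          class = "rlddm_validation_error")
  }
  V0 <- state$V
  delta_c <- observation$R_c - V0 - state$Q_c
  Q_c <- state$Q_c + params$alpha_c * delta_c
  if (feedback == "complete") {
    delta_u <- observation$R_u - V0 - state$Q_u
    Q_u <- state$Q_u + params$alpha_u * delta_u
    delta_V <- (observation$R_c + observation$R_u) / 2 - V0
  } else {
    delta_u <- NA_real_
    Q_u <- state$Q_u
    delta_V <- (observation$R_c + Q_u) / 2 - V0
  }
  V <- V0 + params$alpha_v * delta_V
  list(state = list(Q_c = Q_c, Q_u = Q_u, V = V),
       errors = list(delta_c = delta_c, delta_u = delta_u, delta_V = delta_V))
}

#' Link the latent learning state to the trial's DDM parameters
#'
#' Evaluated on the values held *before* the trial's outcome (the decision
#' precedes the feedback).
#'
#' @param Q_cor,Q_inc Learned values of the correct and incorrect option.
#' @param V Context value.
#' @param params A [relative_params()] object.
#' @return List with `v`, `a`, `ndt` (and the intermediate `delta_Q`,
#'   `conflict`); vectorized over the state arguments.
#' @examples
#' p <- relative_params(0.2, 0.2, 0.2, 1.2, 2, 1, log(0.3), -0.35)
#' link_trial(Q_cor = 1, Q_inc = 0, V = 0.5, params = p)
#' @export
link_trial <- function(Q_cor, Q_inc, V, params) {
  params <- as_relative_params(params)
  delta_Q <- Q_cor - Q_inc
  conflict <- 1 / (abs(delta_Q) + 1)
  list(
    v = params$v_coeff * delta_Q,
    a = params$a_int * (1 + params$a_coeff * (conflict - 1)),
    ndt = exp(params$ndt_int + params$ndt_coeff * V),
    delta_Q = delta_Q,
    conflict = conflict
  )
}

#' Run the learning model forward over one participant's trials
#'
#' Tracks the four context states independently (with `Q = V = 0` at the
#' start of each session when `reset_per_session = TRUE`, the default, since
#' each session introduces new cue symbols), records the pre-update latent
#' state and linked DDM parameters for every trial, then applies the
#' learning update. Non-response trials (`correct` missing) contribute no
#' update and carry `NA` prediction errors.
#'
#' @param trials A [trial_table] subset for a single participant, ordered by
#'   session then `trial_index`.
#' @param params A [relative_params()] object.
#' @param reset_per_session Reset `Q` and `V` at each session start?
#' @return A tibble (`latent_trace`) aligned row-for-row with `trials`:
#'   `Q_cor`, `Q_inc`, `V`, `delta_Q`, `conflict`, `v_t`, `a_t`, `ndt_t`,
#'   `delta_c`, `delta_u`, `delta_V`.
#' @export
forward_pass <- function(trials, params, reset_per_session = TRUE) {
  params <- as_relative_params(params)
  if (length(unique(trials$participant_id)) > 1) {
    abort("forward_pass expects a single participant",
          class = "rlddm_validation_error")
  }
  key <- paste(trials$session, trials$trial_index)
  if (anyDuplicated(key)) {
    abort("duplicated trial indices", class = "rlddm_validation_error")
  }
  ord <- order(trials$session, trials$trial_index)
  if (any(ord != seq_along(ord))) {
    abort("trials must be ordered by session then trial_index",
          class = "rlddm_validation_error")
  }
  m <- cpp_forward_pass(
    as.integer(trials$session),
    context_index(trials$context_valence, trials$context_feedback),
    as.integer(trials$correct),
    as.numeric(trials$outcome_chosen),
    ifelse(is.na(trials$outcome_unchosen), 0, trials$outcome_unchosen),
    as.integer(trials$context_feedback == "complete"),
    params_vec(params), reset_per_session
  )
  out <- tibble::as_tibble(as.data.frame(m))
  class(out) <- c("latent_trace", class(out))
  out
}

# stable 0-based context index used by the compiled state tracker
context_index <- function(valence, feedback) {
  as.integer((valence == "punishment") * 2L + (feedback == "complete"))
}
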