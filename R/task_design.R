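#' Factorial task designs
#'
#' Builds the 2x2 (valence x feedback) probabilistic instrumental learning
#' task design. The four fixed-pair contexts are reward-partial,
#' reward-complete, punishment-partial and punishment-complete. In reward
#' contexts the best cue pays `+magnitude` with probability 0.75 (else 0) and
#' the worst cue with probability 0.25; in punishment contexts the best cue
#' pays `-magnitude` with probability 0.25 (else 0) and the worst cue with
#' probability 0.75. Trials are divided evenly among the four contexts.
#'
#' Presets `"exp1"`--`"exp4"` reproduce the four study layouts:
#' sessions 2/3/3/2, trials per session 80/96/96/80, response windows
#' 3/3/3/1.5 seconds.
#'
#' @param experiment_id One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`, or any
#'   label when a full custom spec is supplied.
#' @param n_sessions,trials_per_session,response_window Custom design fields;
#'   all three must be given together to override a preset.
#' @param p_best,p_worst Payoff probabilities of the best and worst cue
#'   (defaults 0.75/0.25; interpreted on the gain for reward contexts and on
#'   the loss for punishment contexts, so the punishment best cue *loses*
#'   with probability `1 - p_best`).
#' @param outcome_magnitude Absolute payoff in points (default 1).
#' @return A `task_design` object: list with the design fields and a
#'   `contexts` tibble of four rows (`valence`, `feedback`, `p_outcome_best`,
#'   `p_outcome_worst`, `outcome_magnitude`), where `p_outcome_*` is the
#'   probability that the cue's non-zero payoff occurs.
#' @examples
#' make_design("exp1")
#' make_design("pilot", n_sessions = 1, trials_per_session = 40,
#'             response_window = 3)
#' @export
make_design <- function(experiment_id, n_sessions = NULL,
                        trials_per_session = NULL, response_window = NULL,
                        p_best = 0.75, p_worst = 0.25, outcome_magnitude = 1) {
  presets <- list(
    exp1 = list(n_sessions = 2L, trials_per_session = 80L, response_window = 3.0),
    exp2 = list(n_sessions = 3L, trials_per_session = 96L, response_window = 3.0),
    exp3 = list(n_sessions = 3L, trials_per_session = 96L, response_window = 3.0),
    exp4 = list(n_sessions = 2L, trials_per_session = 80L, response_window = 1.5)
  )
  custom <- !is.null(n_sessions) || !is.null(trials_per_session) ||
    !is.null(response_window)
  if (custom) {
    if (is.null(n_sessions) || is.null(trials_per_session) ||
        is.null(response_window)) {
      abort("a custom design needs n_sessions, trials_per_session and response_window",
            class = "rlddm_parameter_error")
    }
    d <- list(n_sessions = as.integer(n_sessions),
              trials_per_session = as.integer(trials_per_session),
              response_window = as.numeric(response_window))
  } else {
    if (!experiment_id %in% names(presets)) {
      abort(paste0("unknown design preset '", experiment_id,
                   "'; supply a custom spec or one of exp1..exp4"),
            class = "rlddm_parameter_error")
    }
    d <- presets[[experiment_id]]
  }
  if (d$trials_per_session %% 4 != 0) {
    abort("trials_per_session must be divisible by 4 (even context split)",
          class = "rlddm_parameter_error")
  }
  contexts <- tibble::tibble(
    valence = rep(c("reward", "punishment"), each = 2),
    feedback = rep(c("partial", "complete"), times = 2),
    # probability that the non-zero payoff (gain or loss) occurs
    p_outcome_best = c(p_best, p_best, 1 - p_best, 1 - p_best),
    p_outcome_worst = c(p_worst, p_worst, 1 - p_worst, 1 - p_worst),
    outcome_magnitude = outcome_magnitude
  )
  structure(c(list(experiment_id = experiment_id), d,
              list(contexts = contexts)),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design> ", x$experiment_id, ": ", x$n_sessions, " session(s) x ",
      x$trials_per_session, " trials, response window ", x$response_window,
      " s\n", sep = "")
  print(x$contexts)
  invisible(x)
}

context_payoff <- function(valence, magnitude) {
  ifelse(valence == "reward", magnitude, -magnitude)
}

#' Draw a per-trial outcome schedule
#'
#' Realizes the potential payoffs of *both* cues on every trial of every
#' session, drawn independently from each cue's Bernoulli payoff
#' distribution (i.i.d. across trials). Contexts are interleaved in a random
#' order within each session, with `trials_per_session / 4` trials per
#' context. Uses R's RNG; `set.seed()` first for a reproducible schedule.
#'
#' @param design A [make_design()] object.
#' @return A tibble with one row per trial: `session`, `trial_index`,
#'   `context_valence`, `context_feedback`, `outcome_best`, `outcome_worst`
#'   (points; the best cue is the reward-maximizing or punishment-minimizing
#'   one).
#' @examples
#' set.seed(7)
#' sched <- draw_outcome_schedule(make_design("exp1"))
#' head(sched)
#' @export
draw_outcome_schedule <- function(design) {
  if (!inherits(design, "task_design")) {
    abort("design must be a task_design", class = "rlddm_parameter_error")
  }
  per_ctx <- design$trials_per_session %/% 4L
  out <- vector("list", design$n_sessions)
  for (s in seq_len(design$n_sessions)) {
    ctx_idx <- sample(rep(1:4, per_ctx))  # random interleaving
    ctx <- design$contexts[ctx_idx, ]
    pay <- context_payoff(ctx$valence, ctx$outcome_magnitude)
    out[[s]] <- tibble::tibble(
      session = s,
      trial_index = seq_len(design$trials_per_session),
      context_valence = ctx$valence,
      context_feedback = ctx$feedback,
      # + 0 normalizes IEEE negative zeros from loss payoffs
      outcome_best = pay * rbinom(nrow(ctx), 1, ctx$p_outcome_best) + 0,
      outcome_worst = pay * rbinom(nrow(ctx), 1, ctx$p_outcome_worst) + 0
    )
  }
  dplyr::bind_rows(out)
}
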