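# Small in-code fixtures shared across the test files.

# a minimal well-formed trial table: one participant, one session,
# two trials in each of the four contexts
tiny_trial_table <- function(window = 3) {
  ctx <- expand.grid(
    context_valence = c("reward", "punishment"),
    context_feedback = c("partial", "complete"),
    rep = 1:2, stringsAsFactors = FALSE
  )
  n <- nrow(ctx)
  tibble::tibble(
    experiment_id = "exp1",
    participant_id = "p01",
    session = 1L,
    trial_index = seq_len(n),
    context_valence = ctx$context_valence,
    context_feedback = ctx$context_feedback,
    correct = rep(c(1, 0), length.out = n),
    rt = seq(0.4, by = 0.1, length.out = n),
    outcome_chosen = rep(c(1, 0, -1, 0), length.out = n),
    outcome_unchosen = ifelse(ctx$context_feedback == "complete", 0, NA_real_),
    response_window = window
  )
}

# reference learning-rate set used across RELATIVE tests
test_relative_params <- function(...) {
  defaults <- list(alpha_c = 0.3, alpha_u = 0.2, alpha_v = 0.25,
                   v_coeff = 1.2, a_int = 2, a_coeff = 0.7,
                   ndt_int = log(0.3), ndt_coeff = -0.35)
  args <- utils::modifyList(defaults, list(...))
  do.call(relative_params, args)
}

# run the pure-R single-step reference implementation over a trial sequence,
# independent of the compiled sequential pass
r_reference_trace <- function(trials, params) {
  states <- list()
  key0 <- function(s, c) paste(s, c)
  out <- vector("list", nrow(trials))
  cur_session <- trials$session[1]
  for (i in seq_len(nrow(trials))) {
    if (trials$session[i] != cur_session) {
      states <- list()  # session reset
      cur_session <- trials$session[i]
    }
    ck <- paste(trials$context_valence[i], trials$context_feedback[i])
    st <- states[[ck]] %||% list(Q_cor = 0, Q_inc = 0, V = 0)
    lk <- link_trial(st$Q_cor, st$Q_inc, st$V, params)
    out[[i]] <- tibble::tibble(Q_cor = st$Q_cor, Q_inc = st$Q_inc, V = st$V,
                               v_t = lk$v, a_t = lk$a, ndt_t = lk$ndt)
    if (!is.na(trials$correct[i])) {
      chose_correct <- trials$correct[i] == 1
      upd_state <- list(
        Q_c = if (chose_correct) st$Q_cor else st$Q_inc,
        Q_u = if (chose_correct) st$Q_inc else st$Q_cor,
        V = st$V
      )
      obs <- list(R_c = trials$outcome_chosen[i])
      fb <- trials$context_feedback[i]
      if (fb == "complete") obs$R_u <- trials$outcome_unchosen[i]
      upd <- update_trial(upd_state, obs, fb, params)
      st <- list(
        Q_cor = if (chose_correct) upd$state$Q_c else upd$state$Q_u,
        Q_inc = if (chose_correct) upd$state$Q_u else upd$state$Q_c,
        V = upd$state$V
      )
      states[[ck]] <- st
    }
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
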