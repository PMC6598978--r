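#' Participant x context cell means
#'
#' Mean accuracy and mean RT over responded trials, one row per participant
#' per context (four rows per participant, pooled over sessions).
#'
#' @param data A validated [trial_table].
#' @return A `cell_means` tibble: `participant_id`, `experiment_id`,
#'   `context_valence`, `context_feedback`, `mean_accuracy`, `mean_rt`.
#' @export
cell_means <- function(data) {
  data <- validate_trial_table(data)
  out <- data |>
    dplyr::filter(!is.na(rt)) |>
    dplyr::group_by(participant_id, experiment_id, context_valence,
                    context_feedback) |>
    dplyr::summarise(mean_accuracy = mean(correct), mean_rt = mean(rt),
                     .groups = "drop")
  n_ctx <- table(out$participant_id)
  bad <- names(n_ctx)[n_ctx != 4]
  if (length(bad) > 0) {
    abort(paste0("participant(s) missing a context cell: ",
                 paste(bad, collapse = ", ")),
          class = "rlddm_validation_error")
  }
  class(out) <- c("cell_means", class(out))
  out
}

#' Bayesian effect estimation on cell means
#'
#' Gaussian hierarchical linear model on the participant x context cell
#' means: `response = intercept + beta_V * valence + beta_F * feedback +
#' beta_I * interaction (+ experiment fixed effects) + participant random
#' intercept + residual`, with the condition coding of
#' [encode_condition()] (reward-partial is the reference cell; experiment
#' fixed effects use the first experiment as reference). The participant
#' random intercept is marginalized analytically, leaving the effect
#' coefficients, the residual SD and the random-intercept SD to the
#' Metropolis-within-Gibbs engine. Priors: coefficients normal(0, 10); both
#' SDs half-normal(0, 1).
#'
#' The study's favored structures are `include = "feedback"` for accuracy
#' and the full `c("valence", "feedback", "interaction")` with
#' `experiment_as_fixed = TRUE` for RT; both are configurable.
#'
#' @param cells A [cell_means()] tibble.
#' @param response `"accuracy"` or `"rt"`.
#' @param include Effects to estimate: subset of
#'   `c("valence", "feedback", "interaction")`, non-empty.
#' @param experiment_as_fixed Add experiment fixed effects.
#' @param settings Sampler settings ([default_settings()]).
#' @return An `effect_fit`: list with `summary` (a `posterior_summary`
#'   restricted to the included effects), `draws`, and the model
#'   description. Effects for accuracy are on the proportion scale, for RT
#'   in seconds.
#' @export
fit_effect_model <- function(cells, response = c("accuracy", "rt"),
                             include = c("valence", "feedback",
                                         "interaction"),
                             experiment_as_fixed = FALSE,
                             settings = default_settings(chains = 4,
                                                         iter = 2000,
                                                         warmup = 1000)) {
  response <- match.arg(response)
  if (length(include) == 0) {
    abort("include must name at least one effect",
          class = "rlddm_parameter_error")
  }
  include <- match.arg(include, c("valence", "feedback", "interaction"),
                       several.ok = TRUE)
  cells <- dplyr::arrange(tibble::as_tibble(cells), participant_id,
                          context_valence, context_feedback)
  y <- if (response == "accuracy") cells$mean_accuracy else cells$mean_rt
  code <- encode_condition(cells$context_valence, cells$context_feedback)
  X <- cbind(intercept = rep(1, nrow(cells)))
  for (eff in include) X <- cbind(X, code[[eff]])
  colnames(X) <- c("intercept", paste0("beta_", include))
  if (experiment_as_fixed) {
    exps <- sort(unique(cells$experiment_id))
    for (e in exps[-1]) {
      X <- cbind(X, as.numeric(cells$experiment_id == e))
      colnames(X)[ncol(X)] <- paste0("exp_", e)
    }
  }
  pid <- factor(cells$participant_id)
  m <- 4L  # balanced: four context cells per participant
  stopifnot(all(table(pid) == m))
  n <- length(y)
  J <- nlevels(pid)
  # marginal likelihood of the random-intercept model:
  # y_i ~ MVN(X_i beta, sigma^2 I_m + tau^2 J_m) per participant
  log_lik <- function(beta, log_sigma, log_tau) {
    s2 <- exp(2 * log_sigma)
    t2 <- exp(2 * log_tau)
    e <- y - as.numeric(X %*% beta)
    sse <- sum(e^2)
    s_i <- rowsum(e, pid)
    quad <- sse / s2 - (t2 / (s2 * (s2 + m * t2))) * sum(s_i^2)
    logdet <- J * ((m - 1) * log(s2) + log(s2 + m * t2))
    -0.5 * (n * log(2 * pi) + logdet + quad)
  }
  p <- ncol(X)
  par_names <- c(colnames(X), "log_sigma", "log_tau")
  log_post <- function(th) {
    beta <- th[seq_len(p)]
    ll <- log_lik(beta, th[[p + 1]], th[[p + 2]])
    ll + sum(dnorm(beta, 0, 10, log = TRUE)) +
      log_halfnormal_logsd(th[[p + 1]]) + log_halfnormal_logsd(th[[p + 2]])
  }
  sd_y <- max(sd(y), 1e-3)
  init <- function() {
    setNames(c(mean(y), rnorm(p - 1, 0, 0.05 * sd_y),
               log(sd_y) + rnorm(1, 0, 0.2), log(sd_y / 2) + rnorm(1, 0, 0.2)),
             par_names)
  }
  draws <- mcmc_mwg(log_post, init, settings = settings, step0 = 0.1 * sd_y)
  eff_names <- paste0("beta_", include)
  structure(list(summary = summary(draws, parameters = eff_names),
                 draws = draws, response = response, include = include,
                 experiment_as_fixed = experiment_as_fixed),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat("<effect_fit> response:", x$response,
      if (x$experiment_as_fixed) "(+ experiment fixed effects)", "\n")
  print(x$summary)
  invisible(x)
}
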