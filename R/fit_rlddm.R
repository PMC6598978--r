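rlddm_prior_mean <- c(alpha_c = -1, alpha_u = -1, alpha_v = -1, v_coeff = 1,
                      a_int = 0, a_coeff = 0, ndt_int = log(0.3),
                      ndt_coeff = 0)
rlddm_prior_sd <- c(alpha_c = 1, alpha_u = 1, alpha_v = 1, v_coeff = 2,
                    a_int = 2, a_coeff = 1, ndt_int = 0.5, ndt_coeff = 1)

# per-participant compiled-likelihood closures over a trial table
rlddm_participant_data <- function(data, reset_per_session = TRUE) {
  ids <- unique(data$participant_id)
  lapply(ids, function(id) {
    d <- data[data$participant_id == id, ]
    d <- d[order(d$session, d$trial_index), ]
    list(
      id = id,
      session = as.integer(d$session),
      context = context_index(d$context_valence, d$context_feedback),
      correct = as.integer(d$correct),
      rt = as.numeric(d$rt),
      R_ch = as.numeric(d$outcome_chosen),
      R_un = ifelse(is.na(d$outcome_unchosen), 0, d$outcome_unchosen),
      complete = as.integer(d$context_feedback == "complete"),
      min_rt = suppressWarnings(min(d$rt, na.rm = TRUE))
    )
  })
}

rlddm_loglik_one <- function(pd, theta_unc, reset_per_session = TRUE) {
  cpp_rlddm_loglik(pd$session, pd$context, pd$correct, pd$rt, pd$R_ch,
                   pd$R_un, pd$complete, constrain_relative_vec(theta_unc),
                   reset_per_session)
}

#' Fit the hierarchical learning-diffusion model
#'
#' Joint hierarchical Bayesian estimation of the eight model parameters from
#' choices and response times, with participants nested in one experiment
#' (fit experiments separately, as the study design implies different
#' windows and trial counts). Sampling is by slice-within-Gibbs on the
#' unconstrained scale (learning rates and the threshold coefficient via
#' logit, the threshold intercept via log): compiled coordinate and
#' random-direction slice updates for participant parameters, conjugate
#' Gibbs draws for group means, slice updates for group SDs, and
#' non-centered interweaving moves for the hierarchy.
#'
#' Default priors (group means, unconstrained scale): learning rates
#' `N(-1, 1)` on the logit scale; `v_coeff ~ N(1, 2)`;
#' `log a_int ~ N(0, 2)`; `a_coeff ~ N(0, 1)` on the logit scale;
#' `ndt_int ~ N(log 0.3, 0.5)`; `ndt_coeff ~ N(0, 1)`; group SDs
#' half-normal(0, 1).
#'
#' @param data A validated [trial_table] for a single experiment.
#' @param settings Sampler settings ([default_settings()]); the full-scale
#'   study convention is `chains = 4, iter = 10000, warmup = 5000`, the
#'   package default is the desk-scale `iter = 2000, warmup = 1000`.
#' @param reset_per_session Reset learning at session boundaries.
#' @param prior_mean,prior_sd Optional named overrides of the group-mean
#'   priors (unconstrained scale).
#' @return An `rlddm_fit` object; `summary()` reports group-level means,
#'   95% BCIs and R-hat. Parameter naming: `mu_*`/`sigma_*` for group
#'   means/SDs and `par[participant]` for individual values, all on the
#'   unconstrained scale.
#' @export
fit_rlddm <- function(data, settings = default_settings(chains = 4,
                                                        iter = 2000,
                                                        warmup = 1000),
                      reset_per_session = TRUE, prior_mean = NULL,
                      prior_sd = NULL) {
  data <- validate_trial_table(data)
  if (length(unique(data$experiment_id)) > 1) {
    abort("fit_rlddm fits one experiment at a time; split the table",
          class = "rlddm_validation_error")
  }
  pds <- rlddm_participant_data(data, reset_per_session)
  J <- length(pds)
  m0 <- rlddm_prior_mean
  s0 <- rlddm_prior_sd
  if (!is.null(prior_mean)) m0[names(prior_mean)] <- prior_mean
  if (!is.null(prior_sd)) s0[names(prior_sd)] <- prior_sd
  loglik_fun <- function(j, theta) {
    pd <- pds[[j]]
    cpp_rlddm_loglik_unc(pd$session, pd$context, pd$correct, pd$rt, pd$R_ch,
                         pd$R_un, pd$complete, theta, reset_per_session)
  }
  scan_fun <- function(j, theta_j, ll_j, gmu_row, sigma) {
    pd <- pds[[j]]
    out <- cpp_rlddm_slice_scan(pd$session, pd$context, pd$correct, pd$rt,
                                pd$R_ch, pd$R_un, pd$complete,
                                reset_per_session, theta_j, ll_j, gmu_row,
                                sigma, 1.5, 6L)
    list(theta = out[1:8], ll = out[9])
  }
  batch_loglik <- function(theta) {
    cpp_rlddm_loglik_batch(pds, theta, reset_per_session)
  }
  init_fun <- function(j) {
    c(rnorm(3, -1.4, 0.3),                       # logit learning rates
      rnorm(1, 1, 0.3),                          # v_coeff
      rnorm(1, log(1.5), 0.2),                   # log a_int
      rnorm(1, 0, 0.3),                          # logit a_coeff
      log(0.5 * pds[[j]]$min_rt) + rnorm(1, 0, 0.1),  # ndt_int
      rnorm(1, 0, 0.05))                         # ndt_coeff
  }
  draws <- fit_hierarchical_mwg(
    loglik_fun, J = J, K = 8L, prior_mean = m0, prior_sd = s0,
    init_fun = init_fun, settings = settings,
    par_names = relative_param_names,
    participant_ids = vapply(pds, `[[`, "", "id"),
    scan_fun = scan_fun, batch_loglik = batch_loglik
  )
  structure(list(draws = draws, model = "rlddm", data = data,
                 participant_ids = vapply(pds, `[[`, "", "id"),
                 par_names = relative_param_names, settings = settings,
                 reset_per_session = reset_per_session),
            class = c("rlddm_fit", "rlddm_model_fit"))
}

#' @export
print.rlddm_model_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ", length(x$participant_ids),
      " participants, ", x$draws$n_chains, " chains x ",
      dim(x$draws$draws)[1], " retained draws\n", sep = "")
  print(summary(x))
  invisible(x)
}

#' Summarize a model fit at the group level
#'
#' @param object An `rlddm_fit` or `factorial_fit`.
#' @param level Credible mass (default 0.95).
#' @param which `"group"` (default) for group-level means and SDs,
#'   `"all"` for every monitored parameter.
#' @param ... Unused.
#' @return A `posterior_summary` tibble.
#' @export
summary.rlddm_model_fit <- function(object, level = 0.95,
                                    which = c("group", "all"), ...) {
  which <- match.arg(which)
  pars <- dimnames(object$draws$draws)[[3]]
  if (which == "group") {
    pars <- pars[grepl("^(mu_|sigma_|tau_)", pars) & !grepl("\\[g", pars)]
  }
  summary(object$draws, parameters = pars, level = level)
}

#' Convergence gate for a fit
#'
#' @param fit An `rlddm_fit` or `factorial_fit`.
#' @param cutoff R-hat convergence cutoff (1.01 by convention).
#' @param group_only Check only group-level parameters.
#' @return Logical flag with attribute `rhat_max`.
#' @export
converged <- function(fit, cutoff = 1.01, group_only = TRUE) {
  pars <- dimnames(fit$draws$draws)[[3]]
  if (group_only) {
    pars <- pars[grepl("^(mu_|sigma_|tau_)", pars) & !grepl("\\[g", pars)]
  }
  rh <- vapply(pars, function(p) as.numeric(rhat(fit$draws, p)), 0)
  structure(all(rh < cutoff), rhat_max = max(rh))
}

#' Joint log-likelihood of a full parameter assignment
#'
#' Additive over participants: for the learning model, a forward pass per
#' participant feeding the Wiener first-passage density of every responded
#' trial; for the factorial model, the same density at the
#' condition-decoded parameters. Any trial with `rt <= ndt` makes the
#' result `-Inf` (a rejectable, not an error).
#'
#' @param model `"rlddm"` or `"factorial"`.
#' @param data A validated [trial_table].
#' @param params Per-participant natural-scale parameters: for `"rlddm"` a
#'   tibble with `participant_id` plus the eight [relative_params()]
#'   columns; for `"factorial"` a tibble with `participant_id` plus the
#'   twelve coefficient columns (`v_intercept`, ..., `ndt_interaction`; `a`
#'   and `ndt` on the log link scale).
#' @param reset_per_session Session reset rule for the learning model.
#' @return A single number.
#' @export
dataset_loglik <- function(model = c("rlddm", "factorial"), data, params,
                           reset_per_session = TRUE) {
  model <- match.arg(model)
  data <- validate_trial_table(data)
  params <- tibble::as_tibble(params)
  total <- 0
  if (model == "rlddm") {
    pds <- rlddm_participant_data(data, reset_per_session)
    for (pd in pds) {
      row <- params[params$participant_id == pd$id, ]
      if (nrow(row) != 1) {
        abort(paste0("params missing participant ", pd$id),
              class = "rlddm_validation_error")
      }
      nat <- unlist(row[relative_param_names])
      ll <- cpp_rlddm_loglik(pd$session, pd$context, pd$correct, pd$rt,
                             pd$R_ch, pd$R_un, pd$complete, unname(nat),
                             reset_per_session)
      total <- total + ll
      if (!is.finite(total)) return(-Inf)
    }
  } else {
    fds <- factorial_participant_data(data)
    for (fd in fds) {
      row <- params[params$participant_id == fd$id, ]
      if (nrow(row) != 1) {
        abort(paste0("params missing participant ", fd$id),
              class = "rlddm_validation_error")
      }
      ll <- factorial_loglik_one(fd, unlist(row[factorial_par_names]))
      total <- total + ll
      if (!is.finite(total)) return(-Inf)
    }
  }
  total
}

#' Draw from the posterior of one of the package's models
#'
#' Thin dispatcher over [fit_rlddm()] and [fit_factorial_ddm()]; both run
#' the requested number of chains, discard the warmup half, and are
#' bitwise-reproducible given `settings$seed`.
#'
#' @param model `"rlddm"` or `"factorial"`.
#' @param data A validated [trial_table].
#' @param settings [default_settings()] list.
#' @param ... Passed to the model-specific fitting function.
#' @return A fit object whose `$draws` is a `posterior_draws`.
#' @export
sample_posterior <- function(model = c("rlddm", "factorial"), data,
                             settings = default_settings(), ...) {
  model <- match.arg(model)
  switch(model,
         rlddm = fit_rlddm(data, settings = settings, ...),
         factorial = fit_factorial_ddm(data, settings = settings, ...))
}
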