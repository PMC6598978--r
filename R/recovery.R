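#' Parameter-recovery study for the learning-diffusion model
#'
#' The package's estimation-validity check, mirroring the study's own
#' strategy: simulate a cohort from known group-level parameters, refit the
#' hierarchical model, and compare. Reported per group-level mean
#' (unconstrained scale): truth, posterior mean, 95% BCI, coverage flag and
#' R-hat; plus Spearman rank correlations between individual-level
#' posterior means and the simulated participants' true values for the
#' three learning rates.
#'
#' @param design A [make_design()] object (e.g. `make_design("exp1")`).
#' @param true_group A [generating_params()] object (the truth).
#' @param n_participants Cohort size.
#' @param seed Integer seed controlling both simulation and sampling.
#' @param settings Sampler settings; default is the desk-scale
#'   4 chains x 2000 iterations with the first half discarded.
#' @param keep_fit Keep the full fit object in the report.
#' @return A `recovery_report`: list with `group` (tibble), `individual`
#'   (tibble of rank correlations), `rhat_max`, `n_covered`, and optionally
#'   `fit`.
#' @export
parameter_recovery <- function(design, true_group = generating_params(),
                               n_participants = 20, seed = 1,
                               settings = default_settings(chains = 4,
                                                           iter = 2000,
                                                           warmup = 1000),
                               keep_fit = FALSE) {
  if (design$trials_per_session * design$n_sessions < 1) {
    abort("design has no trials", class = "rlddm_parameter_error")
  }
  cohort <- simulate_cohort(design, true_group,
                            n_participants = n_participants, seed = seed)
  truth_ind <- attr(cohort, "participants")
  settings$seed <- seed + 1
  fit <- fit_rlddm(cohort, settings = settings)
  gs <- summary(fit, which = "group")
  group <- dplyr::bind_rows(lapply(names(true_group$means), function(p) {
    row <- gs[gs$parameter == paste0("mu_", p), ]
    tibble::tibble(parameter = p, truth = true_group$means[[p]],
                   estimate = row$mean, bci_low = row$bci_low,
                   bci_high = row$bci_high,
                   covered = truth_ind_cover(true_group$means[[p]], row),
                   rhat = row$rhat)
  }))
  rhat_all <- summary(fit, which = "group")$rhat
  individual <- dplyr::bind_rows(lapply(c("alpha_c", "alpha_u", "alpha_v"),
                                        function(p) {
    est <- vapply(fit$participant_ids, function(id) {
      mean(extract_draws(fit$draws, paste0(p, "[", id, "]")))
    }, 0)
    truth <- truth_ind[[paste0("raw_", p)]][
      match(fit$participant_ids, truth_ind$participant_id)]
    tibble::tibble(parameter = p,
                   rank_correlation = cor(est, truth, method = "spearman"))
  }))
  out <- list(group = group, individual = individual,
              rhat_max = max(rhat_all),
              n_covered = sum(group$covered),
              n_participants = n_participants, seed = seed)
  if (keep_fit) out$fit <- fit
  structure(out, class = "recovery_report")
}

truth_ind_cover <- function(truth, row) {
  truth >= row$bci_low & truth <= row$bci_high
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$n_participants, " participants; ",
      x$n_covered, "/", nrow(x$group), " group-level 95% BCIs cover truth; ",
      "max group R-hat ", round(x$rhat_max, 4), "\n", sep = "")
  print(x$group)
  cat("individual-level rank correlations:\n")
  print(x$individual)
  invisible(x)
}
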