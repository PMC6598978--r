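ppc_bin <- function(data, n_bins) {
  data |>
    dplyr::filter(!is.na(rt)) |>
    dplyr::group_by(experiment_id, participant_id, context_valence,
                    context_feedback) |>
    dplyr::arrange(session, trial_index, .by_group = TRUE) |>
    dplyr::mutate(bin = ceiling(dplyr::row_number() / dplyr::n() * n_bins)) |>
    dplyr::ungroup()
}

ppc_cell_stats <- function(data, n_bins) {
  ppc_bin(data, n_bins) |>
    dplyr::group_by(experiment_id, context_valence, context_feedback, bin) |>
    dplyr::summarise(accuracy = mean(correct), rt = mean(rt),
                     .groups = "drop")
}

rt_quantile_levels <- c(0.1, 0.3, 0.5, 0.7, 0.9)

ppc_quantile_stats <- function(data) {
  data |>
    dplyr::filter(!is.na(rt)) |>
    dplyr::group_by(experiment_id, context_valence, context_feedback,
                    correct) |>
    dplyr::reframe(q_level = rt_quantile_levels,
                   rt_q = quantile(rt, rt_quantile_levels, names = FALSE))
}

participants_from_fit <- function(fit) {
  # posterior draws of every participant's parameter vector, natural scale
  pars <- dimnames(fit$draws$draws)[[3]]
  lapply(fit$participant_ids, function(id) {
    nm <- paste0(fit$par_names, "[", id, "]")
    stopifnot(all(nm %in% pars))
    nm
  })
}

#' Posterior predictive distributions
#'
#' For each replicate, one retained posterior draw is selected, the full
#' dataset is simulated forward under that draw, and the replicate is
#' summarized like the observed data. For the learning model the summary is
#' mean accuracy and mean RT per context x trial bin x experiment; for the
#' factorial model, accuracy per context plus RT quantiles (0.1, 0.3, 0.5,
#' 0.7, 0.9) split by correct/incorrect responses.
#'
#' @param fit An `rlddm_fit` or `factorial_fit`.
#' @param data The observed [trial_table] (defaults to the data the model
#'   was fit to).
#' @param n_rep Number of predictive replicates (>= 1).
#' @param design The [task_design] used to redraw outcome schedules for the
#'   learning model (defaults to the design attached to `data`, else the
#'   experiment preset).
#' @param n_bins Trial bins per context for the learning-model summary.
#' @param seed Optional seed.
#' @return A tibble of cells: grouping keys, `stat`, `observed`,
#'   `pred_mean`, `pred_low`, `pred_high` (95% predictive interval), and
#'   `inside` (is the observed value inside the interval?).
#' @export
posterior_predictive <- function(fit, data = fit$data, n_rep = 100,
                                 design = NULL, n_bins = 4, seed = NULL) {
  if (n_rep < 1) abort("n_rep must be >= 1", class = "rlddm_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  draws <- fit$draws$draws
  n_iter <- dim(draws)[1]
  n_chains <- dim(draws)[2]
  picks <- cbind(sample(n_iter, n_rep, replace = TRUE),
                 sample(n_chains, n_rep, replace = TRUE))
  if (inherits(fit, "rlddm_fit")) {
    design <- design %||% attr(data, "design") %||%
      make_design(data$experiment_id[1])
    obs <- ppc_cell_stats(data, n_bins)
    reps <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      th <- draws[picks[r, 1], picks[r, 2], ]
      ptab <- lapply(seq_along(fit$participant_ids), function(j) {
        nm <- paste0(fit$par_names, "[", fit$participant_ids[j], "]")
        nat <- constrain_relative(as.list(setNames(th[nm], fit$par_names)))
        tibble::as_tibble(as.list(nat))
      })
      ptab <- dplyr::bind_rows(ptab)
      ptab$participant_id <- fit$participant_ids
      sim <- simulate_cohort(design, params = ptab, dt = 1e-3,
                             reset_per_session = fit$reset_per_session)
      reps[[r]] <- dplyr::mutate(ppc_cell_stats(sim, n_bins), .rep = r)
    }
    keys <- c("experiment_id", "context_valence", "context_feedback", "bin")
    long_obs <- tidyr::pivot_longer(obs, c("accuracy", "rt"),
                                    names_to = "stat",
                                    values_to = "observed")
    long_rep <- tidyr::pivot_longer(dplyr::bind_rows(reps),
                                    c("accuracy", "rt"), names_to = "stat",
                                    values_to = "value")
  } else {
    obs_acc <- data |>
      dplyr::filter(!is.na(rt)) |>
      dplyr::group_by(experiment_id, context_valence, context_feedback) |>
      dplyr::summarise(observed = mean(correct), .groups = "drop") |>
      dplyr::mutate(stat = "accuracy")
    obs_q <- ppc_quantile_stats(data) |>
      dplyr::mutate(stat = paste0("rt_q", q_level * 100, "_",
                                  ifelse(correct == 1, "correct", "error"))) |>
      dplyr::select(experiment_id, context_valence, context_feedback, stat,
                    observed = rt_q)
    long_obs <- dplyr::bind_rows(
      dplyr::mutate(obs_acc, bin = NA_real_),
      dplyr::mutate(obs_q, bin = NA_real_)
    )
    counts <- data |>
      dplyr::filter(!is.na(rt)) |>
      dplyr::count(experiment_id, participant_id, context_valence,
                   context_feedback)
    reps <- vector("list", n_rep)
    for (r in seq_len(n_rep)) {
      th <- draws[picks[r, 1], picks[r, 2], ]
      sim_rows <- lapply(seq_len(nrow(counts)), function(i) {
        id <- counts$participant_id[i]
        nm <- paste0(fit$par_names, "[", id, "]")
        cf <- factorial_coeffs(th[nm][1:4], th[nm][5:8], th[nm][9:12])
        code <- encode_condition(counts$context_valence[i],
                                 counts$context_feedback[i])
        p <- condition_ddm_params(cf, code)
        s <- simulate_ddm(counts$n[i], p, dt = 1e-3)
        tibble::tibble(
          experiment_id = counts$experiment_id[i],
          participant_id = id,
          context_valence = counts$context_valence[i],
          context_feedback = counts$context_feedback[i],
          correct = as.numeric(s$boundary == "upper"),
          rt = s$rt
        )
      })
      sim <- dplyr::bind_rows(sim_rows)
      rep_acc <- sim |>
        dplyr::filter(!is.na(rt)) |>
        dplyr::group_by(experiment_id, context_valence, context_feedback) |>
        dplyr::summarise(value = mean(correct), .groups = "drop") |>
        dplyr::mutate(stat = "accuracy")
      rep_q <- ppc_quantile_stats(sim) |>
        dplyr::mutate(stat = paste0("rt_q", q_level * 100, "_",
                                    ifelse(correct == 1, "correct",
                                           "error"))) |>
        dplyr::select(experiment_id, context_valence, context_feedback,
                      stat, value = rt_q)
      reps[[r]] <- dplyr::mutate(dplyr::bind_rows(rep_acc, rep_q), .rep = r)
    }
    keys <- c("experiment_id", "context_valence", "context_feedback")
    long_rep <- dplyr::mutate(dplyr::bind_rows(reps), bin = NA_real_)
  }
  pred <- long_rep |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "stat")))) |>
    dplyr::summarise(pred_mean = mean(value),
                     pred_low = quantile(value, 0.025, names = FALSE),
                     pred_high = quantile(value, 0.975, names = FALSE),
                     .groups = "drop")
  out <- dplyr::inner_join(long_obs, pred, by = c(keys, "stat"))
  dplyr::mutate(out,
                inside = observed >= pred_low & observed <= pred_high)
}
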