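# Blocked slice-within-Gibbs, with ancillarity-sufficiency interweaving
# (ASIS), for hierarchical models of the form
#   theta[j, k] ~ N(mu[g(j), k], sigma[k])           (participant level)
#   mu[g, k]    ~ N(M[k], S[k])                      (group level, if G > 1)
#   M[k]        ~ N(prior_mean[k], prior_sd[k])      (top level)
#   sigma[k], S[k] ~ half-normal(0, 1)
# with an arbitrary per-participant data log-likelihood on the unconstrained
# theta row. Update scheme, per iteration:
#   * participant coordinates: univariate stepping-out slice sampling
#     (Neal-style) on each theta[j, k], with the slice width expressed in
#     units of the current sigma[k] so it tracks the hierarchical funnel.
#     Slice updates never reject, which keeps the per-coordinate
#     autocorrelation far below that of scalar random-walk proposals —
#     the property the 1.01 convergence gate needs at desk-scale chain
#     lengths.
#   * group means: conjugate normal Gibbs draws.
#   * group SDs (and the between-group SDs): slice sampling on the log
#     scale against the half-normal prior; these conditionals involve only
#     normal densities of the theta (or mu) column, so the extra
#     evaluations are free.
#   * non-centered interweaving: random-walk moves that hold the
#     standardized residuals eta = (theta - mu)/sigma fixed while
#     translating mu[g, k] or rescaling sigma[k], accepted against the
#     summed data likelihood plus the top-level prior (eta ~ N(0,1) is
#     invariant, so the hierarchy's density drops out). Without these the
#     group-level chain inherits the slow drift of the theta cloud.

# One univariate stepping-out slice update. lp must return the log target;
# returns the new point (never rejects). max_step bounds the stepping-out.
slice_update <- function(x0, lp0, lp, w, max_step = 8L) {
  ly <- lp0 - rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  s <- 0L
  while (s < max_step && lp(L) > ly) { L <- L - w; s <- s + 1L }
  s <- 0L
  while (s < max_step && lp(R) > ly) { R <- R + w; s <- s + 1L }
  repeat {
    x1 <- runif(1, L, R)
    lp1 <- lp(x1)
    if (lp1 >= ly) return(list(x = x1, lp = lp1))
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(list(x = x0, lp = lp0))
  }
}

# scan_fun(j, theta_j, ll_j, gmu_row, sigma) -> list(theta, ll): optional
# compiled replacement for the R coordinate-slice scan (adds
# random-direction updates); batch_loglik(theta_matrix) -> J log-likelihoods
# evaluated in one call, used by the non-centered moves.
fit_hierarchical_mwg <- function(loglik_fun, J, K, group = rep(1L, J),
                                 prior_mean, prior_sd, init_fun,
                                 settings = default_settings(),
                                 par_names, participant_ids = NULL,
                                 hyper_sd_scale = 1, scan_fun = NULL,
                                 batch_loglik = NULL) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  group <- as.integer(factor(group))
  G <- max(group)
  pid <- participant_ids %||% sprintf("p%02d", seq_len(J))
  stopifnot(length(par_names) == K, length(pid) == J)

  theta_names <- as.vector(outer(par_names, pid,
                                 function(p, id) paste0(p, "[", id, "]")))
  mu_names <- paste0("mu_", par_names)
  sigma_names <- paste0("sigma_", par_names)
  all_names <- c(theta_names, mu_names, sigma_names)
  if (G > 1) {
    gmu_names <- as.vector(outer(par_names, seq_len(G),
                                 function(p, g) paste0("mu_", p, "[g", g, "]")))
    tau_names <- paste0("tau_", par_names)
    all_names <- c(theta_names, gmu_names, mu_names, tau_names, sigma_names)
  }

  n_keep <- settings$iter - settings$warmup
  arr <- array(NA_real_, c(n_keep, settings$chains, length(all_names)),
               dimnames = list(NULL, NULL, all_names))
  batch <- 25L

  for (ch in seq_len(settings$chains)) {
    # initialize participants at finite likelihood (<= 100 redraws each)
    theta <- matrix(NA_real_, J, K)
    ll <- numeric(J)
    for (j in seq_len(J)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- init_fun(j)
        l <- loglik_fun(j, cand)
        if (is.finite(l)) { theta[j, ] <- cand; ll[j] <- l; ok <- TRUE; break }
      }
      if (!ok) abort("no finite initial log density after 100 draws",
                     class = "rlddm_initialization_error")
    }
    gmu <- matrix(0, G, K)
    for (g in seq_len(G)) {
      gmu[g, ] <- colMeans(theta[group == g, , drop = FALSE])
    }
    M <- colMeans(gmu)
    S <- rep(0.5, K)      # group-of-groups SD (only used when G > 1)
    sigma <- rep(0.5, K)  # participant-level SD

    w_theta <- 1.5        # slice width for theta, in units of sigma[k]
    w_sd <- 1             # slice width for log-SD updates
    step_nc_mu <- matrix(0.1, G, K)
    step_nc_sig <- rep(0.1, K)
    acc_nc_mu <- matrix(0L, G, K)
    acc_nc_sig <- integer(K)

    for (it in seq_len(settings$iter)) {
      # --- participant-level slice updates ---
      if (!is.null(scan_fun)) {
        for (j in seq_len(J)) {
          upd <- scan_fun(j, theta[j, ], ll[j], gmu[group[j], ], sigma)
          theta[j, ] <- upd$theta
          ll[j] <- upd$ll
        }
      } else {
        for (j in seq_len(J)) {
          g <- group[j]
          th_j <- theta[j, ]
          for (k in seq_len(K)) {
            lp_k <- function(x) {
              th_j[k] <- x
              l <- loglik_fun(j, th_j)
              if (!is.finite(l)) return(-Inf)
              l + dnorm(x, gmu[g, k], sigma[k], log = TRUE)
            }
            lp0 <- ll[j] + dnorm(th_j[k], gmu[g, k], sigma[k], log = TRUE)
            upd <- slice_update(th_j[k], lp0, lp_k, w_theta * sigma[k])
            th_j[k] <- upd$x
            ll[j] <- upd$lp - dnorm(upd$x, gmu[g, k], sigma[k], log = TRUE)
          }
          theta[j, ] <- th_j
        }
      }
      # --- group means: conjugate Gibbs ---
      for (g in seq_len(G)) {
        n_g <- sum(group == g)
        for (k in seq_len(K)) {
          pr_mean <- if (G > 1) M[k] else prior_mean[k]
          pr_sd <- if (G > 1) S[k] else prior_sd[k]
          prec <- n_g / sigma[k]^2 + 1 / pr_sd^2
          m <- (sum(theta[group == g, k]) / sigma[k]^2 + pr_mean / pr_sd^2) /
            prec
          gmu[g, k] <- rnorm(1, m, 1 / sqrt(prec))
        }
      }
      if (G > 1) {
        for (k in seq_len(K)) {
          prec <- G / S[k]^2 + 1 / prior_sd[k]^2
          m <- (sum(gmu[, k]) / S[k]^2 + prior_mean[k] / prior_sd[k]^2) / prec
          M[k] <- rnorm(1, m, 1 / sqrt(prec))
          lp_S <- function(ls) {
            sum(dnorm(gmu[, k], M[k], exp(ls), log = TRUE)) +
              log_halfnormal_logsd(ls, hyper_sd_scale)
          }
          S[k] <- exp(slice_update(log(S[k]), lp_S(log(S[k])), lp_S, w_sd)$x)
        }
      }
      # --- participant-level SDs: slice on the log scale ---
      for (k in seq_len(K)) {
        lp_sig <- function(ls) {
          sum(dnorm(theta[, k], gmu[group, k], exp(ls), log = TRUE)) +
            log_halfnormal_logsd(ls, hyper_sd_scale)
        }
        sigma[k] <- exp(slice_update(log(sigma[k]), lp_sig(log(sigma[k])),
                                     lp_sig, w_sd)$x)
      }
      # --- non-centered interweaving moves ---
      for (k in seq_len(K)) {
        for (g in seq_len(G)) {
          jj <- which(group == g)
          delta <- rnorm(1, 0, step_nc_mu[g, k])
          theta_prop <- theta
          theta_prop[jj, k] <- theta[jj, k] + delta
          mu_prop <- gmu[g, k] + delta
          pr_mean <- if (G > 1) M[k] else prior_mean[k]
          pr_sd <- if (G > 1) S[k] else prior_sd[k]
          lp_diff <- dnorm(mu_prop, pr_mean, pr_sd, log = TRUE) -
            dnorm(gmu[g, k], pr_mean, pr_sd, log = TRUE)
          ll_prop <- if (!is.null(batch_loglik)) {
            batch_loglik(theta_prop)[jj]
          } else {
            vapply(jj, function(j) loglik_fun(j, theta_prop[j, ]), 0)
          }
          if (all(is.finite(ll_prop)) &&
              log(runif(1)) < sum(ll_prop) - sum(ll[jj]) + lp_diff) {
            theta <- theta_prop
            gmu[g, k] <- mu_prop
            ll[jj] <- ll_prop
            acc_nc_mu[g, k] <- acc_nc_mu[g, k] + 1L
          }
        }
        # rescale the whole column about its group means
        ls_prop <- log(sigma[k]) + rnorm(1, 0, step_nc_sig[k])
        scl <- exp(ls_prop) / sigma[k]
        theta_prop <- theta
        theta_prop[, k] <- gmu[group, k] + (theta[, k] - gmu[group, k]) * scl
        lp_diff <- log_halfnormal_logsd(ls_prop, hyper_sd_scale) -
          log_halfnormal_logsd(log(sigma[k]), hyper_sd_scale)
        ll_prop <- if (!is.null(batch_loglik)) {
          batch_loglik(theta_prop)
        } else {
          vapply(seq_len(J), function(j) loglik_fun(j, theta_prop[j, ]), 0)
        }
        if (all(is.finite(ll_prop)) &&
            log(runif(1)) < sum(ll_prop) - sum(ll) + lp_diff) {
          theta <- theta_prop
          sigma[k] <- exp(ls_prop)
          ll <- ll_prop
          acc_nc_sig[k] <- acc_nc_sig[k] + 1L
        }
      }
      # --- warmup adaptation of the non-centered step sizes ---
      if (it <= settings$warmup && it %% batch == 0) {
        b <- it %/% batch
        step_nc_mu <- adapt_step(step_nc_mu, acc_nc_mu / batch, b)
        step_nc_sig <- adapt_step(step_nc_sig, acc_nc_sig / batch, b)
        acc_nc_mu[] <- 0L; acc_nc_sig[] <- 0L
      }
      # --- store ---
      if (it > settings$warmup) {
        row <- if (G > 1) {
          c(as.vector(t(theta)), as.vector(t(gmu)), M, S, sigma)
        } else {
          c(as.vector(t(theta)), gmu[1, ], sigma)
        }
        arr[it - settings$warmup, ch, ] <- row
      }
    }
  }
  new_posterior_draws(arr, settings$warmup, settings$seed)
}
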