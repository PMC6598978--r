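#' @title Posterior draw containers and convergence diagnostics
#' @description
#' All samplers in the package return a `posterior_draws` object: a 3-d array
#' of retained draws indexed `(iteration, chain, parameter)` plus the sampler
#' metadata. [rhat()] implements the split-chain potential-scale-reduction
#' statistic with the conventional 1.01 convergence cutoff, and [bci()] the
#' central credible interval.
#' @name posterior-draws
NULL

new_posterior_draws <- function(arr, n_warmup, seed = NULL) {
  stopifnot(length(dim(arr)) == 3)
  structure(list(draws = arr, n_iter = dim(arr)[1] + n_warmup,
                 n_chains = dim(arr)[2], n_warmup = n_warmup, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", dim(x$draws)[3], " parameters, ", x$n_chains,
      " chains x ", dim(x$draws)[1], " retained draws (", x$n_warmup,
      " warmup discarded)\n", sep = "")
  invisible(x)
}

#' Extract one parameter's retained draws
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param merge Concatenate chains into one vector (default) or keep the
#'   iteration x chain matrix.
#' @return Numeric vector (or matrix with `merge = FALSE`).
#' @export
extract_draws <- function(draws, parameter, merge = TRUE) {
  pars <- dimnames(draws$draws)[[3]]
  if (!parameter %in% pars) {
    abort(paste0("unknown parameter: ", parameter),
          class = "rlddm_parameter_error")
  }
  m <- draws$draws[, , parameter, drop = TRUE]
  if (merge) as.numeric(m) else m
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half, the between- and within-(half-)chain
#' variances are combined, and convergence is flagged at the conventional
#' `rhat < 1.01` cutoff.
#'
#' @param draws A `posterior_draws` object (at least 2 chains and 4 retained
#'   draws per chain), or an iterations x chains matrix.
#' @param parameter Parameter name (when `draws` is a `posterior_draws`).
#' @return The R-hat value, with attribute `converged` (logical).
#' @export
rhat <- function(draws, parameter = NULL) {
  m <- if (inherits(draws, "posterior_draws")) {
    extract_draws(draws, parameter, merge = FALSE)
  } else {
    as.matrix(draws)
  }
  if (ncol(m) < 2) {
    abort("rhat needs at least 2 chains", class = "rlddm_parameter_error")
  }
  if (nrow(m) < 4) {
    abort("rhat needs at least 4 draws per chain",
          class = "rlddm_parameter_error")
  }
  half <- floor(nrow(m) / 2)
  split <- cbind(m[seq_len(half), , drop = FALSE],
                 m[(nrow(m) - half + 1):nrow(m), , drop = FALSE])
  n <- nrow(split)
  chain_means <- colMeans(split)
  chain_vars <- apply(split, 2, var)
  W <- mean(chain_vars)
  B <- n * var(chain_means)
  if (W == 0) {
    r <- if (B == 0) 1 else Inf
  } else {
    r <- sqrt(((n - 1) / n * W + B / n) / W)
  }
  structure(r, converged = is.finite(r) && r < 1.01)
}

#' Central Bayesian credible interval
#'
#' The `(1 - level)/2` and `1 - (1 - level)/2` empirical quantiles of the
#' retained draws (95% central interval by default).
#'
#' @param draws Numeric vector of draws, or a `posterior_draws` object
#'   together with `parameter`.
#' @param level Interval mass (default 0.95).
#' @param parameter Parameter name when `draws` is a `posterior_draws`.
#' @return Named numeric vector `c(low, high)`.
#' @export
bci <- function(draws, level = 0.95, parameter = NULL) {
  x <- if (inherits(draws, "posterior_draws")) {
    extract_draws(draws, parameter)
  } else {
    as.numeric(draws)
  }
  if (length(x) == 0) {
    abort("bci needs at least one draw", class = "rlddm_parameter_error")
  }
  alpha <- (1 - level) / 2
  q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, na.rm = FALSE)
  c(low = q[1], high = q[2])
}

#' Summarize posterior draws
#'
#' @param object A `posterior_draws` object.
#' @param parameters Optional subset of parameter names.
#' @param level Credible-interval mass.
#' @param ... Unused.
#' @return A `posterior_summary` tibble: `parameter`, `mean`, `bci_low`,
#'   `bci_high`, `rhat`.
#' @export
summary.posterior_draws <- function(object, parameters = NULL, level = 0.95,
                                    ...) {
  pars <- parameters %||% dimnames(object$draws)[[3]]
  rows <- lapply(pars, function(p) {
    x <- extract_draws(object, p)
    ci <- bci(x, level = level)
    tibble::tibble(parameter = p, mean = mean(x), bci_low = ci[["low"]],
                   bci_high = ci[["high"]],
                   rhat = as.numeric(rhat(object, p)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("posterior_summary", class(out))
  out
}

#' Sampler settings
#'
#' Chains, total iterations per chain, warmup iterations (discarded;
#' defaults to half, matching the convention of discarding the first half
#' of each chain), and an optional seed that makes the draws bitwise
#' reproducible. The full-scale study convention is
#' `default_settings(chains = 4, iter = 10000)`.
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (warmup included).
#' @param warmup Warmup iterations discarded from each chain.
#' @param seed Optional integer seed.
#' @return A named list.
#' @export
default_settings <- function(chains = 4, iter = 2000, warmup = iter %/% 2,
                             seed = NULL) {
  list(chains = as.integer(chains), iter = as.integer(iter),
       warmup = as.integer(warmup), seed = seed)
}

# Robbins-Monro-style batch adaptation of a log step size toward a target
# acceptance rate (0.44 is optimal-ish for scalar proposals).
adapt_step <- function(step, accept_rate, batch, target = 0.44) {
  delta <- min(0.1, 1 / sqrt(batch))
  step * exp(ifelse(accept_rate > target, delta, -delta))
}

#' Generic adaptive Metropolis-within-Gibbs sampler
#'
#' Scalar random-walk proposals on each coordinate of an unconstrained
#' parameter vector, with per-coordinate step sizes adapted during warmup
#' toward a 0.44 acceptance rate and frozen afterwards. This is the engine
#' behind the cell-means effect model and the conjugate-toy validation; the
#' hierarchical model fits use a more specialized slice-within-Gibbs kernel
#' (see [fit_rlddm()]).
#'
#' @param log_post Function mapping a named parameter vector to the log
#'   posterior density (may return `-Inf`).
#' @param init Function returning an initial named parameter vector (re-drawn
#'   up to 100 times per chain until the log posterior is finite), or a fixed
#'   named vector.
#' @param settings Sampler settings from [default_settings()]: `chains`,
#'   `iter`, `warmup`, `seed`. Retained draws per chain = `iter - warmup`.
#' @param step0 Initial proposal SD (scalar or per-parameter).
#' @return A `posterior_draws` object.
#' @examples
#' # conjugate-normal toy: posterior N(0.5 * ybar * n/(n*0.5+1)...,) checked
#' set.seed(1); y <- rnorm(50, 1, 1)
#' lp <- function(th) sum(dnorm(y, th[["mu"]], 1, log = TRUE)) +
#'   dnorm(th[["mu"]], 0, 1, log = TRUE)
#' d <- mcmc_mwg(lp, c(mu = 0), default_settings(chains = 2, iter = 500))
#' @export
mcmc_mwg <- function(log_post, init, settings = default_settings(),
                     step0 = 0.5) {
  if (!is.null(settings$seed)) set.seed(settings$seed)
  init_fun <- if (is.function(init)) init else function() init
  proto <- init_fun()
  pn <- names(proto)
  if (is.null(pn)) abort("init must be named", class = "rlddm_parameter_error")
  K <- length(proto)
  n_keep <- settings$iter - settings$warmup
  arr <- array(NA_real_, c(n_keep, settings$chains, K),
               dimnames = list(NULL, NULL, pn))
  batch_size <- 25L
  for (ch in seq_len(settings$chains)) {
    theta <- find_finite_init(init_fun, log_post)
    lp <- log_post(theta)
    step <- rep_len(step0, K)
    acc <- integer(K)
    for (it in seq_len(settings$iter)) {
      for (k in seq_len(K)) {
        prop <- theta
        prop[k] <- theta[k] + rnorm(1, 0, step[k])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[k] <- acc[k] + 1L
        }
      }
      if (it <= settings$warmup && it %% batch_size == 0) {
        step <- adapt_step(step, acc / batch_size, it %/% batch_size)
        acc <- integer(K)
      }
      if (it > settings$warmup) {
        arr[it - settings$warmup, ch, ] <- theta
      }
    }
  }
  new_posterior_draws(arr, settings$warmup, settings$seed)
}

find_finite_init <- function(init_fun, log_post, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    theta <- init_fun()
    if (is.finite(log_post(theta))) return(theta)
  }
  abort("no finite initial log density after 100 draws",
        class = "rlddm_initialization_error")
}

# half-normal(0, scale) log density for an SD parameterized by its log
# (includes the log-Jacobian of the exp transform)
log_halfnormal_logsd <- function(log_sd, scale = 1) {
  sd <- exp(log_sd)
  dnorm(sd, 0, scale, log = TRUE) + log(2) + log_sd
}
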