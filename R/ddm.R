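#' Diffusion decision model parameters for a single decision
#'
#' Bundles the three free parameters of the unbiased diffusion decision model
#' (DDM): drift rate `v`, threshold separation `a`, and non-decision time
#' `ndt`. The relative start point is fixed at 0.5 (evidence accumulation
#' starts from half the threshold, i.e. unbiased) and the diffusion noise
#' constant is fixed at 1, which sets the scale of `v` and `a`.
#'
#' @param v Drift rate (evidence units per second). Positive values favour the
#'   upper (correct) boundary.
#' @param a Threshold separation (evidence units), strictly positive.
#' @param ndt Non-decision time in seconds (stimulus encoding + motor time),
#'   non-negative.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, ndt = 0.3)
#' @export
ddm_params <- function(v, a, ndt) {
  if (!is.numeric(v) || !is.numeric(a) || !is.numeric(ndt)) {
    abort("v, a and ndt must be numeric", class = "rlddm_parameter_error")
  }
  if (any(a <= 0)) {
    abort("threshold separation 'a' must be > 0", class = "rlddm_parameter_error")
  }
  if (any(ndt < 0)) {
    abort("non-decision time 'ndt' must be >= 0", class = "rlddm_parameter_error")
  }
  structure(list(v = v, a = a, ndt = ndt, z_rel = 0.5, c = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params> v =", format(x$v), " a =", format(x$a),
      " ndt =", format(x$ndt), "(z_rel = 0.5, c = 1)\n")
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  if (is.list(x) && all(c("v", "a", "ndt") %in% names(x))) {
    return(ddm_params(x$v, x$a, x$ndt))
  }
  abort("cannot interpret input as ddm_params", class = "rlddm_parameter_error")
}

#' Wiener first-passage-time density
#'
#' Defective density of the first passage through one boundary of the diffusion
#' process at clock time `t` (seconds). The density is zero for
#' `t <= ndt` and the two boundary densities integrate jointly to one. The
#' evaluation switches automatically between the small-time and large-time
#' series expansions, truncated at a tolerance of 1e-7.
#'
#' @param t Vector of clock times (seconds).
#' @param boundary `"upper"` (the correct option) or `"lower"`.
#' @param params A [ddm_params()] object (vectorized parameters of matching
#'   length are allowed).
#' @return Density values (1/seconds), same length as `t`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, ndt = 0.3)
#' wfpt_density(c(0.2, 0.5, 1), "upper", p)
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  b <- if (boundary == "upper") 1L else -1L
  cpp_wfpt_density(as.numeric(t), b, as.numeric(params$v),
                   as.numeric(params$a), as.numeric(params$ndt), 0.5)
}

#' Probability of absorbing at the upper (correct) boundary
#'
#' Closed form for the unbiased diffusion with unit noise:
#' `P(upper) = 1 / (1 + exp(-v * a))`. Independent of the non-decision time.
#'
#' @param v Drift rate.
#' @param a Threshold separation, > 0.
#' @return Probability in (0, 1), vectorized over `v` and `a`.
#' @examples
#' choice_prob_upper(0, 2)    # 0.5 by symmetry
#' choice_prob_upper(1, 2)
#' @export
choice_prob_upper <- function(v, a) {
  if (any(a <= 0)) {
    abort("threshold separation 'a' must be > 0", class = "rlddm_parameter_error")
  }
  plogis(v * a)
}

#' Simulate first passages of the diffusion process
#'
#' Brute-force Euler--Maruyama simulation of the bounded accumulator, the
#' package's numerical oracle for the analytic density. Uses R's RNG: call
#' `set.seed()` beforehand for reproducibility.
#'
#' @param n Number of simulated decisions.
#' @param params A [ddm_params()] object.
#' @param dt Euler step in seconds (default 1e-3; use smaller steps when
#'   high-accuracy passage-time distributions are needed, since the plain
#'   Euler scheme biases passage times upward by O(sqrt(dt))).
#' @param max_t Cap on the decision time in seconds; paths still in play at
#'   the cap are returned as `boundary = NA, rt = NA`.
#' @return A tibble with columns `boundary` (`"upper"`/`"lower"`, `NA` if
#'   capped) and `rt` (seconds, passage time + ndt).
#' @examples
#' set.seed(1)
#' sims <- simulate_ddm(100, ddm_params(v = 1, a = 2, ndt = 0.3))
#' mean(sims$boundary == "upper", na.rm = TRUE)
#' @export
simulate_ddm <- function(n, params, dt = 1e-3, max_t = 20) {
  params <- as_ddm_params(params)
  if (dt <= 0) abort("dt must be > 0", class = "rlddm_parameter_error")
  m <- cpp_sim_ddm(as.integer(n), as.numeric(params$v), as.numeric(params$a),
                   as.numeric(params$ndt), 0.5, dt, max_t)
  tibble::tibble(
    boundary = c("lower", NA, "upper")[m[, 1] + 2],
    rt = m[, 2]
  )
}

#' Joint choice/response-time log-likelihood under the DDM
#'
#' Sum over trials of the log Wiener first-passage density at the observed
#' boundary and time. Any trial with `rt <= ndt` yields `-Inf` (an impossible
#' parameter value, which a sampler rejects rather than erroring).
#'
#' @param rt Vector of response times (seconds).
#' @param boundary Character vector (`"upper"`/`"lower"`) or +1/-1 integers;
#'   upper = correct response.
#' @param params A [ddm_params()] object; `v`, `a`, `ndt` may be per-trial
#'   vectors.
#' @return A single log-likelihood value (0 for an empty trial set).
#' @export
wfpt_loglik <- function(rt, boundary, params) {
  params <- as_ddm_params(params)
  if (length(rt) == 0) return(0)
  if (is.character(boundary)) {
    if (!all(boundary %in% c("upper", "lower"))) {
      abort("boundary must be 'upper' or 'lower'", class = "rlddm_parameter_error")
    }
    boundary <- ifelse(boundary == "upper", 1L, -1L)
  }
  cpp_wfpt_loglik(as.numeric(rt), as.integer(boundary), as.numeric(params$v),
                  as.numeric(params$a), as.numeric(params$ndt), 0.5)
}
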