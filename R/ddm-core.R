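#' Drift-diffusion model parameters
#'
#' Bundles the four parameters of a two-boundary Wiener diffusion with unit
#' diffusion coefficient: the process starts at `z = z_rel * a`, drifts at
#' rate `v` (positive toward the upper boundary at `a`, lower boundary at 0),
#' and the observed response time is the first-passage time plus the
#' non-decision time `tau`. The diffusion coefficient is fixed at s = 1, the
#' convention of most hierarchical DDM software; all times are in seconds.
#'
#' @param v Drift rate (evidence units per second, signed).
#' @param a Boundary separation (> 0).
#' @param z_rel Relative starting point in (0, 1); the absolute start is
#'   `z_rel * a`. 0.5 is unbiased.
#' @param tau Non-decision time in seconds (>= 0).
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1.5, a = 2, z_rel = 0.5, tau = 0.3)
#' prob_upper(p)
#' @export
ddm_params <- function(v, a, z_rel = 0.5, tau = 0) {
  vals <- c(v = v, a = a, z_rel = z_rel, tau = tau)
  if (length(vals) != 4L || !all(is.finite(vals)))
    stop("all DDM parameters must be finite scalars")
  if (a <= 0) stop("boundary separation 'a' must be > 0")
  if (z_rel <= 0 || z_rel >= 1) stop("'z_rel' must lie strictly in (0, 1)")
  if (tau < 0) stop("non-decision time 'tau' must be >= 0")
  structure(list(v = v, a = a, z_rel = z_rel, tau = tau, s = 1),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.4g, a = %.4g, z_rel = %.4g, tau = %.4g (s = 1)\n",
              x$v, x$a, x$z_rel, x$tau))
  invisible(x)
}

.as_ddm_params <- function(params) {
  if (!inherits(params, "ddm_params")) stop("'params' must be a ddm_params object")
  params
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form absorption probability of the Wiener diffusion (the classic
#' gambler's-ruin formula): `(1 - exp(-2 v z)) / (1 - exp(-2 v a))` with
#' `z = z_rel * a`, evaluated stably via `expm1`; the zero-drift limit is
#' `z_rel`.
#'
#' @param params A [ddm_params()] object.
#' @return Probability in \[0, 1\] that the process hits the upper boundary.
#' @examples
#' prob_upper(ddm_params(v = 1, a = 2))  # ~0.8808
#' @export
prob_upper <- function(params) {
  params <- .as_ddm_params(params)
  prob_upper_cpp(params$v, params$a, params$z_rel)
}

#' First-passage-time density of the Wiener diffusion
#'
#' Defective density of absorption at the requested boundary at decision time
#' `t` (seconds, non-decision time excluded). The density integrates over t
#' to the probability of that choice, not to 1. Two series expansions are
#' implemented -- the large-time Fourier form and the small-time image
#' (reflection) form -- and `method = "auto"` picks whichever needs fewer
#' terms for the requested truncation tolerance.
#'
#' @param t Vector of decision times (> 0), seconds.
#' @param boundary `"upper"` or `"lower"`.
#' @param params A [ddm_params()] object; `tau` is ignored here (pass decision
#'   times directly).
#' @param tol Absolute truncation tolerance of the series (> 0).
#' @param method `"auto"` (default), `"small_time"` or `"large_time"`.
#' @return Vector of density values (1/s), zero for `t <= 0` is an error.
#' @examples
#' p <- ddm_params(v = 1, a = 2)
#' fpt_density(c(0.1, 0.5, 1), "upper", p)
#' @export
fpt_density <- function(t, boundary = c("upper", "lower"), params,
                        tol = 1e-7, method = c("auto", "small_time", "large_time")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  params <- .as_ddm_params(params)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("'t' must be positive and finite")
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0)
    stop("'tol' must be a positive scalar")
  m <- match(method, c("auto", "small_time", "large_time")) - 1L
  wiener_pdf_cpp(t, boundary == "upper", params$v, params$a, params$z_rel,
                 tol, m)
}

#' Simulate choices and response times from the diffusion process
#'
#' Forward Euler--Maruyama simulation of the Wiener process with a
#' Brownian-bridge correction for boundary crossings inside a step (which
#' removes the leading-order discretization bias in absorption). Response
#' time equals the absorption time plus the non-decision time.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials (>= 1).
#' @param seed Integer seed; identical seeds give identical output.
#' @param dt Time step in seconds (default 1e-4).
#' @param tmax Maximum decision time simulated; trials unabsorbed by then get
#'   `NA` response time and boundary.
#' @return A data.frame with columns `boundary` (factor upper/lower, `NA` if
#'   unabsorbed) and `rt` (seconds).
#' @examples
#' sim <- sample_trials(ddm_params(v = 2, a = 1.5, tau = 0.3), n = 10, seed = 1)
#' @export
sample_trials <- function(params, n, seed, dt = 1e-4, tmax = 10) {
  params <- .as_ddm_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  if (dt <= 0 || dt > 0.01) stop("'dt' must be in (0, 0.01]")
  res <- sim_trials_cpp(as.integer(n), params$v, params$a, params$z_rel,
                        params$tau, dt, tmax, as.double(seed))
  boundary <- factor(ifelse(res$boundary < 0, NA_character_,
                            ifelse(res$boundary == 1, "upper", "lower")),
                     levels = c("upper", "lower"))
  data.frame(boundary = boundary, rt = res$rt)
}

#' Joint log-likelihood of choice and response-time data
#'
#' Sums the log defective first-passage density over trials, evaluated at
#' `rt - tau` for the boundary each trial terminated at. Any trial with
#' `rt <= tau` makes the data impossible under the parameters and the
#' function returns `-Inf`.
#'
#' @param trials A data.frame with columns `boundary` ("upper"/"lower") and
#'   `rt` (seconds), e.g. from [sample_trials()].
#' @param params A [ddm_params()] object.
#' @param tol Series truncation tolerance.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
loglik_trials <- function(trials, params, tol = 1e-7) {
  params <- .as_ddm_params(params)
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    stop("'trials' must be a non-empty data.frame")
  if (!all(c("boundary", "rt") %in% names(trials)))
    stop("'trials' needs columns 'boundary' and 'rt'")
  b <- as.character(trials$boundary)
  if (any(is.na(b)) || !all(b %in% c("upper", "lower")))
    stop("every trial must have boundary 'upper' or 'lower'")
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
    stop("all response times must be positive")
  loglik_cpp(trials$rt, b == "upper", params$v, params$a, params$z_rel,
             params$tau, tol)
}
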