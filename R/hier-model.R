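# Hierarchical Bayesian estimation of the twelve-group drift-diffusion model.

#' MCMC configuration
#'
#' Defaults follow the full estimation profile (60,000 draws, 5,000 burn-in).
#' For desk-scale checks a short profile such as
#' `fit_config(3000, 500, thin = 1)` is adequate.
#'
#' @param n_samples Total MCMC draws.
#' @param burn_in Draws discarded from the front (`< n_samples`).
#' @param seed Integer seed; fits are bit-reproducible given the seed.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_samples = 60000, burn_in = 5000, seed = 1, thin = 10) {
  if (burn_in >= n_samples) stop("'burn_in' must be smaller than 'n_samples'")
  if (thin < 1) stop("'thin' must be >= 1")
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in),
                 seed = as.double(seed), thin = as.integer(thin)),
            class = "fit_config")
}

#' Default priors of the hierarchical model
#'
#' Weakly informative defaults chosen to match common hierarchical-DDM
#' practice: group mean drift Normal(0, 2); group mean boundary Gamma(1.5,
#' 0.75) truncated above 0.3; group mean non-decision time Uniform(0.05,
#' min observed RT); group starting point Beta(2, 2); half-normal group
#' spreads (unit scale for v and a; 0.2 for the starting point whose support
#' is (0,1)).
#'
#' @param tau_ub Upper bound of the non-decision-time prior (set from the
#'   data by [build_model()]).
#' @return Named list of hyperparameters.
#' @export
default_priors <- function(tau_ub = 1) {
  list(mu_v_mean = 0, mu_v_sd = 2,
       a_shape = 1.5, a_rate = 0.75, a_lb = 0.3,
       tau_lb = 0.05, tau_ub = tau_ub,
       z_a = 2, z_b = 2,
       sig_scale_v = 1, sig_scale_a = 1, sig_scale_t = 1, sig_scale_w = 0.2)
}

#' Build the hierarchical model specification from a trial table
#'
#' Prepares one evaluation task of the canonical trial table for fitting:
#' each of the twelve valence groups gets its own family of drift rates,
#' boundary separations and non-decision times (group-level mean and spread,
#' one value per participant), while the relative starting point is a single
#' per-participant value shared across all groups. In the moral task the
#' upper boundary is the "moral" response and the lower the "immoral" one,
#' so moral words load on positive drift. The `"no_bias"` variant pins the
#' starting point at 0.5 instead of estimating it.
#'
#' Timeout trials are always dropped; by default incorrect responses are
#' dropped too (the convention of deadline evaluation studies), while
#' `include_errors = TRUE` keeps both boundaries' responses, making the
#' defective-density likelihood match the full generative process.
#'
#' @param trials Canonical trial table (see [simulate_dataset()]).
#' @param variant `"bias"` (estimate the starting point) or `"no_bias"`.
#' @param task Which task to fit (default `"moral"`).
#' @param include_errors Keep incorrect responses (default FALSE).
#' @param priors Optional prior list, see [default_priors()].
#' @return A `ddm_model_spec` object.
#' @export
build_model <- function(trials, variant = c("bias", "no_bias"),
                        task = "moral", include_errors = FALSE,
                        priors = NULL) {
  variant <- match.arg(variant)
  labels <- .cell_labels()
  tr <- trials[trials$task == task & !trials$timeout & !is.na(trials$response), ,
               drop = FALSE]
  if (!include_errors) tr <- tr[tr$correct, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no usable trials for task '", task, "'")
  bad <- setdiff(unique(tr$group), labels)
  if (length(bad) > 0L)
    stop("unknown valence group label(s): ", paste(bad, collapse = ", "))
  if (length(unique(tr$group)) < length(labels))
    stop("all ", length(labels), " valence groups must be present; found ",
         length(unique(tr$group)))
  participants <- sort(unique(tr$participant_id))
  if (length(participants) < 2L) stop("need >= 2 participants")
  upper_resp <- if (task == "moral") "moral" else "positive"
  dat <- data.frame(
    rt = tr$rt_ms / 1000,
    upper = tr$response == upper_resp,
    pid = match(tr$participant_id, participants) - 1L,
    cell = match(tr$group, labels) - 1L
  )
  if (any(dat$rt <= 0)) stop("non-positive response times in data")
  # prior upper bound for the group-mean non-decision time: each participant's
  # own t0 is already bounded by their fastest trial through the likelihood,
  # so the group mean may range up to the largest participant-level minimum RT
  tau_cap <- max(tapply(dat$rt, dat$pid, min)) * 0.999
  priors <- if (is.null(priors)) default_priors(tau_ub = tau_cap) else priors
  structure(list(data = dat, participants = participants, groups = labels,
                 P = length(participants), G = length(labels),
                 variant = variant, task = task,
                 include_errors = include_errors, priors = priors),
            class = "ddm_model_spec")
}

#' Prior-only model specification
#'
#' A model with no trials attached: sampling from it draws from the joint
#' prior, which is useful for validating the sampler against direct prior
#' simulation and for prior predictive exploration.
#'
#' @param n_participants Number of (data-free) participants.
#' @param variant `"bias"` or `"no_bias"`.
#' @param priors Prior list, see [default_priors()].
#' @return A `ddm_model_spec` with an empty trial table.
#' @export
prior_only_model <- function(n_participants = 8,
                             variant = c("bias", "no_bias"),
                             priors = default_priors(tau_ub = 1)) {
  variant <- match.arg(variant)
  labels <- .cell_labels()
  structure(list(
    data = data.frame(rt = numeric(0), upper = logical(0),
                      pid = integer(0), cell = integer(0)),
    participants = sprintf("P%02d", seq_len(n_participants)),
    groups = labels, P = n_participants, G = length(labels),
    variant = variant, task = "moral", include_errors = FALSE,
    priors = priors), class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat(sprintf("hierarchical DDM spec (%s variant): %d participants, %d groups, %d trials\n",
              x$variant, x$P, x$G, nrow(x$data)))
  cat(sprintf("free parameter families: 12 x (v, a, tau)%s\n",
              if (x$variant == "bias") " + shared starting point z_rel" else
                "; z_rel fixed at 0.5"))
  invisible(x)
}

# EZ-style moment inits for one participant x group cell (s = 1)
.ez_init <- function(rt, upper) {
  n <- length(rt)
  fallback <- c(v = if (mean(upper) >= 0.5) 1 else -1, a = 1.8,
                ter = max(0.05, 0.7 * min(rt)))
  if (n < 4L) return(fallback)
  sgn <- if (mean(upper) >= 0.5) 1 else -1
  pc <- max(mean(upper), 1 - mean(upper))
  pc <- min(max(pc, 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
  vrt <- var(rt)
  if (!is.finite(vrt) || vrt <= 1e-6) return(fallback)
  L <- log(pc / (1 - pc))
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  if (!is.finite(x) || x <= 0) return(fallback)
  vmag <- x^0.25
  a <- L / vmag
  y <- -vmag * a
  mdt <- (a / (2 * vmag)) * (1 - exp(y)) / (1 + exp(y))
  ter <- mean(rt) - mdt
  v <- sgn * min(max(vmag, 0.05), 8)
  a <- min(max(a, 0.35), 4)
  ter <- min(max(ter, 0.03), 0.95 * min(rt))
  c(v = v, a = a, ter = ter)
}

.make_inits <- function(model) {
  P <- model$P; G <- model$G
  v0 <- matrix(0, P, G); a0 <- matrix(1.8, P, G); t0 <- matrix(0.25, P, G)
  d <- model$data
  for (g in seq_len(G) - 1L) {
    for (p in seq_len(P) - 1L) {
      sel <- d$pid == p & d$cell == g
      if (any(sel)) {
        ez <- .ez_init(d$rt[sel], d$upper[sel])
        t_cap <- if (any(sel)) 0.9 * min(d$rt[sel]) else 1
        v0[p + 1, g + 1] <- ez["v"]
        a0[p + 1, g + 1] <- ez["a"]
        t0[p + 1, g + 1] <- min(ez["ter"], t_cap)
      }
    }
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  list(v = v0, a = a0, t0 = t0, w = rep(0.5, P),
       mu_v = clamp(colMeans(v0), -8, 8),
       sig_v = clamp(apply(v0, 2, sd), 0.1, 2),
       mu_a = clamp(colMeans(a0), 0.35, 4),
       sig_a = clamp(apply(a0, 2, sd), 0.1, 2),
       mu_t = clamp(colMeans(t0), model$priors$tau_lb + 1e-3,
                    model$priors$tau_ub - 1e-3),
       sig_t = clamp(apply(t0, 2, sd), 0.05, 1),
       mu_w = 0.5, sig_w = 0.1)
}

#' Draw from the joint posterior of the hierarchical model
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler (proposal adaptation is
#' confined to burn-in). Chains are initialised from EZ-style moment
#' estimates of each participant x group cell. The returned object carries
#' the post-burn-in draws of all group-level parameters and the deviance,
#' thinned participant-level draws, and convergence diagnostics (split
#' R-hat, effective sample size, autocorrelation profiles). A warning is
#' attached (and emitted) when any group-level R-hat exceeds 1.1.
#'
#' @param model A [build_model()] specification.
#' @param config A [fit_config()].
#' @return A `ddm_fit` object.
#' @export
sample_posterior <- function(model, config = fit_config()) {
  if (!inherits(model, "ddm_model_spec")) stop("'model' must come from build_model()")
  if (!inherits(config, "fit_config")) stop("'config' must come from fit_config()")
  d <- model$data
  inits <- .make_inits(model)
  res <- ddm_mcmc_cpp(d$rt, d$upper, d$pid, d$cell, model$P, model$G,
                      model$variant == "bias",
                      config$n_samples, config$burn_in, config$thin,
                      config$seed, model$priors, inits, 1e-7)
  labels <- model$groups
  gnames <- c(paste0("mu_v_", labels), paste0("sig_v_", labels),
              paste0("mu_a_", labels), paste0("sig_a_", labels),
              paste0("mu_t_", labels), paste0("sig_t_", labels))
  if (model$variant == "bias") gnames <- c(gnames, "mu_z", "sig_z")
  gnames <- c(gnames, "deviance")
  colnames(res$group) <- gnames
  inames <- c(outer(model$participants, labels,
                    function(p, g) paste0("v_", p, "_", g)),
              c(outer(model$participants, labels,
                      function(p, g) paste0("a_", p, "_", g))),
              c(outer(model$participants, labels,
                      function(p, g) paste0("t0_", p, "_", g))))
  if (model$variant == "bias")
    inames <- c(inames, paste0("z_", model$participants))
  colnames(res$indiv) <- inames

  diag_cols <- setdiff(gnames, "deviance")
  diagnostics <- chain_diagnostics(res$group[, diag_cols, drop = FALSE])
  not_converged <- diagnostics$summary$rhat > 1.1
  warn <- NULL
  if (any(not_converged)) {
    warn <- paste0("R-hat > 1.1 for: ",
                   paste(diagnostics$summary$parameter[not_converged],
                         collapse = ", "))
    warning(warn, call. = FALSE)
  }
  structure(list(model = model, config = config,
                 chains = res$group, indiv = res$indiv,
                 accept = res$accept, diagnostics = diagnostics,
                 warnings = warn),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("hierarchical DDM fit (%s variant): %d kept draws, %d participants\n",
              x$model$variant, nrow(x$chains), x$model$P))
  cat(sprintf("max group-level R-hat: %.3f; min ESS: %.0f\n",
              max(x$diagnostics$summary$rhat),
              min(x$diagnostics$summary$ess)))
  if (!is.null(x$warnings)) cat("WARNING:", x$warnings, "\n")
  invisible(x)
}

#' Posterior means of the group-level parameters
#'
#' @param fit A `ddm_fit`.
#' @param param One of `"mu_v"`, `"mu_a"`, `"mu_t"` (group means) or the
#'   spreads `"sig_v"`, `"sig_a"`, `"sig_t"`.
#' @return Named numeric vector over the twelve groups.
#' @export
group_means <- function(fit, param = "mu_v") {
  cols <- paste0(param, "_", fit$model$groups)
  setNames(colMeans(fit$chains[, cols, drop = FALSE]), fit$model$groups)
}

#' Extract the posterior draws of one parameter
#'
#' @param fit A `ddm_fit`.
#' @param name Column name in the group-level (or, if not found there,
#'   participant-level) draw matrix, e.g. `"mu_v_moral_2V1M"`.
#' @return Numeric vector of post-burn-in draws.
#' @export
posterior_draws <- function(fit, name) {
  if (name %in% colnames(fit$chains)) return(fit$chains[, name])
  if (name %in% colnames(fit$indiv)) return(fit$indiv[, name])
  stop("unknown parameter '", name, "'")
}
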