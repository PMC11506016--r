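# Posterior inference: difference distributions, DIC, posterior predictive
# checks.

#' Posterior difference distribution between two parameters
#'
#' Element-wise difference `a - b` of two aligned posterior sample vectors,
#' summarised by its mean and the percentages of mass below and above zero.
#' The difference is called significant when at least 95% of it falls on one
#' side of zero. Draws exactly equal to zero are counted half to each side.
#'
#' @param samples_a,samples_b Equal-length numeric vectors of aligned
#'   posterior draws.
#' @return A `diff_summary` object: mean, pct_below_zero, pct_above_zero,
#'   significant.
#' @examples
#' d <- diff_distribution(rnorm(1e4, 0.5), rnorm(1e4, 0))
#' print(d)
#' @export
diff_distribution <- function(samples_a, samples_b) {
  if (length(samples_a) != length(samples_b))
    stop("posterior sample vectors must have equal length")
  if (length(samples_a) == 0L) stop("empty posterior samples")
  d <- samples_a - samples_b
  ties <- mean(d == 0)
  below <- 100 * (mean(d < 0) + ties / 2)
  above <- 100 * (mean(d > 0) + ties / 2)
  structure(list(mean = mean(d), pct_below_zero = below,
                 pct_above_zero = above,
                 significant = max(below, above) >= 95),
            class = "diff_summary")
}

#' Format a difference summary in reporting style
#'
#' Renders a [diff_distribution()] result as e.g.
#' `"M = 1.21, 0.2% < 0 < 99.8%"`, with a trailing `*` when the 95%
#' directional rule is met.
#'
#' @param x A `diff_summary`.
#' @param digits Digits for the mean.
#' @return Character scalar.
#' @export
format_diff_summary <- function(x, digits = 2) {
  stopifnot(inherits(x, "diff_summary"))
  sprintf("M = %.*f, %.1f%% < 0 < %.1f%%%s", digits, x$mean,
          x$pct_below_zero, x$pct_above_zero,
          if (x$significant) " *" else "")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(format_diff_summary(x), "\n")
  invisible(x)
}

# participant-level posterior means arranged as P x G matrices (+ z vector)
.point_params <- function(fit) {
  m <- fit$model
  im <- colMeans(fit$indiv)
  pick <- function(prefix) {
    matrix(im[c(outer(m$participants, m$groups,
                      function(p, g) paste0(prefix, "_", p, "_", g)))],
           m$P, m$G)
  }
  w <- if (m$variant == "bias") unname(im[paste0("z_", m$participants)]) else
    rep(0.5, m$P)
  list(v = pick("v"), a = pick("a"), t0 = pick("t0"), w = w)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = Dbar + pD` where `Dbar` is the posterior mean deviance
#' (`D = -2 log L`, accumulated during sampling) and
#' `pD = Dbar - D(theta_bar)` is the effective number of parameters, with
#' `theta_bar` the posterior mean of the participant-level parameters.
#' Lower values indicate better expected predictive fit.
#'
#' @param fit A `ddm_fit`.
#' @return Scalar DIC, with attributes `Dbar`, `pD` and `D_at_mean`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  dev <- fit$chains[, "deviance"]
  if (any(!is.finite(dev))) stop("non-finite deviance draws; cannot compute DIC")
  dbar <- mean(dev)
  pp <- .point_params(fit)
  d <- fit$model$data
  ll <- loglik_point_cpp(d$rt, d$upper, d$pid, d$cell, fit$model$P,
                         fit$model$G, pp$v, pp$a, pp$t0, pp$w, 1e-7)
  if (!is.finite(ll)) stop("non-finite deviance at the posterior mean")
  d_hat <- -2 * ll
  pd <- dbar - d_hat
  structure(dbar + pd, Dbar = dbar, pD = pd, D_at_mean = d_hat)
}

#' Posterior predictive check
#'
#' Simulates replicated datasets from randomly chosen posterior draws of the
#' participant-level parameters, matching the observed trial counts per
#' participant x group cell. For each valence group it summarises the upper
#' boundary choice proportion and RT quantiles (10/30/50/70/90%) at each
#' boundary, and compares the observed statistics against the central 95%
#' predictive interval.
#'
#' @param fit A `ddm_fit`.
#' @param n_rep Number of replicated datasets (default 100).
#' @param seed Integer seed.
#' @param dt Simulator step (seconds).
#' @return List with `stats` (long data.frame: group, statistic, observed,
#'   lower, upper, covered), `coverage` (fraction of covered cells) and
#'   `coverage_ok` (coverage >= 0.9).
#' @export
posterior_predict <- function(fit, n_rep = 100, seed = 1, dt = 1e-4) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (n_rep < 1) stop("'n_rep' must be >= 1")
  m <- fit$model
  d <- m$data
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)

  cell_stats <- function(rt, upper) {
    out <- c(prop_upper = mean(upper))
    for (side in c(TRUE, FALSE)) {
      r <- rt[upper == side]
      nm <- paste0(if (side) "rt_upper_q" else "rt_lower_q", qs * 100)
      out <- c(out, setNames(
        if (length(r) >= 5) quantile(r, qs, names = FALSE) else rep(NA_real_, 5),
        nm))
    }
    out
  }
  by_group <- function(rt, upper, cell) {
    t(sapply(seq_len(m$G) - 1L, function(g) {
      sel <- cell == g
      if (!any(sel)) return(rep(NA_real_, 11))
      cell_stats(rt[sel], upper[sel])
    }))
  }
  obs <- by_group(d$rt, d$upper, d$cell)

  draw_rows <- .with_seed(seed, sample.int(nrow(fit$indiv), n_rep, replace = TRUE))
  sims <- array(NA_real_, c(m$G, 11, n_rep))
  for (r in seq_len(n_rep)) {
    row <- fit$indiv[draw_rows[r], ]
    pick <- function(prefix) matrix(
      row[c(outer(m$participants, m$groups,
                  function(p, g) paste0(prefix, "_", p, "_", g)))], m$P, m$G)
    v <- pick("v"); a <- pick("a"); t0 <- pick("t0")
    w <- if (m$variant == "bias") unname(row[paste0("z_", m$participants)]) else
      rep(0.5, m$P)
    k <- cbind(d$pid + 1L, d$cell + 1L)
    sim <- sim_schedule_cpp(v[k], a[k], w[d$pid + 1L], t0[k], dt, 5,
                            as.double(seed) * 1000 + r)
    ok <- sim$boundary >= 0
    sims[, , r] <- by_group(sim$rt[ok], sim$boundary[ok] == 1, d$cell[ok])
  }
  lower <- apply(sims, c(1, 2), quantile, 0.025, na.rm = TRUE)
  upper_ <- apply(sims, c(1, 2), quantile, 0.975, na.rm = TRUE)
  stat_names <- colnames(obs)
  stats <- do.call(rbind, lapply(seq_len(m$G), function(g) {
    data.frame(group = m$groups[g], statistic = stat_names,
               observed = obs[g, ], lower = lower[g, ], upper = upper_[g, ],
               row.names = NULL)
  }))
  stats$covered <- !is.na(stats$observed) & is.finite(stats$lower) &
    stats$observed >= stats$lower & stats$observed <= stats$upper
  usable <- !is.na(stats$observed) & is.finite(stats$lower) & is.finite(stats$upper)
  coverage <- mean(stats$covered[usable])
  list(stats = stats, coverage = coverage, coverage_ok = coverage >= 0.9)
}
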