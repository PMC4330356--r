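#' Fit the inheritance model to an observed trajectory
#'
#' Least-squares recovery of the inheritance parameters (initial
#' methylation `m0`, de novo rate `delta`, maintenance efficiency
#' `rho`) from a pooled methylation trajectory sampled over a
#' suppression/recovery timeline.  The suppression phase is modelled
#' with maintenance off (`rho = 0`; that is the experimental
#' manipulation), so `rho` refers to the recovery phase.  The de novo
#' gate is taken as open throughout (`theta = 0`), appropriate for loci
#' whose methylation stays above the gate threshold.
#'
#' The fit proceeds in closed form where possible -- with maintenance
#' off, \eqn{m_{d0} = \delta + (m_0 - \delta) 2^{-T}} inverts exactly
#' for \eqn{\delta} given \eqn{m_0 \approx m_{control}} -- followed by a
#' joint box-constrained quasi-Newton refinement.  On noise-free model
#' output the generating parameters are recovered to numerical
#' precision.
#'
#' @param trajectory Named numeric vector of observed methylation
#'   fractions; names must be timepoints of `tl` and include at least 3
#'   timepoints.
#' @param tl A [timeline()].
#' @return An object of class `"dynamics_fit"` with components
#'   `coefficients` (`m0`, `delta`, `rho`), `fitted.values`,
#'   `residuals`, `observed`, `timeline`, `sse`, `rho_identifiable`,
#'   and `degenerate` (TRUE for a constant-zero trajectory, where only
#'   `delta = 0` is identified).
#' @seealso [expected_trajectory()], [simulate_experiment()]
#' @export
fit_dynamics <- function(trajectory, tl = timeline()) {
  stopifnot(is.numeric(trajectory), !is.null(names(trajectory)))
  obs <- trajectory[!is.na(trajectory)]
  if (length(obs) < 3)
    stop("need at least 3 observed timepoints")
  if (!all(names(obs) %in% tl$timepoints))
    stop("trajectory names must be timeline timepoints")
  if (any(obs < 0 | obs > 1))
    stop("trajectory values must lie in [0, 1]")
  sub_tl <- tl
  keep <- tl$timepoints %in% names(obs)
  sub_tl$timepoints <- tl$timepoints[keep]
  sub_tl$days <- tl$days[keep]
  obs <- obs[sub_tl$timepoints]

  model <- function(par) {
    expected_trajectory(list(m0 = par[1], rho_on = par[3], delta = par[2],
                             delta_recovery = par[2], theta = 0,
                             alleles = 1L), sub_tl)
  }
  sse <- function(par) sum((model(par) - obs)^2)

  has_recovery <- any(timeline_divisions(sub_tl)$n_on > 0)
  degenerate <- all(obs <= 1e-8)
  if (degenerate) {
    par <- c(m0 = 0, delta = 0, rho = NA_real_)
    fitted <- stats::setNames(rep(0, length(obs)), names(obs))
    return(new_dynamics_fit(par, fitted, obs, sub_tl, sse = 0,
                            rho_identifiable = FALSE, degenerate = TRUE))
  }

  # closed-form starts: m0 from control, delta from the d0 plateau
  m0_0 <- if ("control" %in% names(obs)) obs[["control"]] else max(obs)
  t_off <- sub_tl$divisions_off
  delta_0 <- if ("d0" %in% names(obs) && t_off > 0) {
    max(0, min(1, (obs[["d0"]] - m0_0 * 2^-t_off) / (1 - 2^-t_off)))
  } else mean(obs)
  rho_0 <- if (has_recovery) {
    stats::optimize(function(r) sse(c(m0_0, delta_0, r)),
                    c(0, 1), tol = 1e-10)$minimum
  } else 0.5

  starts <- rbind(c(m0_0, delta_0, rho_0),
                  c(m0_0, delta_0, 0.95),
                  c(max(obs), 0.1, 0.5))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], sse, method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(1, 1, 1),
                      control = list(factr = 10, pgtol = 0, maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # coordinate polish: re-solve rho exactly, then one more joint pass
  if (has_recovery) {
    r <- stats::optimize(function(r) sse(c(best$par[1:2], r)), c(0, 1),
                         tol = 1e-12)$minimum
    if (sse(c(best$par[1:2], r)) < best$value) best$par[3] <- r
    o <- stats::optim(best$par, sse, method = "L-BFGS-B",
                      lower = c(0, 0, 0), upper = c(1, 1, 1),
                      control = list(factr = 10, pgtol = 0, maxit = 500))
    if (o$value < best$value) best <- o
  }
  par <- c(m0 = unname(best$par[1]), delta = unname(best$par[2]),
           rho = if (has_recovery) unname(best$par[3]) else NA_real_)
  fitted <- model(c(par[["m0"]], par[["delta"]],
                    if (has_recovery) par[["rho"]] else 0))
  new_dynamics_fit(par, fitted, obs, sub_tl, sse = best$value,
                   rho_identifiable = has_recovery, degenerate = FALSE)
}

new_dynamics_fit <- function(par, fitted, obs, tl, sse,
                             rho_identifiable, degenerate) {
  structure(list(coefficients = par,
                 fitted.values = fitted,
                 residuals = obs - fitted,
                 observed = obs,
                 timeline = tl,
                 sse = sse,
                 rho_identifiable = rho_identifiable,
                 degenerate = degenerate),
            class = "dynamics_fit")
}

#' @export
print.dynamics_fit <- function(x, digits = 4, ...) {
  cat("Methylation inheritance model fit\n")
  cat("  timepoints:", paste(names(x$observed), collapse = ", "), "\n")
  cat("  coefficients:\n")
  print(round(x$coefficients, digits))
  if (!x$rho_identifiable)
    cat("  note: rho not identifiable",
        if (x$degenerate) "(constant-zero trajectory)" else
          "(no recovery timepoints)", "\n")
  invisible(x)
}

#' @export
coef.dynamics_fit <- function(object, ...) object$coefficients

#' @export
fitted.dynamics_fit <- function(object, ...) object$fitted.values

#' @export
residuals.dynamics_fit <- function(object, ...) object$residuals

#' @export
summary.dynamics_fit <- function(object, ...) {
  structure(list(fit = object,
                 rmse = sqrt(mean(object$residuals^2)),
                 n = length(object$observed)),
            class = "summary.dynamics_fit")
}

#' @export
print.summary.dynamics_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  n =", x$n, " RMSE =", signif(x$rmse, digits),
      " SSE =", signif(x$fit$sse, digits), "\n")
  invisible(x)
}

#' Predict expected methylation from a fitted inheritance model
#'
#' @param object A `"dynamics_fit"`.
#' @param tl Optional [timeline()]; defaults to the fitting timeline.
#' @param ... Unused.
#' @return Named numeric vector of expected methylation fractions.
#' @export
predict.dynamics_fit <- function(object, tl = NULL, ...) {
  if (is.null(tl)) tl <- object$timeline
  cf <- object$coefficients
  rho <- if (is.na(cf[["rho"]])) 0 else cf[["rho"]]
  expected_trajectory(list(m0 = cf[["m0"]], rho_on = rho,
                           delta = cf[["delta"]],
                           delta_recovery = cf[["delta"]],
                           theta = 0, alleles = 1L), tl)
}

#' Plot an inheritance model fit
#'
#' Observed pooled methylation (points) and the fitted trajectory
#' (line) against cumulative cell divisions.
#'
#' @param x A `"dynamics_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dynamics_fit <- function(x, ...) {
  sched <- timeline_divisions(x$timeline)
  div <- sched$n_off + sched$n_on
  graphics::plot(div, x$observed, xlab = "cell divisions",
                 ylab = "methylation fraction", ylim = c(0, 1),
                 pch = 19, ...)
  graphics::lines(div, x$fitted.values, col = "steelblue")
  graphics::axis(3, at = div, labels = sched$timepoint, cex.axis = 0.7)
  invisible(x)
}

#' Simulate pooled trajectories from a fitted inheritance model
#'
#' Draws `nsim` noisy realisations of the fitted trajectory: each
#' timepoint is observed as the pooled methylated fraction of `n_cpg`
#' CpGs at binomial read depth `coverage`.
#'
#' @param object A `"dynamics_fit"`.
#' @param nsim Number of realisations.
#' @param seed Optional integer seed.
#' @param n_cpg CpGs pooled per timepoint.
#' @param coverage Reads per CpG.
#' @param ... Unused.
#' @return data.frame, one column per realisation, rownames timepoints.
#' @export
simulate.dynamics_fit <- function(object, nsim = 1, seed = NULL,
                                  n_cpg = 100, coverage = 30, ...) {
  mu <- predict(object)
  draw <- function() {
    vapply(mu, function(m)
      stats::rbinom(1, n_cpg * coverage, m) / (n_cpg * coverage),
      numeric(1))
  }
  run <- function() as.data.frame(replicate(nsim, draw()))
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
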