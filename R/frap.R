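#' FRAP region-intensity trace
#'
#' Raw ROI intensities from a fluorescence-recovery-after-photobleaching
#' experiment: the bleached spot, a reference region with signal away from
#' the bleach site, and a signal-free background region. Time is 0 at the
#' first postbleach frame; prebleach frames carry negative times. The bleach
#' itself (tens of ms) is treated as instantaneous relative to the frame
#' interval.
#'
#' @param time Frame times, s; strictly increasing, 0 at first postbleach
#'   frame.
#' @param bleach,reference,background ROI intensities, a.u.; non-negative.
#' @param n_prebleach Number of prebleach frames (>= 1).
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(time, bleach, reference, background, n_prebleach) {
  check_strictly_increasing(time)
  n <- length(time)
  if (length(bleach) != n || length(reference) != n ||
      length(background) != n)
    stop_ftsz("ftszdyn_invalid_argument", "channel lengths differ")
  if (any(bleach < 0) || any(reference < 0) || any(background < 0))
    stop_ftsz("ftszdyn_invalid_argument", "intensities must be >= 0")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n - n_prebleach < 2L)
    stop_ftsz("ftszdyn_invalid_argument",
              "need >= 1 prebleach and >= 2 postbleach frames")
  structure(list(time = as.numeric(time), bleach = as.numeric(bleach),
                 reference = as.numeric(reference),
                 background = as.numeric(background),
                 n_prebleach = n_prebleach),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("FRAP trace: %d prebleach + %d postbleach frames\n",
              x$n_prebleach, length(x$time) - x$n_prebleach))
  invisible(x)
}

#' Double-normalize a FRAP trace
#'
#' Background is subtracted from the bleach and reference channels at each
#' frame, the bleach/reference ratio corrects for acquisition photobleaching
#' and lamp drift, and the result is scaled by its prebleach mean so the
#' prebleach level is 1 by construction:
#' `value(t) = [(bleach - background) / (reference - background)] /
#' prebleach mean of the same ratio`. Adding a constant to all three
#' channels leaves the output unchanged.
#'
#' @param trace A [frap_trace()].
#' @return An object of class `normalized_recovery` with elements `time`,
#'   `value`, `n_prebleach`.
#' @export
normalize_frap <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  denom <- trace$reference - trace$background
  if (any(denom <= 0))
    stop_ftsz("ftszdyn_degenerate_normalization",
              "reference must exceed background at every frame")
  ratio <- (trace$bleach - trace$background) / denom
  pre <- mean(ratio[seq_len(trace$n_prebleach)])
  if (pre <= 0)
    stop_ftsz("ftszdyn_degenerate_normalization",
              "prebleach ratio must be positive")
  structure(list(time = trace$time, value = ratio / pre,
                 n_prebleach = trace$n_prebleach),
            class = "normalized_recovery")
}

#' Two-binding-state FRAP recovery model
#'
#' Evaluates
#' \deqn{FRAP(t) = (1 - r)(1 - C_{eq1} e^{-k_{off1} t} - C_{eq2}
#'   e^{-k_{off2} t})}
#' where `koff1` and `koff2` are dissociation rate constants of two binding
#' states, `c_eq1` and `c_eq2` the corresponding fractions of bound
#' molecules, and `r` accounts for incomplete recovery: the plateau is
#' `1 - r` and `FRAP(0) = (1 - r)(1 - c_eq1 - c_eq2)`.
#'
#' @param t Time since bleach, s.
#' @param fit A `frap_fit` or any list with elements `r`, `c_eq1`, `c_eq2`,
#'   `koff1`, `koff2`.
#' @return Normalized recovery values at `t`.
#' @examples
#' p <- list(r = 0.05, c_eq1 = 0.5, c_eq2 = 0.4, koff1 = 0.05, koff2 = 0.005)
#' model_frap(c(0, 10, Inf), p)
#' @export
model_frap <- function(t, fit) {
  (1 - fit$r) *
    (1 - fit$c_eq1 * exp(-fit$koff1 * t) - fit$c_eq2 * exp(-fit$koff2 * t))
}

# residuals in the (r, s, w, log k1, log k2) parameterisation, which turns
# the constraint c_eq1 + c_eq2 <= 1 into plain box bounds:
# c_eq1 = s * w, c_eq2 = s * (1 - w)
frap_resid <- function(p, t, y) {
  fit <- list(r = p[1], c_eq1 = p[2] * p[3], c_eq2 = p[2] * (1 - p[3]),
              koff1 = exp(p[4]), koff2 = exp(p[5]))
  model_frap(t, fit) - y
}

#' Fit the two-binding-state model to a normalized recovery curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the postbleach
#' points, with multistart over randomized initializations because the
#' bi-exponential surface is ill-conditioned when the two rate constants are
#' close. The lowest-RSS solution is returned with the ordering convention
#' `koff1 >= koff2`. When the optimum has `koff1/koff2 < 2` the two states
#' are weakly identifiable and a reduced single-state fit is attached as
#' `$single_state` for comparison.
#'
#' @param recovery A [normalize_frap()] result (or a list with `time`,
#'   `value`, `n_prebleach`).
#' @param n_starts Number of starts (>= 1; default 20).
#' @param seed Integer seed for the randomized starts.
#' @param koff_limits Bounds on both rate constants, s^-1.
#' @return An object of class `frap_fit`: parameters `r`, `c_eq1`, `c_eq2`,
#'   `koff1`, `koff2`; derived `plateau = 1 - r` and
#'   `recovery_percent = 100 (1 - r)`; `rss`, `max_abs_residual`, `fitted`,
#'   `time`, `value`, plus flags `at_bounds` and `degenerate` (no measurable
#'   recovery, `r` near 1, rate constants not interpretable).
#' @export
fit_frap <- function(recovery, n_starts = 20L, seed = 1L,
                     koff_limits = c(1e-6, 10)) {
  if (is.null(recovery$time) || is.null(recovery$value) ||
      length(recovery$time) != length(recovery$value) ||
      !all(is.finite(recovery$value)))
    stop_ftsz("ftszdyn_invalid_argument",
              "`recovery` must have finite `time` and `value` of equal length")
  if (n_starts < 1L)
    stop_ftsz("ftszdyn_invalid_argument", "`n_starts` must be >= 1")
  post <- recovery$time >= 0
  t <- recovery$time[post]
  y <- recovery$value[post]
  if (length(t) < 10L)
    stop_ftsz("ftszdyn_insufficient_data",
              "need at least 10 postbleach points to fit")
  lower <- c(0, 0, 0, log(koff_limits[1]), log(koff_limits[1]))
  upper <- c(1, 1, 1, log(koff_limits[2]), log(koff_limits[2]))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                     ptol = 1e-13)

  # heuristic start from the data, then randomized starts
  r0 <- min(max(1 - max(y), 0), 1)
  starts <- list(c(r0, 0.9, 0.7, log(0.05), log(0.005)))
  if (n_starts > 1L) {
    rand <- with_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i)
        c(stats::runif(1, 0, 0.8), stats::runif(1, 0.2, 1),
          stats::runif(1),
          log(stats::runif(1, 1e-3, 1)), log(stats::runif(1, 1e-4, 0.1))))
    })
    starts <- c(starts, rand)
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = frap_resid, t = t, y = y, control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop_ftsz("ftszdyn_fit_failure", "no optimizer start converged")

  p <- best$par
  pars <- list(r = p[1], c_eq1 = p[2] * p[3], c_eq2 = p[2] * (1 - p[3]),
               koff1 = exp(p[4]), koff2 = exp(p[5]))
  if (pars$koff2 > pars$koff1) {   # enforce koff1 >= koff2
    pars[c("koff1", "koff2")] <- pars[c("koff2", "koff1")]
    pars[c("c_eq1", "c_eq2")] <- pars[c("c_eq2", "c_eq1")]
  }
  fitted <- model_frap(t, pars)
  resid <- y - fitted
  tol <- 1e-6
  at_bounds <- any(abs(p - lower) < tol | abs(p - upper) < tol)
  degenerate <- pars$r > 0.99

  out <- c(pars,
           list(plateau = 1 - pars$r,
                recovery_percent = 100 * (1 - pars$r),
                rss = sum(resid^2),
                max_abs_residual = max(abs(resid)),
                time = t, value = y, fitted = fitted,
                at_bounds = at_bounds, degenerate = degenerate,
                niter = best$niter))
  class(out) <- "frap_fit"

  if (!degenerate && pars$koff1 / pars$koff2 < 2)
    out$single_state <- fit_frap_single(t, y, n_starts, seed, koff_limits)
  out
}

# reduced single-state model (1-r)(1 - c exp(-k t)) for weakly identifiable
# two-state optima
fit_frap_single <- function(t, y, n_starts, seed, koff_limits) {
  resid1 <- function(p, t, y)
    (1 - p[1]) * (1 - p[2] * exp(-exp(p[3]) * t)) - y
  lower <- c(0, 0, log(koff_limits[1]))
  upper <- c(1, 1, log(koff_limits[2]))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                     ptol = 1e-13)
  starts <- c(list(c(min(max(1 - max(y), 0), 1), 0.9, log(0.01))),
              with_seed(seed + 1L, lapply(seq_len(max(n_starts - 1L, 0)),
                function(i) c(stats::runif(1, 0, 0.8), stats::runif(1),
                              log(stats::runif(1, 1e-4, 1))))))
  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid1, t = t, y = y, control = ctrl),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$deviance) &&
        (is.null(best) || res$deviance < best$deviance))
      best <- res
  }
  if (is.null(best)) return(NULL)
  list(r = best$par[1], c_eq = best$par[2], koff = exp(best$par[3]),
       rss = best$deviance)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("Two-binding-state FRAP fit\n")
  cat(sprintf("  r = %.4g (recovery %.1f%%)\n", x$r, x$recovery_percent))
  cat(sprintf("  c_eq1 = %.4g, koff1 = %.4g /s\n", x$c_eq1, x$koff1))
  cat(sprintf("  c_eq2 = %.4g, koff2 = %.4g /s\n", x$c_eq2, x$koff2))
  cat(sprintf("  rss = %.3g, max |residual| = %.3g\n",
              x$rss, x$max_abs_residual))
  if (isTRUE(x$degenerate))
    cat("  note: no measurable recovery; rate constants not interpretable\n")
  if (!is.null(x$single_state))
    cat(sprintf(
      "  note: koff1/koff2 < 2; single-state fit: koff %.4g /s, rss %.3g\n",
      x$single_state$koff, x$single_state$rss))
  invisible(x)
}

#' Compare two FRAP fits
#'
#' Side-by-side fitted parameters and the difference in percent recovery
#' (`a - b`), e.g. subunit turnover with and without a coassembly partner.
#'
#' @param fit_a,fit_b `frap_fit` objects.
#' @param labels Length-2 character labels.
#' @return An object of class `frap_comparison`: a parameter table plus
#'   `recovery_difference` in percentage points.
#' @export
compare_recovery <- function(fit_a, fit_b, labels = c("a", "b")) {
  stopifnot(inherits(fit_a, "frap_fit"), inherits(fit_b, "frap_fit"))
  grab <- function(f) c(recovery_percent = f$recovery_percent,
                        plateau = f$plateau, r = f$r,
                        c_eq1 = f$c_eq1, c_eq2 = f$c_eq2,
                        koff1 = f$koff1, koff2 = f$koff2)
  tab <- data.frame(grab(fit_a), grab(fit_b))
  names(tab) <- labels
  structure(list(table = tab,
                 recovery_difference = fit_a$recovery_percent -
                   fit_b$recovery_percent,
                 labels = labels),
            class = "frap_comparison")
}

#' @export
print.frap_comparison <- function(x, ...) {
  cat("FRAP recovery comparison\n")
  print(round(x$table, 4))
  cat(sprintf("  recovery difference (%s - %s): %.1f percentage points\n",
              x$labels[1], x$labels[2], x$recovery_difference))
  invisible(x)
}
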