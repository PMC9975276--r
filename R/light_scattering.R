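#' 90-degree light-scattering trace
#'
#' LS reports combined polymerization and bundling of protofilaments in
#' arbitrary instrument units; no conversion to polymer mass is attempted.
#'
#' @param time Time, s; strictly increasing.
#' @param intensity Scattering intensity, a.u.
#' @param reaction Optional [reaction_spec()] describing the reaction.
#' @param nucleotide `"GTP"` or `"GDP"`.
#' @param meta Optional named list of metadata (generator ground truth,
#'   baseline, labels).
#' @return An object of class `ls_trace`.
#' @export
ls_trace <- function(time, intensity, reaction = NULL,
                     nucleotide = c("GTP", "GDP"), meta = list()) {
  check_strictly_increasing(time)
  if (length(intensity) != length(time))
    stop_ftsz("ftszdyn_invalid_argument",
              "time and intensity lengths differ")
  nucleotide <- match.arg(nucleotide)
  if (!is.null(reaction)) stopifnot(inherits(reaction, "reaction_spec"))
  structure(list(time = as.numeric(time), intensity = as.numeric(intensity),
                 reaction = reaction, nucleotide = nucleotide, meta = meta),
            class = "ls_trace")
}

#' @export
print.ls_trace <- function(x, ...) {
  cat(sprintf("LS trace: %d samples over %g s (%s)%s\n",
              length(x$time), diff(range(x$time)), x$nucleotide,
              if (isTRUE(x$meta$normalized)) ", baseline-normalized" else ""))
  invisible(x)
}

# moving average with shrinking window at the edges, so no samples are lost
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

n_metric_min <- 20L  # minimum samples for LS metric extraction

check_ls_metric_ready <- function(trace) {
  if (length(trace$time) < n_metric_min)
    stop_ftsz("ftszdyn_insufficient_data",
              sprintf("LS metrics need at least %d samples", n_metric_min))
  invisible(trace)
}

#' Baseline-normalize a light-scattering trace
#'
#' Subtracts the mean intensity over a window preceding nucleotide addition
#' and stores the baseline (and its sd) in the trace metadata.
#'
#' @param trace An [ls_trace()].
#' @param baseline_window Time window `c(from, to)` in s; must precede
#'   nucleotide addition and contain at least 3 points.
#' @return The normalized `ls_trace`; `$meta$baseline` holds the subtracted
#'   level.
#' @export
normalize_trace <- function(trace, baseline_window) {
  stopifnot(inherits(trace, "ls_trace"))
  if (length(baseline_window) != 2L || baseline_window[1] >= baseline_window[2])
    stop_ftsz("ftszdyn_invalid_argument",
              "`baseline_window` must be an increasing pair of times")
  keep <- trace$time >= baseline_window[1] & trace$time <= baseline_window[2]
  if (sum(keep) < 3L)
    stop_ftsz("ftszdyn_invalid_argument",
              "baseline window must contain at least 3 points")
  baseline <- mean(trace$intensity[keep])
  trace$intensity <- trace$intensity - baseline
  trace$meta$baseline <- baseline
  trace$meta$baseline_sd <- stats::sd(trace$intensity[keep])
  trace$meta$normalized <- TRUE
  trace
}

#' Initial assembly rate of an LS trace
#'
#' Slope of a least-squares line over the earliest points, from signal start
#' (nucleotide addition) until the trace first reaches `fit_fraction` of its
#' maximum. Parameter-light "initial rate" semantics: as `fit_fraction`
#' shrinks the estimate approaches the true initial slope.
#'
#' @param trace A baseline-normalized [ls_trace()].
#' @param fit_fraction Fraction of the maximum delimiting the fit window
#'   (default 0.5).
#' @param noise_floor Amplitude below which the trace is considered to show
#'   no assembly; default 5 x the baseline sd when known, else 0.
#' @return Rate in a.u. s^-1, with attributes `window` (fit endpoints, s) and
#'   `no_assembly` (logical). Traces without detectable assembly return 0
#'   flagged `no_assembly = TRUE`.
#' @export
initial_rate <- function(trace, fit_fraction = 0.5, noise_floor = NULL) {
  stopifnot(inherits(trace, "ls_trace"))
  check_ls_metric_ready(trace)
  if (fit_fraction <= 0 || fit_fraction > 1)
    stop_ftsz("ftszdyn_invalid_argument", "`fit_fraction` must be in (0, 1]")
  t_add <- trace$meta$t_add %||% trace$time[1]
  if (is.null(noise_floor))
    noise_floor <- if (!is.null(trace$meta$baseline_sd))
      5 * trace$meta$baseline_sd else 0
  sel <- trace$time >= t_add
  tt <- trace$time[sel]; yy <- trace$intensity[sel]
  peak <- max(yy)
  if (peak <= noise_floor || peak <= 0) {
    out <- 0
    attr(out, "window") <- c(NA_real_, NA_real_)
    attr(out, "no_assembly") <- TRUE
    return(out)
  }
  cross <- which(yy >= fit_fraction * peak)[1]
  end <- max(cross, 2L)
  fit <- stats::lm(yy[1:end] ~ tt[1:end])
  out <- stats::coef(fit)[[2]]
  attr(out, "window") <- c(tt[1], tt[end])
  attr(out, "no_assembly") <- FALSE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the onset of protofilament disassembly
#'
#' Disassembly is called only if the smoothed (centered moving average)
#' trace falls below `(1 - drop_fraction)` of its maximum and stays below it
#' for at least `smooth_window` consecutive samples; monotone nondecreasing
#' traces never yield an onset. The onset time itself is then located by a
#' least-squares plateau-then-decline breakpoint fit on the raw trace
#' between the smoothed maximum and the sustained drop. For a noiseless
#' kinked trace the breakpoint coincides with the trace maximum; unlike the
#' raw argmax it remains well-determined when assembly saturates long before
#' disassembly begins, where the peak region is flat and an argmax under
#' noise can wander far along the plateau.
#'
#' @param trace A baseline-normalized [ls_trace()].
#' @param smooth_window Moving-average window, samples (default 5).
#' @param drop_fraction Sustained fractional drop below the maximum required
#'   to call disassembly (default 0.1).
#' @return Onset time in s, or `NA` if no disassembly is detected.
#' @export
detect_onset <- function(trace, smooth_window = 5L, drop_fraction = 0.1) {
  stopifnot(inherits(trace, "ls_trace"))
  check_ls_metric_ready(trace)
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop_ftsz("ftszdyn_invalid_argument", "`drop_fraction` must be in (0, 1)")
  t_add <- trace$meta$t_add %||% trace$time[1]
  sel <- trace$time >= t_add
  tt <- trace$time[sel]
  sm <- moving_average(trace$intensity[sel], as.integer(smooth_window))
  noise_floor <- if (!is.null(trace$meta$baseline_sd))
    5 * trace$meta$baseline_sd else 0
  peak_i <- which.max(sm)
  peak <- sm[peak_i]
  if (peak <= noise_floor || peak <= 0) return(NA_real_)
  after <- sm[-seq_len(peak_i)]
  if (length(after) < smooth_window) return(NA_real_)
  below <- after < (1 - drop_fraction) * peak
  run <- rle(below)
  sustained <- any(run$values & run$lengths >= smooth_window)
  if (!sustained) return(NA_real_)

  # first index (absolute, within tt) of the sustained sub-threshold run
  ends <- cumsum(run$lengths)
  k <- which(run$values & run$lengths >= smooth_window)[1]
  cross_i <- peak_i + (if (k == 1L) 1L else ends[k - 1L] + 1L)

  # two-segment breakpoint fit on the raw trace: flat plateau up to the
  # onset, linear decline after it; grid over candidate breakpoints
  yy <- trace$intensity[sel]
  fit_breakpoint <- function(lo, hi, cand) {
    win <- lo:hi
    rss <- vapply(cand, function(j) {
      x <- pmax(tt[win] - tt[j], 0)
      sum(stats::lm.fit(cbind(1, x), yy[win])$residuals^2)
    }, 0)
    cand[which.min(rss)]
  }
  cand <- peak_i:cross_i
  if (length(cand) > 250L)
    cand <- unique(round(seq(peak_i, cross_i, length.out = 250L)))
  j1 <- fit_breakpoint(peak_i, min(length(tt), cross_i + 200L), cand)
  # refine in a window with a short plateau side (the plateau is only
  # approximately flat while assembly still saturates) and a long decay side
  # (more leverage on the decline slope)
  lo2 <- max(1L, j1 - 25L)
  hi2 <- min(length(tt), j1 + 200L)
  j2 <- fit_breakpoint(lo2, hi2,
                       max(lo2 + 2L, j1 - 25L):min(hi2 - 2L, j1 + 25L))
  tt[j2]
}

#' Summarise a light-scattering trace
#'
#' Runs [normalize_trace()] (when a baseline window is given),
#' [initial_rate()] and [detect_onset()] and collects the results.
#'
#' @param trace An [ls_trace()].
#' @param baseline_window Optional baseline window passed to
#'   [normalize_trace()]; omit if the trace is already normalized.
#' @param fit_fraction,smooth_window,drop_fraction Tuning parameters of the
#'   underlying operations.
#' @return An object of class `ls_metrics` with elements `baseline`,
#'   `amplitude`, `initial_rate`, `rate_window`, `onset_time`, `no_assembly`,
#'   `label`.
#' @export
ls_metrics <- function(trace, baseline_window = NULL, fit_fraction = 0.5,
                       smooth_window = 5L, drop_fraction = 0.1) {
  stopifnot(inherits(trace, "ls_trace"))
  if (!is.null(baseline_window))
    trace <- normalize_trace(trace, baseline_window)
  check_ls_metric_ready(trace)
  rate <- initial_rate(trace, fit_fraction)
  t_add <- trace$meta$t_add %||% trace$time[1]
  sm <- moving_average(trace$intensity[trace$time >= t_add],
                       as.integer(smooth_window))
  structure(
    list(baseline = trace$meta$baseline %||% 0,
         amplitude = max(max(sm), 0),
         initial_rate = as.numeric(rate),
         rate_window = attr(rate, "window"),
         onset_time = detect_onset(trace, smooth_window, drop_fraction),
         no_assembly = isTRUE(attr(rate, "no_assembly")),
         label = trace$meta$label %||%
           (if (!is.null(trace$reaction)) trace$reaction$label else "")),
    class = "ls_metrics"
  )
}

#' @export
print.ls_metrics <- function(x, ...) {
  cat("LS metrics\n")
  cat(sprintf("  baseline %0.4g a.u., amplitude %0.4g a.u.\n",
              x$baseline, x$amplitude))
  cat(sprintf("  initial rate %0.4g a.u./s (window %g-%g s)\n",
              x$initial_rate, x$rate_window[1], x$rate_window[2]))
  cat(sprintf("  disassembly onset: %s\n",
              if (is.na(x$onset_time)) "none" else
                sprintf("%g s", x$onset_time)))
  invisible(x)
}

#' Classify disassembly onset against predicted GTP depletion
#'
#' @param metrics An [ls_metrics()] result.
#' @param prediction A [depletion_time()] result for the same reaction, or
#'   `NULL` when no prediction exists (e.g. protein at or below Cc).
#' @return One of `"before"`, `"after"`, `"no_disassembly"`,
#'   `"no_prediction"`. `"before"` means disassembly began before the
#'   predicted moment of GTP exhaustion.
#' @examples
#' k <- list(activity = 0.59, cc = 2.12)
#' pred <- depletion_time(reaction_spec(c(SeFtsZ = 14), 50, k))
#' m <- structure(list(onset_time = 350, label = ""), class = "ls_metrics")
#' classify_onset(m, pred)  # "before"
#' @export
classify_onset <- function(metrics, prediction = NULL) {
  stopifnot(inherits(metrics, "ls_metrics"))
  if (!is.null(prediction)) {
    stopifnot(inherits(prediction, "depletion_prediction"))
    la <- metrics$label %||% ""
    lb <- prediction$label %||% ""
    if (nzchar(la) && nzchar(lb) && la != lb)
      stop_ftsz("ftszdyn_invalid_argument",
                sprintf("reaction labels differ: '%s' vs '%s'", la, lb))
  }
  if (is.na(metrics$onset_time %||% NA_real_)) return("no_disassembly")
  if (is.null(prediction) || !isTRUE(prediction$defined))
    return("no_prediction")
  if (metrics$onset_time < prediction$depletion_time_raw) "before" else "after"
}
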