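#' Ground-truth parameter set for the synthetic-data generators
#'
#' Collects every parameter the generators need so that downstream estimators
#' can be tested against known truth. Defaults reproduce the study conditions
#' of the cyanobacterial FtsZ characterisation the package models: GTPase
#' activity 0.59 GTP min^-1 FtsZ^-1 with critical concentration 2.12 uM,
#' protein titrations from 2 to 14 uM, and assembly reactions started with
#' 50 uM GTP.
#'
#' @param activity GTPase activity, GTP min^-1 FtsZ^-1 (slope of the velocity
#'   vs concentration line above the critical concentration). Must be > 0.
#' @param cc Critical concentration, uM. Must be >= 0.
#' @param protein_concs Protein concentrations (uM) at which GTPase traces are
#'   generated.
#' @param gtp_conc Starting GTP concentration, uM.
#' @param ls_amplitude_scale Light-scattering amplitude per uM of polymerized
#'   protein, a.u. uM^-1. Arbitrary instrument units.
#' @param ls_rise_rate First-order rate constant of the saturating-exponential
#'   LS rise, s^-1.
#' @param disassembly_onset Time (s) at which LS decay begins, or `NULL` for
#'   traces that never disassemble.
#' @param frap Named list with elements `r`, `c_eq1`, `c_eq2`, `koff1`,
#'   `koff2`: parameters of the two-binding-state recovery model. Constraints:
#'   `0 <= r <= 1`, `c_eq1, c_eq2 >= 0`, `c_eq1 + c_eq2 <= 1`,
#'   `koff1, koff2 > 0`.
#' @param noise Named list of per-channel Gaussian noise standard deviations:
#'   `a340` (absorbance units), `ls` (a.u.), `frap` (normalized recovery
#'   units), `sed` (pellet-fraction units). All must be >= 0.
#' @param seed Integer seed; all generator randomness flows through it.
#'
#' @return An object of class `ground_truth`.
#' @examples
#' gt <- ground_truth()
#' gt$activity
#' @export
ground_truth <- function(activity = 0.59,
                         cc = 2.12,
                         protein_concs = seq(2, 14, by = 2),
                         gtp_conc = 50,
                         ls_amplitude_scale = 25,
                         ls_rise_rate = 0.02,
                         disassembly_onset = NULL,
                         frap = list(r = 0.05, c_eq1 = 0.5, c_eq2 = 0.4,
                                     koff1 = 0.05, koff2 = 0.005),
                         noise = list(a340 = 0.002, ls = 2, frap = 0.01,
                                      sed = 0.02),
                         seed = 1L) {
  check_number(activity, "activity", positive = TRUE)
  check_number(cc, "cc", nonneg = TRUE)
  check_number(gtp_conc, "gtp_conc", nonneg = TRUE)
  check_number(ls_amplitude_scale, "ls_amplitude_scale", nonneg = TRUE)
  check_number(ls_rise_rate, "ls_rise_rate", positive = TRUE)
  if (!is.null(disassembly_onset))
    check_number(disassembly_onset, "disassembly_onset", positive = TRUE)
  if (!is.numeric(protein_concs) || length(protein_concs) < 1L ||
      any(protein_concs < 0))
    stop_ftsz("ftszdyn_invalid_argument",
              "`protein_concs` must be non-negative concentrations")
  need <- c("r", "c_eq1", "c_eq2", "koff1", "koff2")
  if (!all(need %in% names(frap)))
    stop_ftsz("ftszdyn_invalid_argument",
              paste("`frap` must contain", paste(need, collapse = ", ")))
  with(frap, {
    if (r < 0 || r > 1 || c_eq1 < 0 || c_eq2 < 0 || c_eq1 + c_eq2 > 1 ||
        koff1 <= 0 || koff2 <= 0)
      stop_ftsz("ftszdyn_invalid_argument",
                "frap parameters violate model constraints")
  })
  for (ch in c("a340", "ls", "frap", "sed"))
    check_number(noise[[ch]], paste0("noise$", ch), nonneg = TRUE)
  structure(
    list(activity = activity, cc = cc, protein_concs = protein_concs,
         gtp_conc = gtp_conc, ls_amplitude_scale = ls_amplitude_scale,
         ls_rise_rate = ls_rise_rate, disassembly_onset = disassembly_onset,
         frap = frap[need], noise = noise, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for synthetic FtsZ data\n")
  cat(sprintf("  GTPase activity: %g GTP min^-1 FtsZ^-1, Cc: %g uM\n",
              x$activity, x$cc))
  cat(sprintf("  protein concs (uM): %s;  GTP: %g uM\n",
              paste(x$protein_concs, collapse = ", "), x$gtp_conc))
  cat(sprintf("  LS: amplitude %g a.u./uM, rise rate %g /s, onset %s\n",
              x$ls_amplitude_scale, x$ls_rise_rate,
              if (is.null(x$disassembly_onset)) "none"
              else paste0(x$disassembly_onset, " s")))
  cat(sprintf("  FRAP: r=%g c_eq1=%g c_eq2=%g koff1=%g koff2=%g\n",
              x$frap$r, x$frap$c_eq1, x$frap$c_eq2, x$frap$koff1,
              x$frap$koff2))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Simulate NADH-coupled GTPase assay absorbance traces
#'
#' Emulates the regenerative coupled assay in which each GTP hydrolysed
#' regenerates at the cost of one NADH oxidised, so A340 declines linearly
#' with slope proportional to the hydrolysis velocity
#' `v = activity * max(C - Cc, 0)` uM/min.
#'
#' @param gt A [ground_truth()] object.
#' @param duration Trace length, s. Must be > 0.
#' @param dt Sampling interval, s. Must be > 0.
#' @param epsilon NADH extinction coefficient at 340 nm, M^-1 cm^-1.
#' @param path Optical path length, cm (0.56 cm for 200 ul in a 96-well
#'   plate).
#' @param a340_start Starting absorbance.
#' @return A named list of [absorbance_trace()] objects, one per entry of
#'   `gt$protein_concs`.
#' @examples
#' traces <- make_gtpase_traces(ground_truth(noise = list(
#'   a340 = 0, ls = 0, frap = 0, sed = 0)))
#' velocity_from_trace(traces[["14"]])
#' @export
make_gtpase_traces <- function(gt, duration = 600, dt = 5,
                               epsilon = 6220, path = 0.56,
                               a340_start = 0.9) {
  stopifnot(inherits(gt, "ground_truth"))
  check_number(duration, "duration", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  check_number(epsilon, "epsilon", positive = TRUE)
  check_number(path, "path", positive = TRUE)
  time <- seq(0, duration, by = dt)
  with_seed(gt$seed, {
    out <- lapply(gt$protein_concs, function(conc) {
      v <- gt$activity * max(conc - gt$cc, 0)        # uM GTP / min
      slope <- -v * 1e-6 * epsilon * path / 60       # A340 / s
      a340 <- a340_start + slope * time +
        stats::rnorm(length(time), 0, gt$noise$a340)
      absorbance_trace(time, pmax(a340, 0), protein_conc = conc,
                       gtp_conc = gt$gtp_conc,
                       label = sprintf("%g uM", conc))
    })
    names(out) <- as.character(gt$protein_concs)
    out
  })
}

#' Simulate a 90-degree light-scattering trace
#'
#' Assembly is modelled as a saturating-exponential rise
#' `I(t) = A (1 - exp(-k t))` with amplitude
#' `A = ls_amplitude_scale * max(protein_conc - cc, 0)`: LS amplitude is
#' linear in the protein concentration above the critical concentration and
#' zero below it. If `gt$disassembly_onset` is set and falls inside the
#' trace, a decay (linear by default) starts at that time; the true onset is
#' stored in the trace metadata for recovery tests.
#'
#' @param gt A [ground_truth()] object.
#' @param protein_conc Total protein concentration, uM.
#' @param duration Trace length, s; must exceed `dt`.
#' @param dt Sampling interval, s.
#' @param baseline Baseline intensity before nucleotide addition, a.u.
#' @param baseline_s Length of the pre-addition baseline segment, s
#'   (nucleotide is added at `t = baseline_s`).
#' @param decay Shape of the post-onset decay, `"linear"` or
#'   `"exponential"`.
#' @param decay_rate Linear decay rate (a.u. s^-1) or exponential decay rate
#'   constant (s^-1); default `A/1000` for linear (full disassembly in about
#'   1000 s) and `0.005 s^-1` for exponential.
#' @return An [ls_trace()] object with ground truth in `$meta`.
#' @examples
#' gt <- ground_truth(disassembly_onset = 400,
#'                    noise = list(a340 = 0, ls = 0, frap = 0, sed = 0))
#' tr <- make_ls_trace(gt, protein_conc = 8)
#' tr$meta$onset_truth
#' @export
make_ls_trace <- function(gt, protein_conc, duration = 2000, dt = 2,
                          baseline = 0, baseline_s = 0,
                          decay = c("linear", "exponential"),
                          decay_rate = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  check_number(protein_conc, "protein_conc", nonneg = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (duration <= dt)
    stop_ftsz("ftszdyn_invalid_argument", "`duration` must exceed `dt`")
  decay <- match.arg(decay)

  time <- seq(0, duration, by = dt)
  amp <- gt$ls_amplitude_scale * max(protein_conc - gt$cc, 0)
  s <- pmax(time - baseline_s, 0)
  clean <- baseline + amp * (1 - exp(-gt$ls_rise_rate * s))

  onset <- gt$disassembly_onset
  if (!is.null(onset) && onset < duration && amp > 0) {
    peak <- baseline + amp * (1 - exp(-gt$ls_rise_rate *
                                        max(onset - baseline_s, 0)))
    post <- time > onset
    if (decay == "linear") {
      if (is.null(decay_rate)) decay_rate <- amp / 1000
      clean[post] <- pmax(peak - decay_rate * (time[post] - onset), baseline)
    } else {
      if (is.null(decay_rate)) decay_rate <- 0.005
      clean[post] <- baseline +
        (peak - baseline) * exp(-decay_rate * (time[post] - onset))
    }
  } else {
    onset <- NULL
  }

  intensity <- with_seed(gt$seed, {
    clean + stats::rnorm(length(time), 0, gt$noise$ls)
  })
  ls_trace(time, intensity, nucleotide = "GTP",
           meta = list(onset_truth = onset, t_add = baseline_s,
                       baseline_truth = baseline, amplitude_truth = amp,
                       protein_conc = protein_conc))
}

#' Simulate a FRAP region-intensity trace
#'
#' Postbleach bleach-ROI intensities follow the two-binding-state recovery
#' model (see [model_frap()]) rescaled to raw instrument units between
#' `bg_level` and `prebleach_level`; the reference and background ROIs are
#' constant. Gaussian noise with normalized-unit sd `gt$noise$frap` is added
#' to the bleach channel and, at one tenth of that sd, to the bright flat
#' reference and background channels.
#'
#' @param gt A [ground_truth()] object (FRAP parameters in `gt$frap`).
#' @param n_pre Number of prebleach frames (>= 1).
#' @param n_post Number of postbleach frames (>= 2).
#' @param dt Frame interval, s.
#' @param prebleach_level Prebleach bleach-ROI and reference intensity, a.u.
#' @param bg_level Background intensity, a.u.
#' @return A [frap_trace()] object.
#' @examples
#' gt <- ground_truth(noise = list(a340 = 0, ls = 0, frap = 0, sed = 0))
#' tr <- make_frap_trace(gt)
#' fit_frap(normalize_frap(tr), n_starts = 5, seed = 1)
#' @export
make_frap_trace <- function(gt, n_pre = 3, n_post = 30, dt = 10,
                            prebleach_level = 1000, bg_level = 100) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n_pre < 1 || n_post < 2)
    stop_ftsz("ftszdyn_invalid_argument",
              "need n_pre >= 1 and n_post >= 2")
  check_number(dt, "dt", positive = TRUE)
  if (bg_level >= prebleach_level)
    stop_ftsz("ftszdyn_invalid_argument",
              "`prebleach_level` must exceed `bg_level`")
  t_pre <- seq(-n_pre * dt, -dt, by = dt)
  t_post <- seq(0, (n_post - 1) * dt, by = dt)
  time <- c(t_pre, t_post)
  span <- prebleach_level - bg_level
  m <- model_frap(t_post, gt$frap)
  bleach <- c(rep(prebleach_level, n_pre), bg_level + span * m)
  n <- length(time)
  with_seed(gt$seed, {
    sd_raw <- gt$noise$frap * span
    bleach <- bleach + stats::rnorm(n, 0, sd_raw)
    reference <- prebleach_level + stats::rnorm(n, 0, sd_raw * 0.1)
    background <- bg_level + stats::rnorm(n, 0, sd_raw * 0.1)
    frap_trace(time, pmax(bleach, 0), pmax(reference, 0),
               pmax(background, 0), n_prebleach = n_pre)
  })
}

#' Simulate sedimentation densitometry samples
#'
#' Draws replicate pellet fractions for a GTP and a GDP condition from
#' Gaussian distributions truncated to \[0, 1\], then expresses them as
#' pellet/supernatant density pairs on a fixed total.
#'
#' @param fraction_gtp,fraction_gdp True mean pellet fractions, in \[0, 1\].
#' @param n Replicates per condition (>= 2).
#' @param noise_sd Replicate standard deviation on the fraction scale.
#' @param seed Integer seed.
#' @param total Total lane density, a.u.
#' @return A data frame with columns `label`, `nucleotide`, `density_total`,
#'   `density_supernatant`, `density_pellet`.
#' @examples
#' make_sedimentation_samples(0.4, 0.1, n = 3, noise_sd = 0, seed = 1)
#' @export
make_sedimentation_samples <- function(fraction_gtp, fraction_gdp, n = 3,
                                       noise_sd = 0.02, seed = 1L,
                                       total = 100) {
  for (f in c(fraction_gtp, fraction_gdp))
    if (!is.numeric(f) || f < 0 || f > 1)
      stop_ftsz("ftszdyn_invalid_argument",
                "pellet fractions must lie in [0, 1]")
  if (n < 2)
    stop_ftsz("ftszdyn_invalid_argument", "need n >= 2 replicates")
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(total, "total", positive = TRUE)
  with_seed(seed, {
    draw <- function(mu, cond) {
      f <- pmin(1, pmax(0, stats::rnorm(n, mu, noise_sd)))
      data.frame(label = sprintf("%s_rep%d", cond, seq_len(n)),
                 nucleotide = cond,
                 density_total = total,
                 density_supernatant = (1 - f) * total,
                 density_pellet = f * total,
                 stringsAsFactors = FALSE)
    }
    rbind(draw(fraction_gtp, "GTP"), draw(fraction_gdp, "GDP"))
  })
}
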