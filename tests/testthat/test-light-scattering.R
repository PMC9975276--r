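test_that("normalize_trace subtracts and records the baseline", {
  t <- seq(0, 200, 5)
  const <- ls_trace(t, rep(7, length(t)), meta = list(t_add = 50))
  norm <- normalize_trace(const, c(0, 45))
  expect_equal(norm$intensity, rep(0, length(t)))
  expect_equal(norm$meta$baseline, 7)
  # shift invariance
  shifted <- ls_trace(t, rep(7, length(t)) + 3, meta = list(t_add = 50))
  expect_equal(normalize_trace(shifted, c(0, 45))$intensity, norm$intensity)
  expect_error(normalize_trace(const, c(0, 4)),
               class = "ftszdyn_invalid_argument")
})

test_that("synthetic baseline is recovered by the baseline window mean", {
  gt <- ground_truth(noise = list(a340 = 0, ls = 1, frap = 0, sed = 0),
                     seed = 42)
  tr <- make_ls_trace(gt, 8, baseline = 100, baseline_s = 60, dt = 2)
  norm <- normalize_trace(tr, c(0, 58))
  n_in_window <- sum(tr$time <= 58)
  expect_equal(norm$meta$baseline, 100, tolerance = 5 / sqrt(n_in_window))
})

test_that("initial_rate recovers slopes and the A*k limit", {
  # perfect line: slope recovered over the whole fitted window
  t <- seq(0, 100, 1)
  line <- ls_trace(t, 0.8 * t)
  expect_equal(as.numeric(initial_rate(line)), 0.8, tolerance = 1e-9)
  # saturating exponential: rate tends to A*k as the window shrinks
  gt <- quiet_gt(ls_amplitude_scale = 25, ls_rise_rate = 0.01)
  tr <- make_ls_trace(gt, 8, duration = 1000, dt = 0.5)
  a_k <- 25 * (8 - gt$cc) * 0.01
  expect_equal(as.numeric(initial_rate(tr, fit_fraction = 0.01)), a_k,
               tolerance = 0.02)
  # half-max default window is recorded
  r <- initial_rate(tr)
  expect_length(attr(r, "window"), 2L)
  expect_true(attr(r, "window")[2] > attr(r, "window")[1])
})

test_that("initial rate grows with assembly amplitude", {
  gt <- ground_truth(noise = list(a340 = 0, ls = 0.5, frap = 0, sed = 0),
                     seed = 9)
  rates <- vapply(c(4, 6, 8, 10, 14), function(conc)
    as.numeric(initial_rate(make_ls_trace(gt, conc, dt = 2))), 0)
  expect_true(all(diff(rates) > 0))
})

test_that("traces without assembly yield zero rate with a flag", {
  gt <- ground_truth(noise = list(a340 = 0, ls = 1, frap = 0, sed = 0),
                     seed = 4)
  tr <- make_ls_trace(gt, 2, baseline_s = 60, dt = 2)  # below Cc
  norm <- normalize_trace(tr, c(0, 58))
  r <- initial_rate(norm)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "no_assembly"))
  m <- ls_metrics(norm)
  expect_true(m$no_assembly)
})

test_that("rate and amplitude are invariant to baseline shifts", {
  gt <- ground_truth(noise = list(a340 = 0, ls = 1, frap = 0, sed = 0),
                     seed = 5, disassembly_onset = 600)
  tr <- make_ls_trace(gt, 8, baseline = 0, baseline_s = 60, dt = 2)
  up <- ls_trace(tr$time, tr$intensity + 250, meta = tr$meta)
  m0 <- ls_metrics(tr, baseline_window = c(0, 58))
  m1 <- ls_metrics(up, baseline_window = c(0, 58))
  expect_equal(m1$amplitude, m0$amplitude, tolerance = 1e-12)
  expect_equal(m1$initial_rate, m0$initial_rate, tolerance = 1e-12)
  expect_equal(m1$onset_time, m0$onset_time)
})

test_that("detect_onset never fires on monotone nondecreasing traces", {
  set.seed(77)
  for (i in 1:20) {
    t <- seq(0, 500, 5)
    y <- cumsum(abs(rnorm(length(t))))
    expect_true(is.na(detect_onset(ls_trace(t, y))))
  }
  # flat noise around zero: nothing to detect either
  t <- seq(0, 500, 5)
  tr <- ls_trace(t, rnorm(length(t)), meta = list(baseline_sd = 1))
  expect_true(is.na(detect_onset(tr)))
})

test_that("detect_onset finds constructed onsets and ignores brief dips", {
  tr <- make_ls_trace(quiet_gt(disassembly_onset = 400), 8, dt = 2)
  expect_equal(detect_onset(tr), 400, tolerance = 2)
  # a 5% dip followed by recovery stays below the 10% drop criterion
  t <- seq(0, 400, 2)
  y <- c(seq(0, 100, length.out = 100), seq(100, 95, length.out = 20),
         rep(100, 81))
  expect_true(is.na(detect_onset(ls_trace(t, y))))
})

test_that("classification against predicted depletion covers all branches", {
  k <- table1_kinetics
  pred14 <- depletion_time(reaction_spec(c(Z = 14), 50, k))  # 428 s
  m_after <- structure(list(onset_time = 700, label = ""),
                       class = "ls_metrics")
  m_before <- structure(list(onset_time = 350, label = ""),
                        class = "ls_metrics")
  m_none <- structure(list(onset_time = NA_real_, label = ""),
                      class = "ls_metrics")
  expect_equal(classify_onset(m_after, pred14), "after")
  expect_equal(classify_onset(m_before, pred14), "before")
  expect_equal(classify_onset(m_none, pred14), "no_disassembly")
  expect_equal(classify_onset(m_before, NULL), "no_prediction")
  # label mismatch is an error
  m_lab <- structure(list(onset_time = 350, label = "rxn A"),
                     class = "ls_metrics")
  pred_lab <- depletion_time(reaction_spec(c(Z = 14), 50, k,
                                           label = "rxn B"))
  expect_error(classify_onset(m_lab, pred_lab),
               class = "ftszdyn_invalid_argument")
})

test_that("construction-oracle classification: onset at 0.8x depletion", {
  k <- table1_kinetics
  spec <- reaction_spec(c(Z = 8), 50, k)
  pred <- depletion_time(spec)
  gt <- ground_truth(disassembly_onset = 0.8 * pred$depletion_time_raw,
                     noise = list(a340 = 0, ls = 1, frap = 0, sed = 0),
                     seed = 8)
  m <- ls_metrics(make_ls_trace(gt, 8, dt = 2))
  expect_equal(classify_onset(m, pred), "before")
})
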