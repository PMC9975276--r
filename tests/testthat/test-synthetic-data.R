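test_that("identical seeds give bit-identical synthetic data", {
  gt1 <- ground_truth(seed = 11, disassembly_onset = 500)
  gt2 <- ground_truth(seed = 11, disassembly_onset = 500)
  expect_identical(make_gtpase_traces(gt1), make_gtpase_traces(gt2))
  expect_identical(make_ls_trace(gt1, 8), make_ls_trace(gt2, 8))
  expect_identical(make_frap_trace(gt1), make_frap_trace(gt2))
  expect_identical(make_sedimentation_samples(0.4, 0.1, seed = 5),
                   make_sedimentation_samples(0.4, 0.1, seed = 5))
  gt3 <- ground_truth(seed = 12, disassembly_onset = 500)
  expect_false(identical(make_ls_trace(gt1, 8), make_ls_trace(gt3, 8)))
})

test_that("gtpase traces encode velocity in their slope", {
  gt <- quiet_gt(activity = 0.59, cc = 2.12, protein_concs = c(2.12, 14))
  traces <- make_gtpase_traces(gt, epsilon = 6220, path = 0.56,
                               a340_start = 0.9)
  # at C = Cc the trace is flat at the starting absorbance
  expect_equal(traces[["2.12"]]$a340, rep(0.9, length(traces[["2.12"]]$time)))
  # at 14 uM the slope encodes v = 0.59 * (14 - 2.12) um/min, checked with a
  # two-point oracle independent of the analysis path
  tr <- traces[["14"]]
  v_oracle <- -slope_two_point(tr$time, tr$a340) * 60 / (6220 * 0.56) * 1e6
  expect_equal(v_oracle, 0.59 * (14 - 2.12), tolerance = 1e-12)
})

test_that("gtpase trace generation validates arguments", {
  gt <- quiet_gt()
  expect_error(make_gtpase_traces(gt, duration = -5),
               class = "ftszdyn_invalid_argument")
  expect_error(make_gtpase_traces(gt, dt = 0),
               class = "ftszdyn_invalid_argument")
})

test_that("LS generator: no assembly below Cc, linear amplitude above", {
  gt <- quiet_gt()
  below <- make_ls_trace(gt, protein_conc = 2)
  expect_equal(below$intensity, rep(0, length(below$time)))
  above <- vapply(c(4, 8, 14), function(conc)
    max(make_ls_trace(gt, conc)$intensity), 0)
  truth <- gt$ls_amplitude_scale * (c(4, 8, 14) - gt$cc) *
    (1 - exp(-gt$ls_rise_rate * 2000))
  expect_equal(above, truth, tolerance = 1e-12)
})

test_that("LS generator: no onset gives monotone trace, onset gives argmax", {
  gt <- quiet_gt()
  tr <- make_ls_trace(gt, 8)
  expect_true(all(diff(tr$intensity) >= 0))
  expect_null(tr$meta$onset_truth)
  gt_on <- quiet_gt(disassembly_onset = 400)
  tr_on <- make_ls_trace(gt_on, 8, dt = 2)
  expect_equal(tr_on$time[which.max(tr_on$intensity)], 400)
  expect_equal(tr_on$meta$onset_truth, 400)
  # onset beyond the trace is ignored
  tr_far <- make_ls_trace(quiet_gt(disassembly_onset = 5000), 8)
  expect_null(tr_far$meta$onset_truth)
  expect_true(all(diff(tr_far$intensity) >= 0))
})

test_that("FRAP generator round-trips through normalization", {
  gt <- quiet_gt()
  tr <- make_frap_trace(gt, n_pre = 3, n_post = 31, dt = 10)
  rec <- normalize_frap(tr)
  post <- rec$time >= 0
  expect_equal(rec$value[post], model_frap(rec$time[post], gt$frap),
               tolerance = 1e-12)
  expect_equal(mean(rec$value[!post]), 1, tolerance = 1e-12)
})

test_that("FRAP generator boundary cases behave as the model dictates", {
  # r = 0, c_eq1 + c_eq2 = 1: zero recovery at t = 0
  gt0 <- quiet_gt(frap = list(r = 0, c_eq1 = 0.6, c_eq2 = 0.4,
                              koff1 = 0.05, koff2 = 0.005))
  rec0 <- normalize_frap(make_frap_trace(gt0))
  expect_equal(rec0$value[rec0$time == 0], 0, tolerance = 1e-12)
  # r = 1: bleached spot never recovers
  gt1 <- quiet_gt(frap = list(r = 1, c_eq1 = 0.5, c_eq2 = 0.3,
                              koff1 = 0.05, koff2 = 0.005))
  rec1 <- normalize_frap(make_frap_trace(gt1))
  expect_equal(rec1$value[rec1$time >= 0],
               rep(0, sum(rec1$time >= 0)), tolerance = 1e-12)
})

test_that("sedimentation generator honours its means and truncation", {
  s <- make_sedimentation_samples(0.5, 0, n = 3, noise_sd = 0, seed = 2)
  f <- pellet_fraction(s$density_pellet, s$density_supernatant)
  expect_equal(f[s$nucleotide == "GTP"], rep(0.5, 3))
  expect_equal(s$density_pellet[s$nucleotide == "GDP"], rep(0, 3))
  noisy <- make_sedimentation_samples(0.99, 0.01, n = 50, noise_sd = 0.2,
                                      seed = 3)
  fn <- pellet_fraction(noisy$density_pellet, noisy$density_supernatant)
  expect_true(all(fn >= 0 & fn <= 1))
})

test_that("ground truth constructor enforces its invariants", {
  expect_error(ground_truth(activity = -1),
               class = "ftszdyn_invalid_argument")
  expect_error(ground_truth(cc = -0.1), class = "ftszdyn_invalid_argument")
  expect_error(ground_truth(frap = list(r = 1.2, c_eq1 = 0.5, c_eq2 = 0.4,
                                        koff1 = 0.05, koff2 = 0.005)),
               class = "ftszdyn_invalid_argument")
  expect_error(ground_truth(frap = list(r = 0, c_eq1 = 0.7, c_eq2 = 0.4,
                                        koff1 = 0.05, koff2 = 0.005)),
               class = "ftszdyn_invalid_argument")
  expect_error(ground_truth(noise = list(a340 = -1, ls = 0, frap = 0,
                                         sed = 0)),
               class = "ftszdyn_invalid_argument")
  expect_error(make_sedimentation_samples(1.2, 0.1),
               class = "ftszdyn_invalid_argument")
})
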