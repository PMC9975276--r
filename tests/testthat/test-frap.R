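frap_pars <- list(r = 0.05, c_eq1 = 0.5, c_eq2 = 0.4,
                  koff1 = 0.05, koff2 = 0.005)

test_that("model_frap satisfies its algebraic identities", {
  p <- frap_pars
  expect_equal(model_frap(0, p), (1 - p$r) * (1 - p$c_eq1 - p$c_eq2))
  expect_equal(model_frap(Inf, p), 1 - p$r)
  # classic single-state recovery as a reduction
  single <- list(r = 0, c_eq1 = 1, c_eq2 = 0, koff1 = 0.02, koff2 = 1)
  t <- seq(0, 300, 10)
  expect_equal(model_frap(t, single), 1 - exp(-0.02 * t))
})

test_that("model_frap is monotone nondecreasing for valid parameters", {
  set.seed(31)
  t <- seq(0, 500, 2)
  for (i in 1:25) {
    s <- runif(1); w <- runif(1)
    p <- list(r = runif(1), c_eq1 = s * w, c_eq2 = s * (1 - w),
              koff1 = 10^runif(1, -4, 0), koff2 = 10^runif(1, -4, 0))
    expect_true(all(diff(model_frap(t, p)) >= -1e-12))
  }
})

test_that("double normalization cancels background and reference", {
  t <- seq(-30, 290, 10)
  n <- length(t)
  # bleach identical to reference with zero background: everything is 1
  tr <- frap_trace(t, rep(500, n), rep(500, n), rep(0, n), n_prebleach = 3)
  expect_equal(normalize_frap(tr)$value, rep(1, n))
  # adding a constant to all three channels changes nothing
  gt <- quiet_gt()
  raw <- make_frap_trace(gt)
  shifted <- frap_trace(raw$time, raw$bleach + 55, raw$reference + 55,
                        raw$background + 55, raw$n_prebleach)
  expect_equal(normalize_frap(shifted)$value, normalize_frap(raw)$value,
               tolerance = 1e-12)
  # reference at or below background is degenerate
  bad <- frap_trace(t, rep(100, n), rep(10, n), rep(10, n), n_prebleach = 3)
  expect_error(normalize_frap(bad),
               class = "ftszdyn_degenerate_normalization")
})

test_that("fit_frap recovers noiseless parameters to 1e-4 relative", {
  gt <- quiet_gt(frap = frap_pars)
  rec <- normalize_frap(make_frap_trace(gt, n_pre = 3, n_post = 31))
  fit <- fit_frap(rec, n_starts = 20, seed = 2)
  for (nm in names(frap_pars))
    expect_equal(fit[[nm]], frap_pars[[nm]], tolerance = 1e-4)
  expect_equal(fit$plateau, 1 - frap_pars$r, tolerance = 1e-4)
  expect_equal(fit$recovery_percent, 100 * (1 - frap_pars$r),
               tolerance = 1e-2)
  expect_lt(fit$max_abs_residual, 1e-6)
  expect_true(fit$koff1 >= fit$koff2)
})

test_that("fit is equivariant under time rescaling", {
  gt <- quiet_gt(frap = frap_pars)
  rec <- normalize_frap(make_frap_trace(gt, n_post = 31, dt = 10))
  fast <- list(time = rec$time / 10, value = rec$value,
               n_prebleach = rec$n_prebleach)
  f1 <- fit_frap(rec, n_starts = 15, seed = 3)
  f2 <- fit_frap(fast, n_starts = 15, seed = 3)
  expect_equal(f2$koff1, 10 * f1$koff1, tolerance = 1e-3)
  expect_equal(f2$koff2, 10 * f1$koff2, tolerance = 1e-3)
  expect_equal(f2$r, f1$r, tolerance = 1e-4)
})

test_that("flat-zero recovery drives r to 1 and flags degeneracy", {
  t <- seq(-30, 290, 10)
  val <- c(rep(1, 3), rep(0, 30))
  fit <- fit_frap(list(time = t, value = val, n_prebleach = 3),
                  n_starts = 10, seed = 4)
  expect_gt(fit$r, 0.99)
  expect_true(fit$degenerate)
})

test_that("single-exponential data trigger the identifiability guard", {
  # truth has one binding state; the two-state fit must either collapse the
  # second fraction or report the reduced single-state fit alongside
  single <- list(r = 0.1, c_eq1 = 0.8, c_eq2 = 0, koff1 = 0.02, koff2 = 0.02)
  gt <- quiet_gt(frap = single)
  fit <- fit_frap(normalize_frap(make_frap_trace(gt, n_post = 31)),
                  n_starts = 20, seed = 5)
  expect_true(!is.null(fit$single_state) ||
                min(fit$c_eq1, fit$c_eq2) < 1e-3)
  expect_equal(fit$recovery_percent, 90, tolerance = 0.5)
})

test_that("fit_frap validates its inputs", {
  gt <- quiet_gt()
  rec <- normalize_frap(make_frap_trace(gt, n_post = 5))
  expect_error(fit_frap(rec), class = "ftszdyn_insufficient_data")
  rec31 <- normalize_frap(make_frap_trace(gt, n_post = 31))
  expect_error(fit_frap(rec31, n_starts = 0),
               class = "ftszdyn_invalid_argument")
})

test_that("compare_recovery reports plateau differences both ways", {
  gt_low <- quiet_gt(frap = list(r = 0.83, c_eq1 = 0.6, c_eq2 = 0.3,
                                 koff1 = 0.05, koff2 = 0.005))
  gt_high <- quiet_gt(frap = list(r = 0.05, c_eq1 = 0.6, c_eq2 = 0.3,
                                  koff1 = 0.05, koff2 = 0.005))
  f_low <- fit_frap(normalize_frap(make_frap_trace(gt_low, n_post = 31)),
                    n_starts = 15, seed = 6)
  f_high <- fit_frap(normalize_frap(make_frap_trace(gt_high, n_post = 31)),
                     n_starts = 15, seed = 6)
  expect_equal(f_low$recovery_percent, 17, tolerance = 0.5)
  expect_equal(f_high$recovery_percent, 95, tolerance = 0.5)
  cmp <- compare_recovery(f_high, f_low, labels = c("plus", "minus"))
  expect_equal(cmp$recovery_difference, 78, tolerance = 1)
  swapped <- compare_recovery(f_low, f_high)
  expect_equal(swapped$recovery_difference, -cmp$recovery_difference)
  same <- compare_recovery(f_high, f_high)
  expect_equal(same$recovery_difference, 0)
})
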