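# shared fixtures: noiseless and noisy ground-truth objects

quiet_noise <- list(a340 = 0, ls = 0, frap = 0, sed = 0)

quiet_gt <- function(...) ground_truth(noise = quiet_noise, ...)

table1_kinetics <- list(activity = 0.59, cc = 2.12)

# independent two-point slope oracle for noiseless linear traces
slope_two_point <- function(time, y) {
  n <- length(time)
  (y[n] - y[1]) / (time[n] - time[1])
}
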