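# shared fixtures, all generated in code

quiet_autolabel <- function(trial, ...) {
  suppressMessages(autolabel_trial(trial, ...))
}

# a profile with all randomness switched off
noiseless <- function(p) {
  p$cap_noise_sd <- 0
  p$imu_noise_sd <- 0
  p$hf_amp <- 0
  p
}

# population standard deviation by an explicit scalar loop (independent of
# the vectorized implementation under test)
loop_features <- function(w) {
  n <- length(w)
  s <- 0
  for (v in w) s <- s + v
  m <- s / n
  q <- 0
  mx <- w[1]
  for (v in w) {
    q <- q + (v - m)^2
    if (v > mx) mx <- v
  }
  c(ave = m, std = sqrt(q / n), max = mx, tan = (w[n] - w[1]) / n)
}

# minimal valid trial built directly (not via the generator)
flat_trial <- function(n = 1500, motion = "R", cap_value = 30,
                       euler = c(5, -10, 20)) {
  trial_record("TST", motion, 1L,
               cap = matrix(cap_value, n, 6),
               imu = matrix(rep(euler, each = n), n, 3))
}
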