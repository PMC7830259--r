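# shared fixtures: noiseless and noisy percent-remaining series

noiseless_series <- function(params, end = 130, c0 = 100,
                             temperature_C = NA_real_) {
  tg <- sampling_schedule(end)
  conc_series(tg, remaining_pct(c0, params, tg), temperature_C = temperature_C)
}

noisy_series <- function(params, seed, noise_cv = 0.02, end = 130) {
  tg <- sampling_schedule(end)
  mu <- remaining_pct(100, params, tg)
  set.seed(seed)
  v <- mu * (1 + rnorm(length(mu), 0, noise_cv))
  v[1] <- 100
  conc_series(tg, pmax(v, 0))
}

# rate constants extracted from the three accelerated runs
k_accel <- c(0.0146, 0.0709, 0.4485)
T_accel <- c(40, 50, 60)
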