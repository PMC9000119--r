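# Small independent oracles used across the test files.

# plain-R forward-Euler step for a single AP-family cell, written directly
# from the model equations (independent of the package's kernel)
fe_step_ap_oracle <- function(u, v, p, dt, i_ext = 0) {
  eps <- p$eps0 + p$mu1 * v / (u + p$mu2)
  du <- p$ct * (p$k * u * (u + p$b) * (1 - u) - v * u) + i_ext
  dv <- p$ct * eps * (-v - p$k * u * (u - p$a - 1))
  c(u + dt * du, v + dt * dv)
}

# FFT-based frequency estimate (Hz) with quadratic peak interpolation
fft_peak_frequency <- function(time, u) {
  dt <- diff(time[1:2])
  x <- u - mean(u)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  sp[1] <- 0
  k <- which.max(sp)
  # quadratic interpolation around the peak bin
  if (k > 1 && k < length(sp)) {
    a <- sp[k - 1]; b <- sp[k]; c <- sp[k + 1]
    delta <- 0.5 * (a - c) / (a - 2 * b + c)
  } else delta <- 0
  1000 * (k - 1 + delta) / (n * dt)
}

# quickly simulate a preset cell and cache nothing (tests are short)
sim_preset <- function(preset, b, duration, dt = 0.01, scheme = "fe",
                       sample_dt = 0.1, ...) {
  simulate_cell(cell_preset(preset, b = b), duration = duration, dt = dt,
                scheme = scheme, sample_dt = sample_dt, ...)
}
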