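# shared fixtures built in code

# constant-amplitude on-resonance shape (phase fixed), for rotation checks
const_shape <- function(amp_hz, duration, n = 64, phase = 0) {
  dt <- duration / n
  rf_shape(time = (seq_len(n) - 0.5) * dt,
           amplitude = rep(2 * pi * amp_hz, n),
           phase = rep(phase, n), dt = dt, label = "const")
}

# effectively single-pool water system (solute fraction 1.5e-8)
water_system <- function(...) two_pool_system("Fn1", "healthy", ...)

# small phantom spec for fast tests
small_phantom <- function(noise_sigma = 0, seed = 1L, mi_ratio = 1.182,
                          grid = c(48, 48), noise_model = "gaussian") {
  phantom_spec(grid = grid,
               region_params = default_region_params(mi_ratio = mi_ratio),
               noise_sigma = noise_sigma, noise_model = noise_model,
               seed = seed)
}

# forward model of the steady-state decay equation (shared plateau ss*si0):
# +Z decays to the plateau, -Z recovers through zero toward the same plateau
ss_forward <- function(tt, R, ss, si0 = 1) si0 * (ss + (1 - ss) * exp(-R * tt))
ss_forward_minus <- function(tt, R, ss, si0 = 1) si0 * (ss - (1 + ss) * exp(-R * tt))
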