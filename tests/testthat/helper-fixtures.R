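# Small in-code fixtures shared across test files.

tiny_sediment <- function(core_id = "T1",
                          depth = c(1, 3, 5),
                          tn = c(1.0, 0.8, 0.6)) {
  sediment_profile(core_id, data.frame(
    depth_cm = depth,
    toc = tn * 10,
    tn = tn,
    d13c = -22,
    d15n = 8,
    pw_mass_fraction = 1.0,
    Al = 60000,
    K = 20000
  ))
}

# Noise-free piecewise N profile sampled at 1-cm steps.
model_sediment <- function(y0 = 1.0, a = 0.9, x_b = 7, depth_max = 20) {
  depth <- seq(1, depth_max)
  tn <- y0 * a^pmin(depth, x_b)
  sediment_profile("model", data.frame(
    depth_cm = depth, toc = tn * 15, tn = tn, d13c = -22, d15n = 8.5))
}

# Noise-free thermal profile from the forward model.
model_thermal <- function(beta, L = 0.4, T_top = 3, T_bottom = 63,
                          n = 5) {
  depth <- seq(0, L, length.out = n)
  thermal_profile("model", data.frame(
    depth_m = depth,
    temp_c = forward_temperature(depth, beta, L, T_top, T_bottom)))
}
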