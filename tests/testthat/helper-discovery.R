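# Small, fast search problem shared by the discovery tests: an 8-spike
# particle whose spike amplitude must grow from 0.15 toward a target.

small_cfg <- function(seed = 11, max_steps = 15, step = 0.04) {
  start <- ensemble_params(
    shape_params(35, 8, 0.15, 0.2, angular_jitter = 0.03, roughness = 0.01),
    cv = c(base_radius_nm = 0.05, spike_amplitude = 0.08),
    n_particles = 40, seed = 3
  )
  trajectory_config(start, step_scales = c(spike_amplitude = step),
                    max_steps = max_steps, seed = seed)
}

# Single-bump landscape centred on the ensemble with the given amplitude,
# placed in the trajectory's own chart.
amp_landscape <- function(cfg, amp = 0.5) {
  ts <- trajectory_space(cfg)
  tgt <- trajectory_centroid_at(
    cfg, ts$space,
    c(base_radius_nm = 35, spike_amplitude = amp, spike_sharpness = 0.2),
    seed = 999)
  width <- sqrt(sum((tgt - ts$centroid)^2)) / 2
  readout_landscape(tgt, amplitudes = 1, widths = width)
}
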