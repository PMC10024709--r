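# Shared fixtures: short pacing protocols and lazily cached simulations so
# that expensive runs are shared across test files within one session.

pr_fast <- function(n_beats = 8, discard = 3)
  stim_protocol(n_beats = n_beats, discard_beats = discard)

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

cell_atr <- function() cached("cell_atr", make_preset("atrial", seed = 42))
cell_ven <- function() cached("cell_ven", make_preset("ventricular", seed = 43))

dc_atr_on_atr <- function() cached("dc_aa",
  run_dc(cell_atr(), ik1_config("atr", scaling_DC = 1), pr_fast()))
dc_atr_on_ven <- function() cached("dc_av",
  run_dc(cell_ven(), ik1_config("atr", scaling_DC = 1), pr_fast()))

# synthetic rectangular / ramp APs with known geometry, on the 0.2 ms grid
square_ap_trace <- function(rest = -80, peak = 20, plateau_ms = 100,
                            t_up = 100, total_ms = 600, dt = 0.2) {
  t <- seq(0, total_ms, by = dt)
  V <- rep(rest, length(t))
  V[t > t_up & t <= t_up + plateau_ms] <- peak
  voltage_trace(t, V, dt, stim_times = t_up)
}

ramp_ap_trace <- function(rest = -80, peak = 20, ramp_ms = 100,
                          t_up = 100, total_ms = 600, dt = 0.2) {
  t <- seq(0, total_ms, by = dt)
  V <- rep(rest, length(t))
  i <- t > t_up & t <= t_up + ramp_ms
  V[i] <- peak - (peak - rest) * (t[i] - t_up) / ramp_ms
  voltage_trace(t, V, dt, stim_times = t_up)
}
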