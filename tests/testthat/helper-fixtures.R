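# Shared fixtures: all synthetic, generated in code at test time.

fix_s267e <- function() myo6_variant("S267E")
fix_wt <- function() myo6_variant("WT")

# state trajectory pinned to a single state over [0, duration]
single_state_traj <- function(state, duration) {
  out <- data.frame(state = state, t_start = 0, t_end = duration,
                    load_at_entry = 0)
  class(out) <- c("state_trajectory", class(out))
  out
}

# simulate a full trace for a variant: returns list(trace, traj)
sim_variant_trace <- function(variant = fix_s267e(), atp = 0.1, n_events = 60,
                              seed = 1, forcing_amp = 0) {
  cond <- conditions(atp)
  dur <- n_events * (1 / variant$rates$k_att +
                       mean_attached_time(variant$rates, cond)) * 1.1 + 5
  traj <- simulate_state_sequence(variant$rates, cond, dur, seed = seed)
  cfg <- sim_config(dur, forcing_amp = forcing_amp, seed = seed)
  list(trace = simulate_trap_trace(traj, variant$mech, cfg, cond),
       traj = traj, cond = cond, cfg = cfg)
}

# dwells of the sequential attached phase drawn directly (oracle generator)
hypoexp_sample <- function(n, a, b, seed) {
  set.seed(seed)
  stats::rexp(n, a) + stats::rexp(n, b)
}

# closed-form hypoexponential survival
hypoexp_surv <- function(t, a, b) {
  (b * exp(-a * t) - a * exp(-b * t)) / (b - a)
}
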