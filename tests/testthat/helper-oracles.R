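# independent oracles used across the suite

# rectangle-rule AUC written out longhand
oracle_auc <- function(v) {
  total <- 0
  for (x in v) total <- total + x * 15
  total
}

# brute-force gap profile for a walk: piecewise-linear triangle evaluated
# point by point, independent of the simulator's approx() path
oracle_gap <- function(times, start, duration, horizon, drop,
                       anchor = "end") {
  t_nadir <- start + (if (anchor == "end") duration else 0) + 30
  t_end <- start + horizon
  vapply(times, function(t) {
    if (t <= start || t >= t_end) return(0)
    if (t <= t_nadir) drop * (t - start) / (t_nadir - start)
    else drop * (t_end - t) / (t_end - t_nadir)
  }, numeric(1))
}

# a drawing that exactly traces a counterfactual from 9 AM on
tracing_drawing <- function(curve) {
  keep <- curve$times >= 540
  drawn_trajectory(curve$times[keep], curve$values[keep])
}
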