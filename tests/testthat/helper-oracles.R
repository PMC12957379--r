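# Shared oracles and fixture shortcuts, independent of the code paths they
# check.

# Volumetric flow carried between transverse positions a and b under the
# parabolic profile, by brute-force quadrature.
parabolic_flow_between <- function(a, b, w, v_mean = 1) {
  stats::integrate(function(y) 6 * v_mean * (y / w) * (1 - y / w),
    lower = a, upper = b, rel.tol = 1e-10
  )$value
}

dg300_flows <- function() flow_config(Q_X = 0.5, Q_S = 0.4, Q_O = 18.3)
dg250_flows <- function() flow_config(Q_X = 4.9, Q_S = 5.0, Q_O = 18.2)

nadh_props <- function() transport_properties(D_ref = 6.7e-6, eta = 5.39)

# Locked-fraction of one segment of an event series, re-windowed from the
# segment start.
segment_locked_fraction <- function(events, from_s, to_s) {
  tt <- events$time_s[events$time_s >= from_s & events$time_s < to_s]
  seg <- simulate_droplets(oscillator_config(period_jitter_sd_s = 0),
    NULL,
    duration_s = 1, seed = 1
  ) # template for class; replaced below
  seg <- structure(tibble::tibble(time_s = tt - from_s),
    duration = to_s - from_s, reference_period = 0.1, seed = NA,
    class = class(seg)
  )
  lock_in_report(seg)$locked_fraction
}
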