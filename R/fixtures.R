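#' Synthetic scenario bundles
#'
#' Generates, from a scenario name and a seed alone, every synthetic input
#' the other modules need: droplet event series, detector traces, hit
#' series, and a closed-form mixing field. Scenarios mirror the qualitative
#' regimes of a triggered droplet-generation run:
#'
#' * `locked_train`: 10 Hz oscillator under a 180 V trigger - locks
#'   immediately and stays locked.
#' * `free_running`: untriggered 10.2 Hz oscillator - the droplet phase
#'   walks linearly across the waterfall.
#' * `intermittent`: 110 V trigger below the 150 V lock threshold -
#'   captures only intermittently.
#' * `amplitude_ladder`: scripted trigger schedule 180 V, off, 40 V,
#'   110 V, 180 V in equal segments.
#' * `mixing_closed_form`: analytic plug-flow erfc concentration field for
#'   validating the advection-diffusion solver.
#'
#' All bundles are reproducible bit-for-bit from `(scenario, seed)`.
#'
#' @param scenario One of the scenario names above.
#' @param seed Integer seed.
#' @param params Optional named list overriding scenario defaults
#'   (`duration_s`, `jitter_sd_s`, `natural_frequency_hz`, `amplitude_V`,
#'   `delay_ms`, `base_hit_prob`, `segment_s`; for `mixing_closed_form`:
#'   `w`, `v_mean`, `D_um2_s`, `c0`, `interface_y`, `nx`, `ny`, `x_max`).
#' @return For the droplet scenarios, a list with `scenario`, `seed`,
#'   `events`, `trace`, `hits`, and for `amplitude_ladder` also `schedule`;
#'   for `mixing_closed_form`, a list with `scenario` and `field` (a
#'   `mixing_field`).
#' @examples
#' b <- make_scenario("locked_train", seed = 1, params = list(duration_s = 5))
#' @export
make_scenario <- function(scenario = c(
                            "locked_train", "free_running", "intermittent",
                            "amplitude_ladder", "mixing_closed_form"
                          ),
                          seed = 1, params = list()) {
  scenario <- match.arg(scenario)
  p <- function(name, default) params[[name]] %||% default

  if (scenario == "mixing_closed_form") {
    w <- p("w", 150)
    v <- p("v_mean", 666.7)
    D <- p("D_um2_s", 120)
    c0 <- p("c0", 300)
    yi <- p("interface_y", w / 2)
    nx <- p("nx", 256)
    ny <- p("ny", 257)
    x_max <- p("x_max", 528)
    x <- seq(0, x_max, length.out = nx)
    y <- seq(0, w, length.out = ny)
    conc <- outer(x, y, function(xx, yy) plug_flow_erfc(xx, yy, yi, D, v, c0))
    field <- structure(
      list(
        x = x, y = y, conc = conc, c0 = c0, interface_y = yi, w = w,
        v_mean = v, D_um2_s = D, Pe = v * w / D, profile = "plug"
      ),
      class = "mixing_field"
    )
    return(list(scenario = scenario, seed = seed, field = field))
  }

  duration <- p("duration_s", 60)
  jitter <- p("jitter_sd_s", 0.002)
  delay_ms <- p("delay_ms", 30)
  base_hit_prob <- p("base_hit_prob", 0.5)

  # Triggered scenarios start with the oscillator near the trigger phase,
  # mirroring the start-up procedure: the trigger is only activated once
  # droplet generation has stabilized close to the target rate and phase.
  osc <- oscillator_config(
    natural_frequency_hz = p(
      "natural_frequency_hz",
      if (scenario == "free_running") 10.2 else 10
    ),
    period_jitter_sd_s = jitter,
    phase0_s = if (scenario == "free_running") 0 else delay_ms / 1e3 - 0.1
  )
  schedule <- NULL
  trig <- switch(scenario,
    locked_train = trigger_config(amplitude_V = p("amplitude_V", 180),
      delay_ms = delay_ms
    ),
    free_running = NULL,
    intermittent = trigger_config(amplitude_V = p("amplitude_V", 110),
      delay_ms = delay_ms
    ),
    amplitude_ladder = trigger_config(amplitude_V = 180, delay_ms = delay_ms)
  )
  if (scenario == "amplitude_ladder") {
    seg <- p("segment_s", 60)
    duration <- p("duration_s", 5 * seg)
    schedule <- tibble::tibble(
      start_s = seg * (0:4),
      amplitude_V = c(180, 0, 40, 110, 180)
    )
  }
  events <- simulate_droplets(osc, trig,
    duration_s = duration, seed = seed,
    amplitude_schedule = schedule
  )
  trace <- synth_trace(events, seed = seed + 1L)
  hits <- make_hits(events, base_hit_prob,
    seed = seed + 2L,
    delay_s = delay_ms / 1e3
  )
  out <- list(
    scenario = scenario, seed = seed, events = events, trace = trace,
    hits = hits
  )
  if (!is.null(schedule)) out$schedule <- schedule
  out
}

#' Synthesize per-train crystal hit counts
#'
#' A crystal hit requires the droplet to overlap the pulse train: a window
#' can score a hit only when its first droplet's phase lies within
#' `phase_tol_s` of the trigger delay (the phase a locked droplet holds).
#' In-phase windows then score Bernoulli(`base_hit_prob`) hits.
#'
#' @param events A `droplet_events`.
#' @param base_hit_prob Probability of a hit in an in-phase window.
#' @param seed Integer seed.
#' @param window_length_s Reference window length (s).
#' @param delay_s Trigger delay, the locked droplet phase (s).
#' @param phase_tol_s In-phase tolerance (s).
#' @return Integer vector of hits per window.
#' @export
make_hits <- function(events, base_hit_prob, seed, window_length_s = 0.1,
                      delay_s = 0.03, phase_tol_s = 0.005) {
  stopifnot(inherits(events, "droplet_events"))
  if (base_hit_prob < 0 || base_hit_prob > 1) {
    abort("`base_hit_prob` must lie in [0, 1].")
  }
  set.seed(seed)
  n_win <- floor(attr(events, "duration") / window_length_s)
  win <- floor(events$time_s / window_length_s) + 1
  first_time <- rep(NA_real_, n_win)
  for (i in rev(seq_along(events$time_s))) {
    if (win[i] >= 1 && win[i] <= n_win) first_time[win[i]] <- events$time_s[i]
  }
  phase <- first_time %% window_length_s
  in_phase <- !is.na(phase) & abs(phase - delay_s) <= phase_tol_s
  hits <- integer(n_win)
  hits[in_phase] <- rbinom(sum(in_phase), 1, base_hit_prob)
  hits
}
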