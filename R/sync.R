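#' Free-running droplet-generator oscillator
#'
#' Behavioral model of the droplet generator as a noisy oscillator: droplet
#' pinch-off recurs with mean period `1/natural_frequency_hz`, Gaussian
#' period jitter, and an optional slow fractional frequency drift.
#'
#' @param natural_frequency_hz Natural droplet generation frequency (Hz).
#' @param period_jitter_sd_s Per-period Gaussian jitter SD (s).
#' @param phase0_s Time of the first scheduled pinch-off relative to t = 0 (s).
#' @param drift_rate Fractional period drift per second (dimensionless).
#' @return An `oscillator_config` object.
#' @export
oscillator_config <- function(natural_frequency_hz = 10,
                              period_jitter_sd_s = 0.002,
                              phase0_s = 0, drift_rate = 0) {
  check_positive(natural_frequency_hz, "natural_frequency_hz")
  check_positive(period_jitter_sd_s, "period_jitter_sd_s", strict = FALSE)
  structure(
    list(
      natural_frequency_hz = natural_frequency_hz,
      period_jitter_sd_s = period_jitter_sd_s,
      phase0_s = phase0_s, drift_rate = drift_rate
    ),
    class = "oscillator_config"
  )
}

#' Electrical trigger configuration
#'
#' The synchronization electrodes perturb droplet pinch-off once per
#' reference period. The physics is abstracted as a phase-resetting capture:
#' a trigger of sufficient amplitude captures an oscillator whose scheduled
#' firing lies within `capture_width_ms` of the trigger onset and resets the
#' firing instant to the trigger, zeroing accumulated phase error. Below
#' `lock_threshold_V` the capture succeeds only with probability
#' amplitude/threshold (intermittent lock); amplitude 0 leaves the
#' oscillator free-running.
#'
#' @param amplitude_V Trigger amplitude (V).
#' @param duration_ms Trigger pulse duration (ms).
#' @param delay_ms Trigger delay after the reference tick (ms).
#' @param lock_threshold_V Amplitude above which capture is deterministic (V).
#' @param capture_width_ms Half-width of the capture window around the
#'   trigger onset (ms).
#' @return A `trigger_config` object.
#' @export
trigger_config <- function(amplitude_V = 180, duration_ms = 4, delay_ms = 30,
                           lock_threshold_V = 150, capture_width_ms = 20) {
  check_positive(amplitude_V, "amplitude_V", strict = FALSE)
  check_positive(duration_ms, "duration_ms")
  check_positive(lock_threshold_V, "lock_threshold_V")
  check_positive(capture_width_ms, "capture_width_ms")
  structure(
    list(
      amplitude_V = amplitude_V, duration_ms = duration_ms,
      delay_ms = delay_ms, lock_threshold_V = lock_threshold_V,
      capture_width_ms = capture_width_ms
    ),
    class = "trigger_config"
  )
}

new_droplet_events <- function(times, duration, reference_period, seed = NA) {
  structure(
    tibble::tibble(time_s = times),
    duration = duration, reference_period = reference_period, seed = seed,
    class = c("droplet_events", class(tibble::tibble()))
  )
}

#' @export
print.droplet_events <- function(x, ...) {
  cat(sprintf(
    "<droplet_events> %d events over %g s (reference period %g s)\n",
    nrow(x), attr(x, "duration"), attr(x, "reference_period")
  ))
  NextMethod()
}

#' Simulate triggered droplet generation
#'
#' Integrate-and-fire simulation of the droplet generator under periodic
#' electrical triggering. Inter-droplet periods are drawn from the
#' [oscillator_config()]; trigger onsets occur at
#' `k * reference_period + delay`. When a scheduled firing falls within the
#' trigger's capture window and the amplitude condition holds (see
#' [trigger_config()]), the firing is reset to the trigger onset (lock-in).
#' Deterministic for a given `seed`.
#'
#' @param osc An [oscillator_config()].
#' @param trig A [trigger_config()], or `NULL` for a free-running oscillator.
#' @param duration_s Simulated duration (s).
#' @param seed Integer seed driving all stochastic draws.
#' @param reference_period_s XFEL reference period (s); 0.1 s for 10 Hz
#'   trains.
#' @param amplitude_schedule Optional data frame (`start_s`, `amplitude_V`)
#'   overriding the trigger amplitude as a step function of time, e.g. to
#'   script an amplitude ladder.
#' @return A `droplet_events` tibble (column `time_s`) with `duration`,
#'   `reference_period`, and `seed` attributes.
#' @examples
#' ev <- simulate_droplets(oscillator_config(), trigger_config(),
#'   duration_s = 10, seed = 1
#' )
#' @export
simulate_droplets <- function(osc, trig = NULL, duration_s, seed,
                              reference_period_s = 0.1,
                              amplitude_schedule = NULL) {
  stopifnot(inherits(osc, "oscillator_config"))
  if (!is.null(trig)) stopifnot(inherits(trig, "trigger_config"))
  check_positive(duration_s, "duration_s")
  set.seed(seed)

  amp_at <- function(t) {
    if (is.null(trig)) {
      return(0)
    }
    if (is.null(amplitude_schedule)) {
      return(trig$amplitude_V)
    }
    idx <- findInterval(t, amplitude_schedule$start_s)
    if (idx == 0) trig$amplitude_V else amplitude_schedule$amplitude_V[[idx]]
  }

  base_period <- 1 / osc$natural_frequency_hz
  draw_period <- function(t) {
    p <- base_period * (1 + osc$drift_rate * t) +
      rnorm(1, 0, osc$period_jitter_sd_s)
    max(p, 0.1 * base_period)
  }

  times <- numeric(0)
  t_last <- osc$phase0_s
  t_next <- t_last + draw_period(t_last)
  n_guard <- ceiling(duration_s / base_period * 20) + 100
  for (step in seq_len(n_guard)) {
    if (t_next > duration_s) break
    fire <- t_next
    if (!is.null(trig)) {
      delay <- trig$delay_ms / 1e3
      cw <- trig$capture_width_ms / 1e3
      k <- round((t_next - delay) / reference_period_s)
      t_k <- k * reference_period_s + delay
      if (k >= 0 && t_k <= duration_s && abs(t_next - t_k) <= cw &&
        t_k > t_last) {
        amp <- amp_at(t_k)
        captured <- if (amp >= trig$lock_threshold_V) {
          TRUE
        } else if (amp > 0) {
          runif(1) < amp / trig$lock_threshold_V
        } else {
          FALSE
        }
        if (captured) fire <- t_k
      }
    }
    times <- c(times, fire)
    t_last <- fire
    t_next <- fire + draw_period(fire)
  }
  new_droplet_events(times, duration_s, reference_period_s, seed)
}

new_detector_trace <- function(time, voltage, sample_rate, t0 = 0) {
  structure(
    tibble::tibble(time = time, voltage = voltage),
    sample_rate = sample_rate, t0 = t0,
    class = c("detector_trace", class(tibble::tibble()))
  )
}

#' @export
print.detector_trace <- function(x, ...) {
  cat(sprintf(
    "<detector_trace> %d samples at %g Hz\n", nrow(x), attr(x, "sample_rate")
  ))
  NextMethod()
}

#' Synthesize a droplet-detector voltage trace
#'
#' Renders droplet events as rectangular voltage pulses on Gaussian noise,
#' emulating the optical-fiber droplet detector signal.
#'
#' @param events A `droplet_events` object.
#' @param pulse_width_s Pulse width (s).
#' @param pulse_amplitude_V Pulse amplitude (V).
#' @param noise_sd_V Gaussian noise SD (V).
#' @param sample_rate_hz Sampling rate (Hz); must satisfy
#'   `sample_rate * pulse_width >= 4`.
#' @param seed Integer seed for the noise.
#' @return A `detector_trace` tibble (`time`, `voltage`) with `sample_rate`
#'   and `t0` attributes.
#' @export
synth_trace <- function(events, pulse_width_s = 0.002, pulse_amplitude_V = 1,
                        noise_sd_V = 0.02, sample_rate_hz = 1e4, seed = 1) {
  stopifnot(inherits(events, "droplet_events"))
  if (sample_rate_hz * pulse_width_s < 4) {
    abort("`sample_rate_hz * pulse_width_s` must be >= 4 to resolve pulses.")
  }
  set.seed(seed)
  duration <- attr(events, "duration")
  n <- floor(duration * sample_rate_hz)
  time <- (seq_len(n) - 1) / sample_rate_hz
  voltage <- if (noise_sd_V > 0) rnorm(n, 0, noise_sd_V) else numeric(n)
  for (te in events$time_s) {
    i0 <- floor(te * sample_rate_hz) + 1
    i1 <- min(floor((te + pulse_width_s) * sample_rate_hz), n)
    if (i0 <= n) voltage[i0:i1] <- voltage[i0:i1] + pulse_amplitude_V
  }
  new_detector_trace(time, voltage, sample_rate_hz)
}

#' Detect droplet events in a detector trace
#'
#' Rising-edge threshold crossings with a refractory hold-off: after each
#' detected edge, further crossings within `holdoff_s` are ignored (two
#' pulses closer than the hold-off merge into one event).
#'
#' @param trace A `detector_trace`.
#' @param threshold_V Detection threshold (V); must sit above the noise
#'   floor and below the pulse amplitude.
#' @param holdoff_s Refractory hold-off (s); defaults to the synthetic
#'   pulse width.
#' @param reference_period_s Reference period carried into the returned
#'   events (s).
#' @return A `droplet_events` tibble of crossing times.
#' @export
detect_events <- function(trace, threshold_V, holdoff_s = 0.002,
                          reference_period_s = 0.1) {
  stopifnot(inherits(trace, "detector_trace"))
  above <- trace$voltage >= threshold_V
  rising <- which(above & !dplyr::lag(above, default = FALSE))
  cand <- trace$time[rising]
  keep <- numeric(0)
  last <- -Inf
  for (tc in cand) {
    if (tc - last >= holdoff_s) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  duration <- nrow(trace) / attr(trace, "sample_rate")
  new_droplet_events(keep, duration, reference_period_s)
}

#' Fold a trace or event series into a waterfall matrix
#'
#' Cuts the input into consecutive reference-period windows and stacks them
#' as matrix rows; the column axis is time within the window. A locked
#' droplet train appears as a vertical stripe. For a `detector_trace`, rows
#' hold the sampled voltage; for `droplet_events`, rows hold binned event
#' counts (total event mass is preserved exactly).
#'
#' @param x A `detector_trace` or `droplet_events`.
#' @param window_length_s Window length (s); 0.1 s for the 10 Hz reference.
#' @param sample_rate_hz Column resolution used when folding events (Hz);
#'   ignored for traces, which keep their own sampling.
#' @return A `waterfall_matrix` object: `matrix` (rows = windows),
#'   `row_times` (window start times, s), `window_length`, `sample_rate`,
#'   and an optional `hits` overlay (see [annotate_hits()]).
#' @export
fold_waterfall <- function(x, window_length_s = 0.1, sample_rate_hz = 1000) {
  check_positive(window_length_s, "window_length_s")
  if (inherits(x, "detector_trace")) {
    sr <- attr(x, "sample_rate")
    ncol <- round(window_length_s * sr)
    if (abs(ncol - window_length_s * sr) > 1e-6) {
      abort("window_length_s * sample_rate must be an integer column count.")
    }
    n_win <- floor(nrow(x) / ncol)
    if (n_win < 1) abort("Trace shorter than one window.")
    m <- matrix(x$voltage[seq_len(n_win * ncol)],
      nrow = n_win, ncol = ncol, byrow = TRUE
    )
  } else if (inherits(x, "droplet_events")) {
    sr <- sample_rate_hz
    ncol <- round(window_length_s * sr)
    n_win <- floor(attr(x, "duration") / window_length_s)
    if (n_win < 1) abort("Event series shorter than one window.")
    m <- matrix(0, nrow = n_win, ncol = ncol)
    tt <- x$time_s[x$time_s < n_win * window_length_s]
    row <- floor(tt / window_length_s) + 1
    # small epsilon so exact-phase events are immune to %% rounding noise
    col <- pmin(floor((tt %% window_length_s) * sr + 1e-6) + 1, ncol)
    for (i in seq_along(tt)) m[row[i], col[i]] <- m[row[i], col[i]] + 1
  } else {
    abort("`x` must be a detector_trace or droplet_events.")
  }
  structure(
    list(
      matrix = m, row_times = (seq_len(n_win) - 1) * window_length_s,
      window_length = window_length_s, sample_rate = sr, hits = NULL
    ),
    class = "waterfall_matrix"
  )
}

#' @export
print.waterfall_matrix <- function(x, ...) {
  cat(sprintf(
    "<waterfall_matrix> %d windows x %d columns (%g s windows)%s\n",
    nrow(x$matrix), ncol(x$matrix), x$window_length,
    if (!is.null(x$hits)) sprintf(", %d hit rows", sum(x$hits > 0)) else ""
  ))
  invisible(x)
}

#' @rdname fold_waterfall
#' @param ... Unused.
#' @method tidy waterfall_matrix
#' @export
tidy.waterfall_matrix <- function(x, ...) {
  tidyr::expand_grid(
    row_time_s = x$row_times,
    phase_s = (seq_len(ncol(x$matrix)) - 1) / x$sample_rate
  ) |>
    dplyr::mutate(amplitude = as.vector(t(x$matrix)))
}

#' Circular standard deviation of droplet phases
#'
#' Maps phases onto the unit circle (period -> 2 pi), computes the mean
#' resultant length R, and returns sqrt(-2 log R) scaled back to time units.
#' Missing phases are excluded.
#'
#' @param phases Phases (s) in `[0, period)`.
#' @param period Reference period (s).
#' @return Circular SD (s); `NA` with fewer than 2 non-missing phases.
#' @export
circular_sd <- function(phases, period) {
  ph <- phases[!is.na(phases)]
  if (length(ph) < 2) {
    return(NA_real_)
  }
  th <- 2 * pi * ph / period
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(max(R, 1e-300))) * period / (2 * pi)
}

#' Lock-in diagnostics of a droplet event series
#'
#' Assigns each reference window its droplet phase (first event time modulo
#' the window length) and computes circular statistics of the phase: the
#' overall circular SD, a rolling circular SD over `min_run` windows that
#' flags each window as locked when below `locked_sd_threshold_s`, the
#' locked fraction, and the longest consecutive locked run. Windows without
#' an event carry a missing phase and are excluded from the SDs.
#'
#' @param events A `droplet_events`.
#' @param window_length_s Reference window length (s).
#' @param locked_sd_threshold_s Rolling circular SD below which a window
#'   counts as locked (s).
#' @param min_run Number of windows in the rolling SD.
#' @return A `lock_in_report`: `per_window` tibble (`window`, `t_start_s`,
#'   `phase_s`, `n_events`, `rolling_sd_s`, `locked`), `circular_sd_s`,
#'   `locked_fraction`, `longest_locked_run`. [glance()] returns the
#'   scalars.
#' @export
lock_in_report <- function(events, window_length_s = 0.1,
                           locked_sd_threshold_s = 0.001, min_run = 5) {
  stopifnot(inherits(events, "droplet_events"))
  n_win <- floor(attr(events, "duration") / window_length_s)
  if (n_win < 2) abort("Need at least 2 reference windows.")
  win <- floor(events$time_s / window_length_s) + 1
  ok <- win >= 1 & win <= n_win
  first_time <- rep(NA_real_, n_win)
  counts <- tabulate(win[ok], nbins = n_win)
  for (i in rev(seq_along(events$time_s))) {
    if (ok[i]) first_time[win[i]] <- events$time_s[i]
  }
  phase <- first_time %% window_length_s
  roll <- rep(NA_real_, n_win)
  locked <- rep(NA, n_win)
  for (i in seq(min_run, n_win)) {
    ph <- phase[(i - min_run + 1):i]
    s <- circular_sd(ph, window_length_s)
    roll[i] <- s
    locked[i] <- if (is.na(s) || any(is.na(ph))) NA else s < locked_sd_threshold_s
  }
  runs <- rle(ifelse(is.na(locked), FALSE, locked))
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  structure(
    list(
      per_window = tibble::tibble(
        window = seq_len(n_win),
        t_start_s = (seq_len(n_win) - 1) * window_length_s,
        phase_s = phase, n_events = counts,
        rolling_sd_s = roll, locked = locked
      ),
      circular_sd_s = circular_sd(phase, window_length_s),
      locked_fraction = mean(locked[!is.na(locked)]),
      longest_locked_run = as.integer(longest),
      window_length_s = window_length_s,
      locked_sd_threshold_s = locked_sd_threshold_s, min_run = min_run
    ),
    class = "lock_in_report"
  )
}

#' @export
print.lock_in_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<lock_in_report> %d windows: circular SD %.3g ms, locked fraction ",
      "%.2f, longest locked run %d\n"
    ),
    nrow(x$per_window), 1e3 * x$circular_sd_s, x$locked_fraction,
    x$longest_locked_run
  ))
  invisible(x)
}

#' @rdname lock_in_report
#' @param x A `lock_in_report`.
#' @param ... Unused.
#' @method tidy lock_in_report
#' @export
tidy.lock_in_report <- function(x, ...) x$per_window

#' @rdname lock_in_report
#' @method glance lock_in_report
#' @export
glance.lock_in_report <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$per_window),
    circular_sd_s = x$circular_sd_s,
    locked_fraction = x$locked_fraction,
    longest_locked_run = x$longest_locked_run,
    missing_windows = sum(is.na(x$per_window$phase_s))
  )
}

#' Overlay per-train crystal hits on a waterfall matrix
#'
#' @param waterfall A `waterfall_matrix`.
#' @param hits Integer vector of hits per train, one per waterfall row.
#' @return The `waterfall_matrix` with a `hits` overlay; [autoplot()] marks
#'   rows with nonzero hits.
#' @export
annotate_hits <- function(waterfall, hits) {
  stopifnot(inherits(waterfall, "waterfall_matrix"))
  if (length(hits) != nrow(waterfall$matrix)) {
    abort(sprintf(
      "`hits` length (%d) must equal the number of waterfall rows (%d).",
      length(hits), nrow(waterfall$matrix)
    ))
  }
  if (any(hits < 0)) abort("`hits` must be non-negative counts.")
  waterfall$hits <- as.integer(hits)
  waterfall
}

#' @rdname fold_waterfall
#' @param object A `waterfall_matrix`.
#' @method autoplot waterfall_matrix
#' @export
autoplot.waterfall_matrix <- function(object, ...) {
  p <- tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      1e3 * .data$phase_s, .data$row_time_s,
      fill = .data$amplitude
    )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "black", name = "signal") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "time within reference window (ms)",
      y = "acquisition time (s)", title = "Droplet waterfall"
    ) +
    ggplot2::coord_cartesian(expand = FALSE)
  if (!is.null(object$hits) && any(object$hits > 0)) {
    hit_df <- tibble::tibble(
      row_time_s = object$row_times[object$hits > 0], phase_ms = 0
    )
    p <- p + ggplot2::geom_point(
      data = hit_df,
      ggplot2::aes(x = .data$phase_ms, y = .data$row_time_s),
      inherit.aes = FALSE, shape = 17, colour = "green3", size = 2
    )
  }
  p
}

#' Per-pulse crystal hit rate
#'
#' @param n_patterns Number of diffraction patterns (hits).
#' @param n_trains Number of pulse trains delivered.
#' @param pulses_per_train Pulses per train.
#' @return Hit rate as a fraction of pulses.
#' @examples
#' hit_rate(1631, 2018, 202) # ~0.004
#' @export
hit_rate <- function(n_patterns, n_trains, pulses_per_train) {
  check_positive(n_patterns, "n_patterns", strict = FALSE)
  check_positive(n_trains, "n_trains")
  check_positive(pulses_per_train, "pulses_per_train")
  n_patterns / (n_trains * pulses_per_train)
}
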