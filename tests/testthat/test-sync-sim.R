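test_that("jitter-free untriggered oscillator is perfectly periodic", {
  ev <- simulate_droplets(
    oscillator_config(period_jitter_sd_s = 0), NULL,
    duration_s = 1.95, seed = 1
  )
  expect_equal(ev$time_s, seq(0.1, 1.9, by = 0.1))
})

test_that("identical seeds give identical event sequences", {
  a <- simulate_droplets(oscillator_config(), trigger_config(), 20, seed = 42)
  b <- simulate_droplets(oscillator_config(), trigger_config(), 20, seed = 42)
  expect_identical(a$time_s, b$time_s)
  c <- simulate_droplets(oscillator_config(), trigger_config(), 20, seed = 43)
  expect_false(identical(a$time_s, c$time_s))
})

test_that("an above-threshold trigger pins the phase to the trigger delay", {
  osc <- oscillator_config(phase0_s = 0.03 - 0.1) # post start-up alignment
  ev <- simulate_droplets(osc, trigger_config(amplitude_V = 180),
    duration_s = 60, seed = 5
  )
  rep <- lock_in_report(ev)
  expect_gt(rep$locked_fraction, 0.95)
  locked_phases <- rep$per_window$phase_s[which(rep$per_window$locked)]
  expect_lt(circular_sd(locked_phases, 0.1), 0.001)
  expect_equal(median(locked_phases), 0.03)
})

test_that("sub-threshold amplitude locks less than full amplitude", {
  osc <- oscillator_config(phase0_s = 0.03 - 0.1)
  hi <- simulate_droplets(osc, trigger_config(amplitude_V = 180), 60, seed = 8)
  lo <- simulate_droplets(osc, trigger_config(amplitude_V = 40), 60, seed = 8)
  f_hi <- lock_in_report(hi)$locked_fraction
  f_lo <- lock_in_report(lo)$locked_fraction
  expect_gt(f_hi, f_lo + 0.2)
})

test_that("locked fraction increases with trigger amplitude across seeds", {
  amps <- c(0, 40, 110, 180)
  osc <- oscillator_config(phase0_s = 0.03 - 0.1)
  mean_locked <- vapply(amps, function(a) {
    fr <- vapply(1:20, function(s) {
      trig <- trigger_config(amplitude_V = a)
      ev <- simulate_droplets(osc, trig, duration_s = 30, seed = s)
      lock_in_report(ev)$locked_fraction
    }, numeric(1))
    mean(fr)
  }, numeric(1))
  expect_gt(cor(amps, mean_locked, method = "spearman"), 0)
  expect_true(all(diff(mean_locked) >= 0))
})

test_that("median inter-event interval recovers the oscillator period", {
  osc <- oscillator_config(
    natural_frequency_hz = 10, period_jitter_sd_s = 0.002
  )
  ev <- simulate_droplets(osc, NULL, duration_s = 120, seed = 11)
  gaps <- diff(ev$time_s)
  expect_equal(median(gaps), 0.1, tolerance = 0.002 / sqrt(length(gaps)) * 5)
})

test_that("trace synthesis and event detection round-trip", {
  osc <- oscillator_config()
  ev <- simulate_droplets(osc, trigger_config(), 10, seed = 3)
  # noiseless: every event recovered within one sample period
  tr0 <- synth_trace(ev, noise_sd_V = 0, sample_rate_hz = 1e4, seed = 1)
  got0 <- detect_events(tr0, threshold_V = 0.5)
  expect_equal(nrow(got0), nrow(ev))
  expect_lt(max(abs(got0$time_s - ev$time_s)), 1 / 1e4 + 1e-12)
  # SNR 10: still exact recovery within one sample period
  tr <- synth_trace(ev, noise_sd_V = 0.1, sample_rate_hz = 1e4, seed = 2)
  got <- detect_events(tr, threshold_V = 0.5)
  expect_equal(nrow(got), nrow(ev))
  expect_lt(max(abs(got$time_s - ev$time_s)), 1 / 1e4 + 1e-12)
  # threshold above the pulse amplitude finds nothing
  expect_equal(nrow(detect_events(tr0, threshold_V = 2)), 0)
})

test_that("pulses closer than the hold-off merge into one event", {
  ev <- structure(tibble::tibble(time_s = c(0.50, 0.5008)),
    duration = 1, reference_period = 0.1, seed = NA,
    class = c("droplet_events", class(tibble::tibble()))
  )
  tr <- synth_trace(ev, noise_sd_V = 0, pulse_width_s = 0.002, seed = 1)
  got <- detect_events(tr, threshold_V = 0.5, holdoff_s = 0.002)
  expect_equal(nrow(got), 1)
})

test_that("waterfall folding preserves event mass and geometry", {
  ev <- simulate_droplets(
    oscillator_config(period_jitter_sd_s = 0, phase0_s = 0.03 - 0.1),
    trigger_config(), 10,
    seed = 1
  )
  wf <- fold_waterfall(ev, window_length_s = 0.1, sample_rate_hz = 1000)
  expect_equal(sum(wf$matrix), nrow(ev))
  # perfect lock: all events in a single column
  cols <- apply(wf$matrix, 1, which.max)
  expect_true(all(cols == cols[[1]]))
  expect_equal((cols[[1]] - 1) / 1000, 0.03)
})

test_that("free-running 10.2 Hz events walk linearly across the waterfall", {
  osc <- oscillator_config(natural_frequency_hz = 10.2, period_jitter_sd_s = 0)
  ev <- simulate_droplets(osc, NULL, duration_s = 10, seed = 1)
  rep <- lock_in_report(ev)
  ph <- rep$per_window$phase_s
  steps <- diff(ph)
  wraps <- steps > 0 # phase decreases except at wrap-around
  # predicted per-window walk: one reference period modulo the oscillator's
  walk <- 0.1 %% (1 / 10.2)
  expect_equal(unique(round(-steps[!wraps], 9)), round(walk, 9))
})

test_that("trace folding reshapes the signal without loss", {
  ev <- simulate_droplets(oscillator_config(), trigger_config(), 2, seed = 9)
  tr <- synth_trace(ev, noise_sd_V = 0, seed = 1)
  wf <- fold_waterfall(tr, window_length_s = 0.1)
  expect_equal(nrow(wf$matrix), 20)
  expect_equal(ncol(wf$matrix), 1000)
  expect_equal(as.vector(t(wf$matrix)), tr$voltage[1:20000])
  # a one-window trace folds to a single row
  short <- synth_trace(
    structure(tibble::tibble(time_s = 0.05),
      duration = 0.1, reference_period = 0.1, seed = NA,
      class = c("droplet_events", class(tibble::tibble()))
    ),
    noise_sd_V = 0, seed = 1
  )
  expect_equal(nrow(fold_waterfall(short, 0.1)$matrix), 1)
})

test_that("lock-in report flags constant and uniform phases correctly", {
  mk <- function(times, duration) {
    structure(tibble::tibble(time_s = times),
      duration = duration, reference_period = 0.1, seed = NA,
      class = c("droplet_events", class(tibble::tibble()))
    )
  }
  const <- mk(seq(0, 9.93, by = 0.1) + 0.03, 10)
  rep_c <- lock_in_report(const)
  expect_equal(rep_c$circular_sd_s, 0)
  expect_equal(rep_c$locked_fraction, 1)
  set.seed(1)
  unif <- mk(sort(seq(0, 9.9, by = 0.1) + runif(100, 0, 0.1)), 10)
  rep_u <- lock_in_report(unif)
  expect_gt(rep_u$circular_sd_s, 0.02)
  expect_lt(rep_u$locked_fraction, 0.1)
  # a window without events is excluded, not fatal
  gappy <- mk(c(seq(0.03, 0.93, by = 0.1), seq(1.13, 1.93, by = 0.1)), 2)
  rep_g <- lock_in_report(gappy)
  expect_equal(sum(is.na(rep_g$per_window$phase_s)), 1)
})

test_that("hit annotation flags the right waterfall rows", {
  ev <- simulate_droplets(oscillator_config(), trigger_config(), 2, seed = 2)
  wf <- fold_waterfall(ev)
  expect_error(annotate_hits(wf, c(1, 0)), "length")
  none <- annotate_hits(wf, rep(0L, nrow(wf$matrix)))
  expect_equal(sum(none$hits > 0), 0)
  one <- annotate_hits(wf, c(3L, rep(0L, nrow(wf$matrix) - 1)))
  expect_equal(which(one$hits > 0), 1L)
  expect_s3_class(autoplot(one), "ggplot")
})

test_that("hit rate is patterns per delivered pulse", {
  expect_equal(hit_rate(1631, 2018, 202), 1631 / (2018 * 202))
  expect_equal(hit_rate(0, 2018, 202), 0)
  expect_equal(hit_rate(2018 * 202, 2018, 202), 1)
  expect_error(hit_rate(10, 0, 202), "n_trains")
})
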