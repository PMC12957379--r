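#' XFEL pulse-train timing
#'
#' The European XFEL delivers bursts ("trains") of MHz-spaced pulses at a
#' 10 Hz train repetition rate; with segmented droplet injection one crystal
#' droplet is aimed at each train rather than at each pulse.
#'
#' @param n_pulses Pulses per train.
#' @param intra_spacing_us Intra-train pulse spacing (us).
#' @param train_rate_hz Train repetition rate (Hz).
#' @param photon_energy_keV Photon energy (keV, metadata only).
#' @return A `pulse_train` object.
#' @examples
#' pulse_train()  # 202 pulses, 1.77 us apart, 10 Hz
#' @export
pulse_train <- function(n_pulses = 202, intra_spacing_us = 1.77,
                        train_rate_hz = 10, photon_energy_keV = NA_real_) {
  if (n_pulses < 1) abort("`n_pulses` must be >= 1.")
  check_positive(intra_spacing_us, "intra_spacing_us")
  check_positive(train_rate_hz, "train_rate_hz")
  dur_s <- n_pulses * intra_spacing_us * 1e-6
  if (dur_s >= 1 / train_rate_hz) {
    abort("Train duration must be shorter than the train period 1/train_rate.")
  }
  structure(
    list(
      n_pulses = as.integer(n_pulses), intra_spacing_us = intra_spacing_us,
      train_rate_hz = train_rate_hz, photon_energy_keV = photon_energy_keV
    ),
    class = "pulse_train"
  )
}

#' Liquid-jet geometry
#'
#' @param velocity_m_s Jet velocity (m/s); gas-focused jets from the aqueous
#'   flow rates used here run near 25 m/s.
#' @param radius_um Jet radius (um); typical gas-focused jets are 3-10 um in
#'   diameter.
#' @return A `jet_spec` object.
#' @export
jet_spec <- function(velocity_m_s = 25, radius_um = 5) {
  check_positive(velocity_m_s, "velocity_m_s")
  check_positive(radius_um, "radius_um")
  structure(list(velocity_m_s = velocity_m_s, radius_um = radius_um),
    class = "jet_spec"
  )
}

#' Pulse-train duration
#'
#' `n_pulses * intra_spacing` (us). The convention multiplies by the full
#' pulse count rather than `n_pulses - 1`; for 202 pulses at 1.77 us this
#' gives 357.5 us.
#'
#' @param train A [pulse_train()].
#' @return Duration (us).
#' @examples
#' train_duration(pulse_train())
#' @export
train_duration <- function(train) {
  stopifnot(inherits(train, "pulse_train"))
  train$n_pulses * train$intra_spacing_us
}

#' Minimum droplet volume that spans a pulse train
#'
#' While jetting, a droplet is stretched into a rod of the jet's radius
#' moving at the jet velocity; to keep crystal-laden liquid in the beam for
#' the whole train the rod must be at least `jet_velocity * train_duration`
#' long. The minimum volume is `pi r^2 L` (no end-cap correction).
#'
#' @param jet A [jet_spec()].
#' @param train A [pulse_train()].
#' @return Minimum spanning volume (pL).
#' @examples
#' min_spanning_volume(jet_spec(), pulse_train())  # ~700 pL
#' @export
min_spanning_volume <- function(jet, train) {
  stopifnot(inherits(jet, "jet_spec"))
  L_um <- jet$velocity_m_s * 1e6 * train_duration(train) * 1e-6 # um
  vol_um3 <- pi * jet$radius_um^2 * L_um
  vol_um3 * 1e-3 # 1 pL = 1e3 um^3
}

#' Droplet volume from the aqueous flow balance
#'
#' At droplet generation frequency f the aqueous flow is parcelled into
#' droplets of volume `Q_aq / f`.
#'
#' @param Q_aq Aqueous flow rate (uL/min).
#' @param f Droplet generation frequency (Hz).
#' @return Droplet volume (nL).
#' @examples
#' droplet_volume_from_flow(1.5, 10)
#' @export
droplet_volume_from_flow <- function(Q_aq, f) {
  check_positive(Q_aq, "Q_aq", strict = FALSE)
  check_positive(f, "f")
  Q_aq / 60 / f * 1e3 # uL/s / Hz -> uL -> nL
}

#' Does a droplet span the pulse train?
#'
#' @param volume_nL Droplet volume (nL).
#' @param jet A [jet_spec()].
#' @param train A [pulse_train()].
#' @return A one-row tibble: `spans` (logical), `margin` (volume over the
#'   minimum spanning volume; spans iff margin >= 1), and
#'   `min_volume_pL`.
#' @examples
#' spans_train(2.3, jet_spec(), pulse_train())
#' @export
spans_train <- function(volume_nL, jet, train) {
  check_positive(volume_nL, "volume_nL")
  vmin_pL <- min_spanning_volume(jet, train)
  margin <- volume_nL * 1e3 / vmin_pL
  tibble::tibble(
    spans = margin >= 1, margin = margin, min_volume_pL = vmin_pL
  )
}
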