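#' Sample volume injected during a run
#'
#' Only the crystal stream `Q_X` counts as sample; substrate and oil are
#' accounted separately.
#'
#' @param Q_X Crystal-stream flow rate (uL/min).
#' @param collection_time_min Data collection time (min).
#' @return Injected sample volume (uL).
#' @export
injected_volume <- function(Q_X, collection_time_min) {
  check_positive(Q_X, "Q_X", strict = FALSE)
  check_positive(collection_time_min, "collection_time_min", strict = FALSE)
  Q_X * collection_time_min
}

#' Indexed patterns per microliter of injected sample
#'
#' @param n_indexed Number of indexed diffraction patterns.
#' @param volume_uL Injected sample volume (uL).
#' @param round Round to the nearest integer for reporting (default); the
#'   exact ratio is returned when `FALSE`.
#' @return Patterns per uL.
#' @examples
#' patterns_per_volume(18794, 4.9 * 38)
#' @export
patterns_per_volume <- function(n_indexed, volume_uL, round = TRUE) {
  check_positive(n_indexed, "n_indexed", strict = FALSE)
  check_positive(volume_uL, "volume_uL")
  r <- n_indexed / volume_uL
  if (round) round(r) else r
}

#' Protein mass in an injected volume
#'
#' @param volume_uL Volume (uL).
#' @param concentration_mg_mL Protein concentration (mg/mL).
#' @return Protein mass (mg).
#' @export
protein_mass <- function(volume_uL, concentration_mg_mL) {
  check_positive(volume_uL, "volume_uL", strict = FALSE)
  check_positive(concentration_mg_mL, "concentration_mg_mL", strict = FALSE)
  volume_uL / 1e3 * concentration_mg_mL
}

#' Continuous-jet consumption for the same duration
#'
#' The comparator for droplet injection is a continuous gas-focused jet run
#' at the same total flow rate `Q_T` for the same time: the volume and
#' protein mass it would consume.
#'
#' @param Q_T Total flow rate (uL/min).
#' @param collection_time_min Collection time (min).
#' @param concentration_mg_mL Protein concentration (mg/mL).
#' @return A one-row tibble: `volume_uL`, `mass_mg`.
#' @examples
#' continuous_equivalent(28.1, 38, 18)
#' @export
continuous_equivalent <- function(Q_T, collection_time_min,
                                  concentration_mg_mL) {
  vol <- injected_volume(Q_T, collection_time_min)
  tibble::tibble(
    volume_uL = vol,
    mass_mg = protein_mass(vol, concentration_mg_mL)
  )
}

#' Sample savings of droplet versus continuous injection
#'
#' For equal durations the savings depend only on the flow ratio:
#' `savings_fraction = 1 - Q_X / Q_T`, `fold_savings = Q_T / Q_X`.
#'
#' @param Q_X Crystal-stream flow rate (uL/min); must be > 0.
#' @param Q_T Total flow rate (uL/min); must be >= `Q_X`.
#' @return A one-row tibble: `savings_fraction`, `fold_savings`.
#' @examples
#' savings(0.5, 19.2) # 97% saved
#' @export
savings <- function(Q_X, Q_T) {
  check_positive(Q_X, "Q_X")
  check_positive(Q_T, "Q_T")
  if (Q_T < Q_X) abort("`Q_T` must be >= `Q_X`.")
  tibble::tibble(
    savings_fraction = 1 - Q_X / Q_T,
    fold_savings = Q_T / Q_X
  )
}

#' Per-run sample-consumption report
#'
#' Assembles the consumption metrics for one or more runs: injected sample
#' volume, indexed patterns per uL, protein mass, the continuous-jet
#' comparator at the same total flow and duration, and the savings. As a
#' secondary comparator, `volume_equal_patterns_uL` gives the volume a
#' continuous jet would need to inject to collect the same pattern count at
#' this run's patterns-per-uL yield scaled by the flow ratio.
#'
#' @param runs A data frame with one row per run and columns `t_R_s`,
#'   `collection_time_min`, `n_indexed`, `Q_X_uL_min`, `Q_T_uL_min`,
#'   `protein_mg_mL` (plus any metadata columns, carried through).
#' @return A tibble with one row per run adding `injected_volume_uL`,
#'   `patterns_per_uL` (integer, as reported), `patterns_per_uL_exact`,
#'   `protein_mass_mg`, `continuous_volume_uL`, `continuous_mass_mg`,
#'   `savings_fraction`, `fold_savings`.
#' @examples
#' runs <- tibble::tibble(
#'   t_R_s = c(0.3, 1.2), collection_time_min = c(38, 85.5),
#'   n_indexed = c(18794, 10992), Q_X_uL_min = c(4.9, 0.5),
#'   Q_T_uL_min = c(28.1, 19.2), protein_mg_mL = c(18, 25.5)
#' )
#' consumption_report(runs)
#' @export
consumption_report <- function(runs) {
  runs <- tibble::as_tibble(runs)
  needed <- c(
    "t_R_s", "collection_time_min", "n_indexed", "Q_X_uL_min",
    "Q_T_uL_min", "protein_mg_mL"
  )
  missing <- setdiff(needed, names(runs))
  if (length(missing) > 0) {
    abort(paste0("`runs` is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(runs$Q_T_uL_min < runs$Q_X_uL_min)) {
    abort("Q_T must be >= Q_X in every run.")
  }
  runs |>
    dplyr::mutate(
      injected_volume_uL = injected_volume(
        .data$Q_X_uL_min, .data$collection_time_min
      ),
      patterns_per_uL_exact = .data$n_indexed / .data$injected_volume_uL,
      patterns_per_uL = round(.data$patterns_per_uL_exact),
      protein_mass_mg = protein_mass(
        .data$injected_volume_uL, .data$protein_mg_mL
      ),
      continuous_volume_uL = injected_volume(
        .data$Q_T_uL_min, .data$collection_time_min
      ),
      continuous_mass_mg = protein_mass(
        .data$continuous_volume_uL, .data$protein_mg_mL
      ),
      savings_fraction = 1 - .data$Q_X_uL_min / .data$Q_T_uL_min,
      fold_savings = .data$Q_T_uL_min / .data$Q_X_uL_min
    )
}
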