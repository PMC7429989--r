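#' Synthesise a 12-lead ECG from the patch-dipole model
#'
#' The net cardiac dipole is the sum of the local patch dipoles, each scaled
#' by a fixed unimodal activation waveform centred on the patch's activation
#' time (Gaussian, standard deviation `waveform_sd` ms):
#' `d(t) = sum_i strength_i * direction_i * w(t - t_i)`. The 8 independent
#' leads are `L %*% d(t)` with `L` the Moore-Penrose pseudo-inverse of the
#' Kors matrix, so applying the Kors transform to the simulated ECG recovers
#' `d(t)` exactly; the 4 dependent limb leads follow their exact linear
#' relations to I and II. Removed and unactivated patches contribute
#' nothing; doubling every dipole strength exactly doubles the ECG.
#'
#' @param model A `patch_model` (scar applied, if any).
#' @param scenario A `simulation_scenario`.
#' @param activation Optional precomputed activation-time vector; computed
#'   with [compute_activation()] when omitted.
#' @return An `ecg_recording` with attribute `"dipole"` (time x 3 matrix of
#'   the net source dipole, the generator ground truth) and attribute
#'   `"activation"` (the activation-time vector).
#' @export
simulate_ecg <- function(model, scenario, activation = NULL) {
  if (is.null(activation)) activation <- compute_activation(model, scenario)
  p <- model$patches
  sd_ms <- scenario$waveform_sd
  # shift by the isoelectric onset pad so no waveform is edge-truncated
  activation <- activation + scenario$onset_ms
  live <- which(!is.na(activation))
  last <- if (length(live)) max(activation[live]) else 0
  if (scenario$duration < last + 3 * sd_ms) {
    stop(sprintf(
      "invalid configuration: duration %.0f ms is shorter than the last activation (%.1f ms) + 3 waveform widths",
      scenario$duration, last), call. = FALSE)
  }
  t <- seq(0, scenario$duration, by = 1000 / scenario$sampling_rate)
  t <- t[t <= scenario$duration + 1e-9]

  strength <- p$dipole_strength
  if (!is.null(scenario$jitter) && is_fast(scenario)) {
    jit <- scenario$jitter
    strength <- strength * withr::with_seed(scenario$seed + 977L, {
      # common-mode factor: beat-to-beat modulation of the heart-electrode
      # coupling (respiration, posture); per-patch factor: local variability
      stats::rlnorm(1, 0, jit$common_sd %||% 0) *
        stats::rlnorm(nrow(p), 0, jit$strength_sd)
    })
  }

  dipole <- matrix(0, nrow = length(t), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (length(live)) {
    # W[t, i] = w(t - t_i); dipole = W %*% (strength * direction)
    W <- exp(-(outer(t, activation[live], "-"))^2 / (2 * sd_ms^2))
    M <- strength[live] * cbind(p$dx[live], p$dy[live], p$dz[live])
    dipole <- W %*% M
    colnames(dipole) <- c("x", "y", "z")
  }

  leads8 <- dipole %*% t(lead_field_matrix())
  samples <- cbind(
    I = leads8[, "I"], II = leads8[, "II"],
    derive_limb_leads(leads8[, "I"], leads8[, "II"]),
    leads8[, c("V1", "V2", "V3", "V4", "V5", "V6")])
  rec <- ecg_recording(samples, scenario$sampling_rate)
  attr(rec, "dipole") <- dipole
  attr(rec, "activation") <- activation
  rec
}

#' Run one scenario end to end: model, scar, activation, ECG
#'
#' Builds (or reuses) the patch model, applies the scenario's scar with the
#' scenario seed, computes activation and synthesises the ECG.
#'
#' @param scenario A `simulation_scenario`.
#' @param model Optional prebuilt `patch_model` to reuse across scenarios
#'   (the scar realisation still depends only on the scenario seed).
#' @return The `ecg_recording` (with `"dipole"` and `"activation"`
#'   attributes).
#' @export
simulate_scenario <- function(scenario, model = NULL) {
  if (is.null(model)) {
    model <- build_patch_model(scenario$n_patches, seed = scenario$seed)
  }
  model <- apply_scar(model, scenario$scar, seed = scenario$seed)
  simulate_ecg(model, scenario)
}

#' Simulate a paired slow/fast pacing experiment
#'
#' The two members share the same scar realisation (same seed) and differ
#' only in basic cycle length, exactly as in a paired pacing protocol.
#'
#' @param pair A `scenario_pair` (see [make_cohort()]), or a list with
#'   elements `slow` and `fast` holding `simulation_scenario`s.
#' @param model Optional shared `patch_model`.
#' @return List with `slow` and `fast` `ecg_recording`s.
#' @export
simulate_pair <- function(pair, model = NULL) {
  if (is.null(model)) {
    model <- build_patch_model(pair$slow$n_patches, seed = pair$slow$seed)
  }
  model <- apply_scar(model, pair$slow$scar, seed = pair$slow$seed)
  list(slow = simulate_ecg(model, pair$slow),
       fast = simulate_ecg(model, pair$fast))
}
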