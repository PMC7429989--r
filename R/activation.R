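#' Default endocardial root-site activation schedule
#'
#' Approximate sinus activation of the ventricles is delivered through a set
#' of early-activated endocardial sites standing in for the Purkinje network:
#' a configurable number of sites (default 8) spread over the LV endocardium
#' (rho = 0) with prescribed activation times staggered over the first
#' ~10 ms, apical sites earliest. The sites span phi in \[-2.2, 2.2\],
#' leaving the posterobasal free-wall seam (|phi| near pi) without direct
#' Purkinje input so that, as in normal hearts, it is the last region to
#' depolarise.
#'
#' @param n_sites Number of root sites.
#' @return Data frame with columns `phi`, `rho`, `z`, `time_ms`.
#' @export
default_root_sites <- function(n_sites = 8) {
  stopifnot(n_sites >= 1)
  phi <- seq(-2.2, 2.2, length.out = n_sites)
  z <- 0.25 + 0.3 * (0.5 - abs(seq(-0.5, 0.5, length.out = n_sites)))
  time_ms <- 10 * abs(seq(-1, 1, length.out = n_sites))
  data.frame(phi = phi, rho = 0, z = z, time_ms = time_ms)
}

#' Define a pacing scenario for the forward model
#'
#' @param bcl Basic cycle length in ms; 600 = slow pacing, 300 = rapid
#'   pacing (canonical values).
#' @param scar A `scar_definition`.
#' @param seed Integer seed controlling the stochastic scar realisation
#'   (and jitter, when enabled).
#' @param n_patches Patch count for the source model.
#' @param sampling_rate ECG sampling rate, Hz.
#' @param duration Recording duration, ms; must cover the last activation
#'   plus three activation-waveform widths.
#' @param root_sites Data frame as returned by [default_root_sites()].
#' @param conduction_velocity_cm_ms Healthy myocardial conduction velocity
#'   (cm/ms) applied to adjacency-graph edges; the default 0.09 places the
#'   control total activation time near 100 ms at the default geometry.
#' @param onset_ms Isoelectric onset pad (ms): the recording starts this
#'   long before the first prescribed root activation, so the earliest
#'   activation waveform is not truncated by the window edge.
#' @param rate_stress Multiplier (>= 1) applied to the scar slowing factors
#'   at rapid pacing only, modelling enhanced rate-dependent conduction
#'   slowing of relatively refractory fibrotic tissue. Healthy tissue is
#'   unaffected, so control activation is pacing-rate independent.
#' @param fast_bcl_threshold BCLs strictly below this (ms) count as rapid.
#' @param waveform_sd Standard deviation (ms) of the Gaussian activation
#'   waveform each patch contributes.
#' @param jitter Optional list `list(time_sd, strength_sd, common_sd)` of
#'   physiological beat-to-beat variability applied at the rapid rate only:
#'   root-site activation times receive Gaussian jitter (ms), patch dipole
#'   strengths independent lognormal jitter (sdlog), and the whole beat one
#'   common-mode lognormal amplitude factor (sdlog). `NULL` (default)
#'   disables jitter, making control scenarios exactly rate-neutral.
#' @return A `simulation_scenario`.
#' @export
simulation_scenario <- function(bcl, scar = scar_definition("none"), seed = 1,
                                n_patches = 1000, sampling_rate = 1000,
                                duration = 250,
                                root_sites = default_root_sites(),
                                conduction_velocity_cm_ms = 0.09,
                                onset_ms = 30,
                                rate_stress = 3,
                                fast_bcl_threshold = 450,
                                waveform_sd = 8,
                                jitter = NULL) {
  stopifnot(bcl > 0, duration > 0, nrow(root_sites) >= 1, rate_stress >= 1)
  structure(
    list(bcl = bcl, scar = scar, seed = as.integer(seed),
         n_patches = n_patches, sampling_rate = sampling_rate,
         duration = duration, root_sites = root_sites,
         conduction_velocity_cm_ms = conduction_velocity_cm_ms,
         onset_ms = onset_ms,
         rate_stress = rate_stress, fast_bcl_threshold = fast_bcl_threshold,
         waveform_sd = waveform_sd, jitter = jitter),
    class = "simulation_scenario")
}

is_fast <- function(scenario) scenario$bcl < scenario$fast_bcl_threshold

#' Compute activation times over the patch-adjacency graph
#'
#' Activation is the shortest-path arrival time from the root sites over the
#' k-nearest-neighbour patch graph. Edge traversal time is edge length
#' divided by the healthy conduction velocity, multiplied by a slowing
#' factor inside scar (`slow_factor_dense` in the dense core,
#' `slow_factor_intermediate` in the boundary and low-density zones; an edge
#' takes the mean factor of its endpoints). At rapid pacing the scar factors
#' are additionally multiplied by `rate_stress`, so control activation is
#' identical at both rates. Removed patches neither conduct nor activate.
#' Root sites falling on removed patches are re-seeded to the nearest
#' surviving patch. Surviving patches unreachable from every root are
#' flagged unactivated (time `NA`) with a warning and contribute no dipole.
#'
#' @param model A `patch_model`, with scar applied if any.
#' @param scenario A `simulation_scenario`.
#' @return Numeric vector of activation times (ms) per patch; `NA` for
#'   removed or unactivated patches.
#' @export
compute_activation <- function(model, scenario) {
  p <- model$patches
  n <- nrow(p)
  alive <- !p$removed
  act <- rep(NA_real_, n)
  if (!any(alive)) return(act)

  zone_factor <- c(healthy = 1,
                   low = scenario$scar$slow_factor_intermediate,
                   bz = scenario$scar$slow_factor_intermediate,
                   dense = scenario$scar$slow_factor_dense)
  if (scenario$scar$location == "none") {
    zone_factor[] <- 1
  } else if (is_fast(scenario)) {
    zone_factor[-1] <- zone_factor[-1] * scenario$rate_stress
  }
  pf <- zone_factor[as.character(p$zone)]

  g <- model$graph
  el <- igraph::as_edgelist(g, names = FALSE)
  keep <- alive[el[, 1]] & alive[el[, 2]]
  # an edge's traversal is slowed by the tissue the segment crosses, not
  # just its endpoints: with a wall only a couple of patch layers thick, an
  # endo-to-epi hop passes through midwall scar even when both endpoints
  # are healthy, so the zone at the edge midpoint (UVC average, phi
  # circular) enters the factor with trapezoid-with-midpoint weights
  a <- el[, 1]; b <- el[, 2]
  mid_phi <- atan2((sin(p$phi[a]) + sin(p$phi[b])) / 2,
                   (cos(p$phi[a]) + cos(p$phi[b])) / 2)
  mid_zone <- classify_zone_vec(mid_phi, (p$rho[a] + p$rho[b]) / 2,
                                (p$z[a] + p$z[b]) / 2, scenario$scar)
  mf <- zone_factor[as.character(mid_zone)]
  w <- igraph::E(g)$length / scenario$conduction_velocity_cm_ms *
    (pf[a] + 2 * mf + pf[b]) / 4
  gs <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
  wts <- w[keep]

  roots <- resolve_root_sites(model, scenario)
  dmat <- igraph::distances(gs, v = roots$index, weights = wts)
  arrival <- apply(dmat + roots$time_ms, 2, min)
  arrival[!alive] <- NA_real_
  if (any(alive & !is.finite(arrival))) {
    warning(sprintf("%d surviving patches are unreachable from the root sites and were excluded",
                    sum(alive & !is.finite(arrival))), call. = FALSE)
    arrival[!is.finite(arrival)] <- NA_real_
  }
  arrival
}

# Map prescribed UVC root sites to the nearest surviving patch; applies
# rapid-rate timing jitter when the scenario enables it.
resolve_root_sites <- function(model, scenario) {
  p <- model$patches
  alive <- which(!p$removed)
  rs <- scenario$root_sites
  idx <- integer(nrow(rs))
  for (i in seq_len(nrow(rs))) {
    # distance in UVC space, phi wrapped
    dphi <- abs(p$phi[alive] - rs$phi[i])
    dphi <- pmin(dphi, 2 * pi - dphi)
    d2 <- dphi^2 + (p$rho[alive] - rs$rho[i])^2 + (p$z[alive] - rs$z[i])^2
    idx[i] <- alive[which.min(d2)]
  }
  times <- rs$time_ms
  if (!is.null(scenario$jitter) && is_fast(scenario)) {
    times <- times + withr::with_seed(
      scenario$seed + 211L,
      stats::rnorm(length(times), 0, scenario$jitter$time_sd))
    times <- pmax(times, 0)
  }
  list(index = idx, time_ms = times)
}
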