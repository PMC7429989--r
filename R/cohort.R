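#' Default cohort sweep configuration
#'
#' The default cohort emulates a systematic sweep of scar geometry and
#' density in the two locations most prevalent in non-ischaemic dilated
#' cardiomyopathy: in each sweep all UVC parameters except the one varied
#' sit at their maximum range. LV free wall: 4 phi ranges, 5 rho ranges,
#' 4 z ranges and 2 reduced-density variants of the largest scar; septum:
#' 5 phi ranges, 5 rho ranges, 4 z ranges and 1 reduced-density variant.
#' That yields 30 scarred scenario pairs (15 per location) plus one
#' scar-free control pair, each pair simulated at a slow (600 ms) and a
#' rapid (300 ms) basic cycle length.
#'
#' @param n_patches,sampling_rate,duration,waveform_sd Generator settings
#'   shared by every scenario (see [simulation_scenario()]).
#' @param bcl_slow,bcl_fast The two pacing cycle lengths, ms.
#' @return A named list understood by [make_cohort()].
#' @export
default_cohort_config <- function(n_patches = 1000, sampling_rate = 1000,
                                  duration = 500, waveform_sd = 8,
                                  bcl_slow = 600, bcl_fast = 300) {
  list(
    n_patches = n_patches, sampling_rate = sampling_rate,
    duration = duration, waveform_sd = waveform_sd,
    bcl_slow = bcl_slow, bcl_fast = bcl_fast,
    lv = list(
      phi_lo = pi * c(0.875, 0.75, 0.625, 0.5),
      rho_hi = c(0.26, 0.42, 0.58, 0.74, 0.9),
      z_lo = c(0.75, 0.6, 0.45, 0.3),
      densities = list(c(0.75, 0.6, 0.45), c(0.6, 0.45, 0.3))),
    septum = list(
      phi_hi = c(0.2, 0.4, 0.6, 0.8, 1.0),
      rho_hi = c(0.26, 0.42, 0.58, 0.74, 0.9),
      z_lo = c(0.75, 0.6, 0.45, 0.3),
      densities = list(c(0.75, 0.6, 0.45))))
}

#' Generate the paired slow/fast simulation cohort
#'
#' Expands the sweep configuration into fully seeded scenario pairs: one
#' scar-free control pair plus one pair per scarred scenario, each pair
#' sharing a scar realisation and differing only in pacing rate. The cohort
#' is a pure function of `(config, seed)`.
#'
#' @param config Sweep configuration, see [default_cohort_config()].
#' @param seed Integer base seed; scenario `i` uses `seed + i`.
#' @return A `vcg_cohort`: list with `pairs` (named list of
#'   `scenario_pair`s: `slow`/`fast` scenarios, `label`, `id`) and
#'   `manifest` (one row per pair: id, location, UVC intervals, densities,
#'   seed, BCLs).
#' @export
make_cohort <- function(config = default_cohort_config(), seed = 1) {
  scars <- cohort_scars(config)
  if (length(scars) == 0) {
    stop("invalid configuration: empty sweep", call. = FALSE)
  }
  scars <- c(list(control = scar_definition("none")), scars)
  pairs <- vector("list", length(scars))
  names(pairs) <- names(scars)
  rows <- vector("list", length(scars))
  for (i in seq_along(scars)) {
    sc <- scars[[i]]
    id <- names(scars)[i]
    s <- as.integer(seed) + i
    mk <- function(bcl) simulation_scenario(
      bcl = bcl, scar = sc, seed = s, n_patches = config$n_patches,
      sampling_rate = config$sampling_rate, duration = config$duration,
      waveform_sd = config$waveform_sd)
    pairs[[i]] <- structure(
      list(slow = mk(config$bcl_slow), fast = mk(config$bcl_fast),
           label = sc$location, id = id),
      class = "scenario_pair")
    rows[[i]] <- data.frame(
      id = id, location = sc$location,
      phi_lo = sc$phi_range[1], phi_hi = sc$phi_range[2],
      rho_lo = sc$rho_range[1], rho_hi = sc$rho_range[2],
      z_lo = sc$z_range[1], z_hi = sc$z_range[2],
      p_dense = sc$p_dense, p_bz = sc$p_bz, p_low = sc$p_low,
      seed = s, bcl_slow = config$bcl_slow, bcl_fast = config$bcl_fast)
  }
  structure(list(pairs = pairs, manifest = do.call(rbind, rows),
                 config = config, seed = seed),
            class = "vcg_cohort")
}

# Expand the sweep configuration into named scar definitions.
cohort_scars <- function(config) {
  out <- list()
  add <- function(name, scar) out[[name]] <<- scar
  lv <- config$lv
  if (!is.null(lv)) {
    for (i in seq_along(lv$phi_lo)) {
      add(sprintf("lv_phi_%02d", i),
          scar_definition("lv_free_wall", phi_range = c(lv$phi_lo[i], pi)))
    }
    for (i in seq_along(lv$rho_hi)) {
      add(sprintf("lv_rho_%02d", i),
          scar_definition("lv_free_wall", rho_range = c(0.1, lv$rho_hi[i])))
    }
    for (i in seq_along(lv$z_lo)) {
      add(sprintf("lv_z_%02d", i),
          scar_definition("lv_free_wall", z_range = c(lv$z_lo[i], 0.9)))
    }
    for (i in seq_along(lv$densities)) {
      d <- lv$densities[[i]]
      add(sprintf("lv_density_%02d", i),
          scar_definition("lv_free_wall", p_dense = d[1], p_bz = d[2],
                          p_low = d[3]))
    }
  }
  sp <- config$septum
  if (!is.null(sp)) {
    for (i in seq_along(sp$phi_hi)) {
      add(sprintf("septum_phi_%02d", i),
          scar_definition("septum", phi_range = c(-sp$phi_hi[i], sp$phi_hi[i])))
    }
    for (i in seq_along(sp$rho_hi)) {
      add(sprintf("septum_rho_%02d", i),
          scar_definition("septum", rho_range = c(0.1, sp$rho_hi[i])))
    }
    for (i in seq_along(sp$z_lo)) {
      add(sprintf("septum_z_%02d", i),
          scar_definition("septum", z_range = c(sp$z_lo[i], 0.9)))
    }
    for (i in seq_along(sp$densities)) {
      d <- sp$densities[[i]]
      add(sprintf("septum_density_%02d", i),
          scar_definition("septum", p_dense = d[1], p_bz = d[2], p_low = d[3]))
    }
  }
  out
}

#' @export
print.vcg_cohort <- function(x, ...) {
  tab <- table(x$manifest$location)
  cat(sprintf("<vcg_cohort> %d scenario pairs (%s), base seed %d\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Scar-free control pairs with physiological beat-to-beat jitter
#'
#' Replicates the control (no-scar) pacing pair with small stochastic
#' variability on the rapid-rate member: Gaussian jitter of the root-site
#' activation times (`time_sd`, ms, beat-to-beat variation of the
#' conduction-system trigger), independent lognormal jitter of individual
#' patch dipole strengths (`strength_sd`, sdlog, local variability), and a
#' single common-mode lognormal amplitude factor per beat (`common_sd`,
#' sdlog, the respiratory/positional modulation of heart-electrode coupling
#' that dominates beat-to-beat ECG amplitude variability in recordings).
#' Without jitter the surrogate control is exactly rate-neutral; the
#' jittered replicates provide the non-degenerate control distribution
#' against which scar-induced rate dependence is compared.
#'
#' @param n Number of replicates.
#' @param seed Integer base seed.
#' @param config Cohort configuration (for the shared generator settings).
#' @param time_sd,strength_sd,common_sd Jitter magnitudes; defaults 5 ms,
#'   0.1 and 0.05.
#' @return Named list of `scenario_pair`s labelled `"none"`.
#' @export
jittered_control_pairs <- function(n = 15, seed = 1,
                                   config = default_cohort_config(),
                                   time_sd = 5, strength_sd = 0.1,
                                   common_sd = 0.05) {
  stopifnot(n >= 1)
  jit <- list(time_sd = time_sd, strength_sd = strength_sd,
              common_sd = common_sd)
  lapply(stats::setNames(seq_len(n), sprintf("control_jitter_%02d", seq_len(n))),
         function(i) {
    s <- as.integer(seed) + 1000L + i
    mk <- function(bcl, jitter) simulation_scenario(
      bcl = bcl, scar = scar_definition("none"), seed = s,
      n_patches = config$n_patches, sampling_rate = config$sampling_rate,
      duration = config$duration, waveform_sd = config$waveform_sd,
      jitter = jitter)
    structure(list(slow = mk(config$bcl_slow, NULL),
                   fast = mk(config$bcl_fast, jit),
                   label = "none", id = sprintf("control_jitter_%02d", i)),
              class = "scenario_pair")
  })
}
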