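#' Build an idealised two-chamber patch-dipole ventricular model
#'
#' Discretises an idealised two-chamber ventricular shell into equal-mass
#' patches, each carrying a position in model space (cm), universal
#' ventricular coordinates (UVC), and an outward (endo-to-epicardial) unit
#' dipole direction. The UVC system is: `phi` rotational in \[-pi, pi\]
#' (0 mid-septum, +/-pi in the LV free wall), `rho` transmural in \[0, 1\]
#' (0 LV endocardium, 1 epicardial/RV-endocardial surface), `z` apicobasal
#' in \[0, 1\] (0 apex, 1 base).
#'
#' The LV is a prolate half-ellipsoidal shell (apicobasal length
#' `length_cm`, basal endocardial radius `radius_cm`, wall thickness
#' `wall_cm`) whose patches are sampled uniformly in (phi, rho, z). The RV
#' free wall (fraction `rv_fraction` of the patches) is a thinner shell
#' segment wrapped around the septal side (`|phi| <` about 1), lying just
#' outside the LV epicardium so that, with root sites on the LV
#' endocardium, it activates through trans-septal conduction; RV patches
#' carry `rho = 1` (the epicardial/RV-endocardial surface), which keeps
#' them outside any midwall scar box. Patch adjacency for activation
#' spread is a symmetrised k-nearest-neighbour graph on patch positions,
#' stitched to a single connected component.
#'
#' @param n_patches Number of patches (>= 10).
#' @param seed Integer seed; the model is a pure function of
#'   `(n_patches, seed)` and the geometry arguments.
#' @param length_cm,radius_cm,wall_cm Shell geometry, cm.
#' @param rv_fraction Fraction of patches on the RV free wall.
#' @param rv_arc Half-arc (radians) of the RV free wall around mid-septum.
#' @param k Neighbours per patch in the adjacency graph.
#' @param total_strength Total dipole strength shared equally by the patches
#'   (arbitrary dipole units; scales the ECG linearly).
#' @return A `patch_model`: data frame `patches` (position `px,py,pz`, UVC
#'   `phi,rho,z`, `chamber`, `dipole_strength`, unit `dx,dy,dz`, `zone`,
#'   `removed`), the adjacency `graph` (igraph, edge attribute `length` in
#'   cm), the geometry parameters, and `free_wall_fraction`, the expected
#'   fraction of patches with `|phi| > pi/2`.
#' @export
build_patch_model <- function(n_patches, seed,
                              length_cm = 8, radius_cm = 3, wall_cm = 1,
                              rv_fraction = 0.25, rv_arc = 1.3,
                              k = 6, total_strength = 30) {
  if (!is.numeric(n_patches) || n_patches < 10) {
    stop("invalid configuration: n_patches must be >= 10", call. = FALSE)
  }
  n <- as.integer(n_patches)
  n_rv <- as.integer(round(rv_fraction * n))
  n_lv <- n - n_rv
  draws <- withr::with_seed(as.integer(seed), {
    list(phi = stats::runif(n_lv, -pi, pi),
         rho = stats::runif(n_lv, 0, 1),
         z = stats::runif(n_lv, 0, 1),
         psi = stats::runif(n_rv, -rv_arc, rv_arc),
         z_rv = stats::runif(n_rv, 0.15, 1))
  })

  pos_lv <- uvc_to_position(draws$phi, draws$rho, draws$z,
                            length_cm, radius_cm, wall_cm)
  dir_lv <- outward_directions(draws$phi, draws$z)
  # RV free wall: a shell segment just outside the LV epicardium on the
  # septal side; reachable only through the septal wall (or around the
  # junctions), as trans-septal activation requires
  r_rv <- radius_cm * sqrt(pmax(0, 1 - (1 - draws$z_rv)^2)) + wall_cm + 0.35
  pos_rv <- cbind(r_rv * cos(draws$psi), r_rv * sin(draws$psi),
                  length_cm * draws$z_rv)
  dir_rv <- outward_directions(draws$psi, draws$z_rv)

  phi <- c(draws$phi, draws$psi / rv_arc)   # RV phi mapped into [-1, 1]
  rho <- c(draws$rho, rep(1, n_rv))
  z <- c(draws$z, draws$z_rv)
  pos <- rbind(pos_lv, pos_rv)
  dirs <- rbind(dir_lv, dir_rv)

  patches <- data.frame(
    px = pos[, 1], py = pos[, 2], pz = pos[, 3],
    phi = phi, rho = rho, z = z,
    chamber = rep(c("lv", "rv"), c(n_lv, n_rv)),
    dipole_strength = total_strength / n,
    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
    zone = factor(rep("healthy", n), levels = zone_levels()),
    removed = FALSE)

  graph <- knn_graph(pos, k = k)

  structure(
    list(patches = patches, graph = graph, n_patches = n, seed = seed,
         geometry = list(length_cm = length_cm, radius_cm = radius_cm,
                         wall_cm = wall_cm, rv_fraction = rv_fraction,
                         rv_arc = rv_arc, k = k),
         free_wall_fraction = 0.5 * (1 - rv_fraction)),
    class = "patch_model")
}

zone_levels <- function() c("healthy", "low", "bz", "dense")

# Map UVC to 3D positions on a prolate half-ellipsoidal shell. The apex sits
# at the origin, the base at z = length_cm; the local radius follows
# sqrt(1 - (1 - z)^2) so the shell closes smoothly at the apex.
uvc_to_position <- function(phi, rho, z, length_cm, radius_cm, wall_cm) {
  r <- radius_cm * sqrt(pmax(0, 1 - (1 - z)^2)) + rho * wall_cm
  cbind(r * cos(phi), r * sin(phi), length_cm * z)
}

# Outward transmural unit directions: radial in the short-axis plane with a
# small apicobasal component near the apex (wavefronts travel endo -> epi).
outward_directions <- function(phi, z) {
  tilt <- -0.4 * (1 - z)          # apexward lean of the apical wall normal
  d <- cbind(cos(phi), sin(phi), tilt)
  d / sqrt(rowSums(d^2))
}

knn_graph <- function(pos, k) {
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges[[i]] <- cbind(i, nb)
  }
  e <- do.call(rbind, edges)
  # symmetrise: keep each undirected pair once
  e <- unique(t(apply(e, 1, sort)))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$length <- d[e]
  # k-NN graphs can leave small islands; stitch components together through
  # their closest point pairs so the intact myocardium is simply connected
  comp <- igraph::components(g)
  while (comp$no > 1) {
    main <- which(comp$membership == which.max(comp$csize))
    rest <- which(comp$membership != which.max(comp$csize))
    sub <- d[rest, main, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    g <- igraph::add_edges(g, c(rest[ij[1]], main[ij[2]]),
                           length = sub[ij[1], ij[2]])
    comp <- igraph::components(g)
  }
  g
}

#' @export
print.patch_model <- function(x, ...) {
  cat(sprintf("<patch_model> %d patches (%d removed), seed %s\n",
              x$n_patches, sum(x$patches$removed), format(x$seed)))
  invisible(x)
}

#' Define a fibrotic scar region in UVC coordinates
#'
#' A scar is a box in UVC space stratified into three density zones: a dense
#' central core (removal probability `p_dense`), a boundary zone (`p_bz`) and
#' a low-density outer region (`p_low`). The core spans the central
#' `dense_fraction` of the scar interval on every axis and the boundary zone
#' the central `bz_fraction`; defaults 2/3 and 5/6 with removal
#' probabilities (0.9, 0.75, 0.6). Conduction through surviving scar tissue
#' is slowed by `slow_factor_dense` in the core and
#' `slow_factor_intermediate` in the boundary and outer zones, surrogates for
#' the 50% and 25% conduction-velocity reductions of dense and intermediate
#' fibrosis.
#'
#' @param location `"none"`, `"lv_free_wall"` or `"septum"`.
#' @param phi_range,rho_range,z_range Closed UVC intervals. Defaults depend
#'   on location: the largest LV free-wall scar spans phi \[pi/2, pi\] and the
#'   largest septal scar phi \[-1, 1\], both with rho \[0.1, 0.9\] and
#'   z \[0.3, 0.9\] (midmyocardial with a basal tendency).
#' @param p_dense,p_bz,p_low Removal probabilities, `p_dense >= p_bz >= p_low`.
#' @param dense_fraction,bz_fraction Central-zone fractions,
#'   `0 < dense_fraction < bz_fraction <= 1`.
#' @param slow_factor_dense,slow_factor_intermediate Activation-delay
#'   multipliers > 1.
#' @return A `scar_definition`.
#' @export
scar_definition <- function(location = c("none", "lv_free_wall", "septum"),
                            phi_range = NULL, rho_range = c(0.1, 0.9),
                            z_range = c(0.3, 0.9),
                            p_dense = 0.9, p_bz = 0.75, p_low = 0.6,
                            dense_fraction = 2 / 3, bz_fraction = 5 / 6,
                            slow_factor_dense = 2,
                            slow_factor_intermediate = 4 / 3) {
  location <- match.arg(location)
  if (is.null(phi_range)) {
    phi_range <- switch(location,
                        none = c(0, 0),
                        lv_free_wall = c(pi / 2, pi),
                        septum = c(-1, 1))
  }
  chk_interval <- function(r, lo, hi, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo - 1e-12 || r[2] > hi + 1e-12) {
      stop("invalid configuration: ", nm, " must be a closed interval within [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk_interval(phi_range, -pi, pi, "phi_range")
  chk_interval(rho_range, 0, 1, "rho_range")
  chk_interval(z_range, 0, 1, "z_range")
  if (!(p_dense >= p_bz && p_bz >= p_low) || any(c(p_dense, p_bz, p_low) < 0) ||
      any(c(p_dense, p_bz, p_low) > 1)) {
    stop("invalid configuration: require 1 >= p_dense >= p_bz >= p_low >= 0",
         call. = FALSE)
  }
  if (!(dense_fraction > 0 && dense_fraction < bz_fraction && bz_fraction <= 1)) {
    stop("invalid configuration: require 0 < dense_fraction < bz_fraction <= 1",
         call. = FALSE)
  }
  if (slow_factor_dense <= 1 || slow_factor_intermediate <= 1) {
    stop("invalid configuration: slowing factors must exceed 1", call. = FALSE)
  }
  structure(
    list(location = location, phi_range = phi_range, rho_range = rho_range,
         z_range = z_range, p_dense = p_dense, p_bz = p_bz, p_low = p_low,
         dense_fraction = dense_fraction, bz_fraction = bz_fraction,
         slow_factor_dense = slow_factor_dense,
         slow_factor_intermediate = slow_factor_intermediate),
    class = "scar_definition")
}

#' @export
print.scar_definition <- function(x, ...) {
  if (x$location == "none") {
    cat("<scar_definition> none (control)\n")
  } else {
    cat(sprintf(
      "<scar_definition> %s  phi [%.2f, %.2f]  rho [%.2f, %.2f]  z [%.2f, %.2f]  p = (%g, %g, %g)\n",
      x$location, x$phi_range[1], x$phi_range[2], x$rho_range[1],
      x$rho_range[2], x$z_range[1], x$z_range[2], x$p_dense, x$p_bz, x$p_low))
  }
  invisible(x)
}

#' Classify a UVC point into a scar density zone
#'
#' A point outside any of the three scar intervals is `healthy`. Inside the
#' scar box, the scar-local normalised coordinate `u = (value - lo)/(hi - lo)`
#' is computed per axis; the point is `dense` if `u` lies within the central
#' `dense_fraction` on every axis, `bz` if within the central `bz_fraction`
#' on every axis, otherwise `low`.
#'
#' @param uvc List or named vector with `phi`, `rho`, `z`.
#' @param scar A `scar_definition`.
#' @return One of `"healthy"`, `"low"`, `"bz"`, `"dense"`.
#' @export
classify_zone <- function(uvc, scar) {
  z <- classify_zone_vec(uvc[["phi"]], uvc[["rho"]], uvc[["z"]], scar)
  as.character(z)
}

# Vectorised zone classification used by apply_scar.
classify_zone_vec <- function(phi, rho, z, scar) {
  n <- length(phi)
  out <- factor(rep("healthy", n), levels = zone_levels())
  if (scar$location == "none") return(out)
  inside <- in_interval(phi, scar$phi_range) &
    in_interval(rho, scar$rho_range) & in_interval(z, scar$z_range)
  if (!any(inside)) return(out)
  u_central <- function(v, r) {
    if (r[2] == r[1]) return(rep(0, length(v)))
    abs((v - r[1]) / (r[2] - r[1]) - 0.5)
  }
  cphi <- u_central(phi, scar$phi_range)
  crho <- u_central(rho, scar$rho_range)
  cz <- u_central(z, scar$z_range)
  cmax <- pmax(cphi, crho, cz)
  lvl <- ifelse(cmax <= scar$dense_fraction / 2, "dense",
                ifelse(cmax <= scar$bz_fraction / 2, "bz", "low"))
  out[inside] <- lvl[inside]
  out
}

in_interval <- function(v, r) v >= r[1] & v <= r[2]

#' Apply stochastic replacement fibrosis to a patch model
#'
#' Assigns each patch its scar density zone, then independently removes
#' scar-zone patches with the zone's removal probability (`p_dense`, `p_bz`,
#' `p_low`). Removed patches emulate non-conducting collagenous replacement:
#' they contribute no dipole and do not conduct. Healthy patches are never
#' removed. Deterministic for a fixed seed.
#'
#' @param model A `patch_model`.
#' @param scar A `scar_definition`.
#' @param seed Integer seed for the removal draws.
#' @return The model with updated `zone` and `removed` columns.
#' @export
apply_scar <- function(model, scar, seed) {
  stopifnot(inherits(model, "patch_model"), inherits(scar, "scar_definition"))
  p <- model$patches
  zone <- classify_zone_vec(p$phi, p$rho, p$z, scar)
  u <- withr::with_seed(as.integer(seed), stats::runif(nrow(p)))
  prob <- c(healthy = 0, low = scar$p_low, bz = scar$p_bz, dense = scar$p_dense)
  p$zone <- zone
  p$removed <- u < prob[as.character(zone)]
  model$patches <- p
  model$scar <- scar
  model
}
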