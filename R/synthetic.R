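# Synthetic water phantom and baseline collimated arc plans. Replaces patient
# CT data and the genetic baseline optimizer so the whole pipeline can be
# exercised end to end: a spherical water phantom with an ellipsoidal target,
# an adjacent organ at risk and a 10 mm rind, and a single 360-degree arc with
# one energy layer per gantry position, a 3 mm spot lattice with a 6 mm target
# expansion, per-spot trimmer configurations at 0 mm offset for out-of-target
# spots, and spot weights from a quadratic dose objective.

#' Phantom geometry specification
#'
#' @param phantom_radius_mm Radius of the spherical water phantom, mm.
#' @param ptv_center_mm,ptv_radii_mm Planning target volume: ellipsoid centre
#'   and semi-axes, mm.
#' @param oar_center_mm,oar_radius_mm Adjacent spherical organ at risk, mm.
#' @param rind_mm Thickness of the dose-spill scoring shell around the PTV.
#' @param spacing_mm Isotropic grid spacing, mm.
#' @param ctv_margin_mm The clinical target volume is the PTV eroded by this
#'   margin (robustness reporting).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(phantom_radius_mm = 170,
                         ptv_center_mm = c(0, 0, 0),
                         ptv_radii_mm = c(20, 15, 25),
                         oar_center_mm = c(0, 32, 0),
                         oar_radius_mm = 12,
                         rind_mm = 10,
                         spacing_mm = 3,
                         ctv_margin_mm = 3) {
  stopifnot(phantom_radius_mm > 0, all(ptv_radii_mm > 0), oar_radius_mm > 0,
            rind_mm >= 0, spacing_mm > 0, ctv_margin_mm >= 0)
  if (sqrt(sum(ptv_center_mm^2)) + max(ptv_radii_mm) >= phantom_radius_mm)
    stop("PTV must lie inside the phantom", call. = FALSE)
  structure(list(phantom_radius_mm = phantom_radius_mm,
                 ptv_center_mm = ptv_center_mm, ptv_radii_mm = ptv_radii_mm,
                 oar_center_mm = oar_center_mm, oar_radius_mm = oar_radius_mm,
                 rind_mm = rind_mm, spacing_mm = spacing_mm,
                 ctv_margin_mm = ctv_margin_mm),
            class = "phantom_spec")
}

#' Voxelize a phantom specification
#'
#' Builds the water-equivalent density grid and structure masks (`external`,
#' `ptv`, `ctv`, `rind10mm`, `oar`) on the isotropic grid, centred on the
#' phantom. Deterministic for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom`: `spacing_mm`, `dim`, `origin_mm` (centre
#'   of voxel `[1,1,1]`), `radius_mm`, `density` (3D array), `masks` (named
#'   logical vectors over the grid), `scored_idx` (grid indices inside the
#'   phantom).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  h <- spec$spacing_mm
  half <- ceiling(spec$phantom_radius_mm / h)
  ax <- (-half:half) * h
  n <- length(ax)
  cx <- rep(ax, times = n * n)
  cy <- rep(rep(ax, each = n), times = n)
  cz <- rep(ax, each = n * n)

  r2 <- cx^2 + cy^2 + cz^2
  external <- r2 <= spec$phantom_radius_mm^2
  density <- array(as.numeric(external), dim = c(n, n, n))

  inside_ellipsoid <- function(center, radii) {
    ((cx - center[1]) / radii[1])^2 + ((cy - center[2]) / radii[2])^2 +
      ((cz - center[3]) / radii[3])^2 <= 1
  }
  ptv <- inside_ellipsoid(spec$ptv_center_mm, spec$ptv_radii_mm) & external
  ctv <- inside_ellipsoid(spec$ptv_center_mm,
                          pmax(spec$ptv_radii_mm - spec$ctv_margin_mm, h)) & external
  rind <- inside_ellipsoid(spec$ptv_center_mm,
                           spec$ptv_radii_mm + spec$rind_mm) & external & !ptv
  oar <- ((cx - spec$oar_center_mm[1])^2 + (cy - spec$oar_center_mm[2])^2 +
            (cz - spec$oar_center_mm[3])^2 <= spec$oar_radius_mm^2) & external

  structure(list(spacing_mm = h, dim = c(n, n, n),
                 origin_mm = c(ax[1], ax[1], ax[1]),
                 radius_mm = spec$phantom_radius_mm,
                 density = density,
                 masks = list(external = external, ptv = ptv, ctv = ctv,
                              rind10mm = rind, oar = oar),
                 scored_idx = which(external),
                 spec = spec,
                 uid = phantom_uid(spec)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %dx%dx%d grid @ %g mm, radius %g mm\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing_mm, x$radius_mm))
  for (s in names(x$masks))
    cat(sprintf("  %-9s %6d voxels (%.1f cm3)\n", s, sum(x$masks[[s]]),
                sum(x$masks[[s]]) * (x$spacing_mm / 10)^3))
  invisible(x)
}

# geometry-cache key: phantoms with identical specs share cached beam
# geometry (safe: the geometry is a pure function of the spec)
phantom_uid <- function(spec) {
  paste(vapply(spec, function(x) paste(format(x, digits = 12), collapse = ","),
               character(1)), collapse = "|")
}

# voxel-centre coordinates of the scored (in-phantom) voxels, mm
phantom_coords <- function(phantom) {
  if (!is.null(phantom$.coords)) return(phantom$.coords)
  n <- phantom$dim
  idx <- phantom$scored_idx - 1L
  i <- idx %% n[1]
  j <- (idx %/% n[1]) %% n[2]
  k <- idx %/% (n[1] * n[2])
  cbind(phantom$origin_mm[1] + i * phantom$spacing_mm,
        phantom$origin_mm[2] + j * phantom$spacing_mm,
        phantom$origin_mm[3] + k * phantom$spacing_mm)
}

# ---- spot lattice ------------------------------------------------------------

# BEV projection of the PTV for a gantry angle and the spot lattice covering
# it with the stated expansion; in-target spots get NA offsets (off config),
# out-of-target spots record the outward direction used for 0 mm-offset bars
make_spot_lattice <- function(phantom, gantry_deg, spacing_mm = 3,
                              expansion_mm = 6) {
  ax <- beam_axes(gantry_deg)
  pc <- phantom_coords(phantom)[phantom$masks$ptv[phantom$scored_idx], , drop = FALSE]
  pu <- as.numeric(pc %*% ax$u)
  pv <- pc[, 3]
  ugrid <- lattice_axis(min(pu) - expansion_mm, max(pu) + expansion_mm, spacing_mm)
  vgrid <- lattice_axis(min(pv) - expansion_mm, max(pv) + expansion_mm, spacing_mm)
  grid <- expand.grid(x_mm = ugrid, y_mm = vgrid)
  # distance from each lattice point to the projected target point cloud
  halfvox <- phantom$spacing_mm * sqrt(2) / 2
  d2 <- vapply(seq_len(nrow(grid)), function(i)
    min((pu - grid$x_mm[i])^2 + (pv - grid$y_mm[i])^2), numeric(1))
  d <- pmax(sqrt(d2) - halfvox, 0)
  keep <- d <= expansion_mm
  grid <- grid[keep, , drop = FALSE]
  grid$in_target <- d[keep] <= 0
  # outward direction for collimating bars of out-of-target spots
  nearest <- vapply(seq_len(nrow(grid)), function(i)
    which.min((pu - grid$x_mm[i])^2 + (pv - grid$y_mm[i])^2), integer(1))
  grid$dir_x <- grid$x_mm - pu[nearest]
  grid$dir_y <- grid$y_mm - pv[nearest]
  rownames(grid) <- NULL
  grid
}

lattice_axis <- function(lo, hi, by) {
  n_lo <- floor(lo / by); n_hi <- ceiling(hi / by)
  (n_lo:n_hi) * by
}

# per-spot trimmer configurations for a lattice: in-target spots share the
# off configuration; an out-of-target spot gets 0 mm-offset bars on the
# side(s) facing away from the target projection, other bars off
lattice_control_point <- function(lattice, gantry_deg, energy_mev, machine,
                                  index = 0L) {
  off_mm <- machine$off_position_mm
  clamp <- function(x) pmin(pmax(x, -20), off_mm)
  n <- nrow(lattice)
  out <- !lattice$in_target
  cfg_id <- ifelse(out, sprintf("t%03d", seq_len(n)), "off")
  trim <- data.frame(
    id = cfg_id[out],
    x_neg = ifelse(lattice$dir_x[out] < -0.5, clamp(-lattice$x_mm[out]), off_mm),
    x_pos = ifelse(lattice$dir_x[out] > 0.5, clamp(lattice$x_mm[out]), off_mm),
    y_neg = ifelse(lattice$dir_y[out] < -0.5, clamp(-lattice$y_mm[out]), off_mm),
    y_pos = ifelse(lattice$dir_y[out] > 0.5, clamp(lattice$y_mm[out]), off_mm),
    stringsAsFactors = FALSE)
  configs <- rbind(trimmer_off(id = "off", off_mm = off_mm), trim)
  rownames(configs) <- NULL
  spots <- data.frame(
    id = sprintf("cp%03d_s%03d", index, seq_len(n)),
    x_mm = lattice$x_mm, y_mm = lattice$y_mm, mu = 1, config = cfg_id,
    stringsAsFactors = FALSE)
  control_point(gantry_deg, energy_mev, spots, configs, index = index)
}

# ---- baseline plan -----------------------------------------------------------

#' Generate a baseline collimated arc plan on a phantom
#'
#' One control point per gantry position, equally spaced over a single
#' 360 degree arc (clockwise, inclusive endpoints: `n_positions = 129` gives
#' the nominal 2.8125 degree spacing reported as 2.8 degrees). Each control
#' point carries one energy, chosen by a round-robin heuristic over the
#' target's radiological depth extent for that angle (a stand-in for a
#' genetic energy selection that produces realistically non-monotone energy
#' sequences). Spots lie on a lattice covering the target's beam's-eye-view
#' projection plus the expansion; out-of-target spots are trimmed with
#' 0 mm-offset bars on their outward side, in-target spots are uncollimated.
#' Weights come from [reoptimize_weights()] against the objectives, the
#' 0.025 MU floor and empty-control-point removal are applied, and the plan
#' is normalized to its prescription rule.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param n_positions Designed number of gantry positions (inclusive
#'   endpoints).
#' @param spot_spacing_mm Lateral lattice spacing, mm.
#' @param expansion_mm Lattice expansion beyond the target projection, mm.
#' @param machine A [machine_model()].
#' @param objectives A [dose_objectives()]; defaults target the prescription.
#' @param model A [beam_model()].
#' @param prescription_gy Prescription, Gy.
#' @param n_depth_slabs Round-robin depth slabs for energy selection.
#' @param seed Integer seed (jitters the depth sampling).
#' @return A validated, normalized `arc_plan`. Attribute `"dose_state"`
#'   carries the influence matrix of the surviving spots.
#' @export
make_baseline_plan <- function(phantom, n_positions = 129, spot_spacing_mm = 3,
                               expansion_mm = 6, machine = machine_model(),
                               objectives = NULL, model = beam_model(),
                               prescription_gy = 50, n_depth_slabs = 5,
                               seed = 1) {
  stopifnot(n_positions >= 2)
  resolution <- 360 / (n_positions - 1)
  gantry <- seq(-180, 180, length.out = n_positions)

  jitter <- with_seed(seed, stats::runif(n_positions, -0.45, 0.45))
  cps <- vector("list", n_positions)
  for (i in seq_len(n_positions)) {
    geom_depths <- target_depth_extent(phantom, gantry[i])
    slab <- ((i - 1) %% n_depth_slabs) + 0.5 + jitter[i]
    depth <- geom_depths[1] +
      (slab / n_depth_slabs) * (geom_depths[2] - geom_depths[1])
    depth <- min(max(depth, 5), 10 * energy_to_range(230))
    energy <- range_to_energy(depth / 10)
    lattice <- make_spot_lattice(phantom, gantry[i], spot_spacing_mm, expansion_mm)
    cps[[i]] <- lattice_control_point(lattice, gantry[i], energy, machine,
                                      index = i - 1L)
  }
  plan <- arc_plan(cps, prescription_gy = prescription_gy,
                   resolution_deg = resolution)

  if (is.null(objectives))
    objectives <- dose_objectives(target_gy = prescription_gy)
  ds <- influence_matrix(plan, phantom, model)
  fit <- reoptimize_weights(plan, ds, objectives, phantom)
  plan <- fit$plan
  ds <- fit$dose_state
  norm <- normalize_to_prescription(plan, ds, phantom)
  plan <- norm$plan
  ds <- norm$dose_state
  # normalization may push weights below the floor; filter once and re-level
  if (any(plan_mu(plan) < 0.025)) {
    plan <- remove_low_mu_spots(plan)
    ds <- influence_matrix(plan, phantom, model)
    norm <- normalize_to_prescription(plan, ds, phantom)
    plan <- norm$plan
    ds <- norm$dose_state
  }
  validate_plan(plan)
  attr(plan, "dose_state") <- ds
  plan
}

# radiological depth interval spanned by the PTV along a beam direction
target_depth_extent <- function(phantom, gantry_deg) {
  geom <- cp_geometry(phantom, gantry_deg)
  sel <- phantom$masks$ptv[phantom$scored_idx]
  range(geom$wed[sel])
}

# ---- energy-sequence fixtures ------------------------------------------------

#' Reproducible energy sequences for sorting experiments
#'
#' @param n Sequence length.
#' @param regime `"random"` (i.i.d. draws from a clinical energy ladder),
#'   `"sawtooth"` (repeated ascending ramps, guaranteeing at least `n/3`
#'   up-jumps) or `"descending"` (no up-jumps).
#' @param seed Integer seed.
#' @return Numeric vector of energies, MeV.
#' @export
make_energy_sequence_fixture <- function(n, regime = c("random", "sawtooth",
                                                       "descending"),
                                         seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n >= 1)
  ladder <- seq(70, 230, by = 2)
  switch(regime,
    random = with_seed(seed, sample(ladder, n, replace = TRUE)),
    sawtooth = {
      ramp_len <- 3L
      base <- with_seed(seed, sample(ladder[ladder <= 200], ceiling(n / ramp_len),
                                     replace = TRUE))
      head(as.numeric(vapply(base, function(b) b + (0:(ramp_len - 1)) * 10,
                             numeric(ramp_len))), n)
    },
    descending = {
      sort(with_seed(seed, sample(ladder, n, replace = TRUE)), decreasing = TRUE)
    })
}
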