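# Analytic collimated pencil-beam dose engine on a 3 mm isotropic grid.
# Depth dose: entrance plateau plus a Gaussian-smeared Bragg peak at the
# energy's water range. Lateral profile: 2D Gaussian with depth-dependent
# sigma, truncated by the four trimmer edges; voxel values are per-axis
# voxel-integrated (error-function) factors, so collimation can only remove
# fluence and a fully retracted configuration reproduces the open beam.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' Proton range in water from beam energy
#'
#' Bragg-Kleeman power law `R = alpha * E^p` with `alpha = 0.0022`,
#' `p = 1.77`; strictly increasing, so ordering by energy and ordering by
#' range coincide.
#'
#' @param energy_mev Beam energy, MeV (> 0). Vectorized.
#' @return Range, cm water-equivalent.
#' @export
energy_to_range <- function(energy_mev) {
  if (any(energy_mev <= 0)) stop("energy must be positive", call. = FALSE)
  0.0022 * energy_mev^1.77
}

#' @rdname energy_to_range
#' @param range_cm Range, cm water-equivalent (> 0).
#' @export
range_to_energy <- function(range_cm) {
  if (any(range_cm <= 0)) stop("range must be positive", call. = FALSE)
  (range_cm / 0.0022)^(1 / 1.77)
}

#' Pencil-beam model constants
#'
#' @param sigma_air_mm In-air spot sigma at isocenter, mm (median dedicated
#'   nozzle spot size 3.2 mm).
#' @param scatter_k Growth of lateral sigma with depth:
#'   `sigma(z) = sqrt(sigma_air^2 + (k z)^2)`.
#' @param plateau Entrance plateau amplitude relative to the unit Bragg-peak
#'   term.
#' @param peak_width_frac,peak_width_min_mm Bragg-peak Gaussian width as a
#'   fraction of range (straggling), with a floor, mm.
#' @param dose_rate_gy_per_mu Calibration: nominal Bragg-peak dose per monitor
#'   unit of an unclipped spot, Gy/MU.
#' @param lateral_cutoff_sigma Candidate voxels beyond this many sigma of the
#'   spot axis are skipped.
#' @param column_floor_rel Influence entries below this fraction of a
#'   beamlet's maximum are dropped from the sparse column.
#' @return A list of class `beam_model`.
#' @export
beam_model <- function(sigma_air_mm = 3.2, scatter_k = 0.025, plateau = 0.3,
                       peak_width_frac = 0.012, peak_width_min_mm = 1.5,
                       dose_rate_gy_per_mu = 1, lateral_cutoff_sigma = 4,
                       column_floor_rel = 1e-4) {
  structure(list(sigma_air_mm = sigma_air_mm, scatter_k = scatter_k,
                 plateau = plateau, peak_width_frac = peak_width_frac,
                 peak_width_min_mm = peak_width_min_mm,
                 dose_rate_gy_per_mu = dose_rate_gy_per_mu,
                 lateral_cutoff_sigma = lateral_cutoff_sigma,
                 column_floor_rel = column_floor_rel),
            class = "beam_model")
}

#' Normalized depth-dose of a beamlet
#'
#' Entrance plateau with an error-function distal falloff plus a Gaussian
#' Bragg peak at the range; a qualitative stand-in for a commissioned engine,
#' adequate for exercising collimation and sequencing trade-offs.
#'
#' @param z_mm Water-equivalent depth(s), mm.
#' @param range_mm Bragg-peak depth, mm.
#' @param model A [beam_model()].
#' @return Relative dose (peak term has unit amplitude).
#' @export
depth_dose <- function(z_mm, range_mm, model = beam_model()) {
  w <- max(model$peak_width_min_mm, model$peak_width_frac * range_mm)
  model$plateau * 0.5 * erfc((z_mm - range_mm) / (sqrt(2) * w)) +
    (1 - model$plateau) * exp(-(z_mm - range_mm)^2 / (2 * w^2))
}

#' @rdname depth_dose
#' @export
lateral_sigma <- function(z_mm, model = beam_model()) {
  sqrt(model$sigma_air_mm^2 + (model$scatter_k * z_mm)^2)
}

#' Transmitted fluence fraction through a trimmer aperture
#'
#' Closed error-function form of the surface integral of a 2D Gaussian spot
#' over the rectangular opening left by the four trimmer bars. A bar edge
#' exactly on the spot axis halves the integral on that axis; bars at the off
#' position leave the spot untouched.
#'
#' @param spot One-row spot `data.frame` (`x_mm`, `y_mm`).
#' @param config One-row configuration `data.frame`.
#' @param sigma_mm Spot sigma, mm.
#' @return Fraction in `[0, 1]`.
#' @export
aperture_transmission <- function(spot, config, sigma_mm) {
  fx <- stats::pnorm((config$x_pos - spot$x_mm) / sigma_mm) -
    stats::pnorm((-config$x_neg - spot$x_mm) / sigma_mm)
  fy <- stats::pnorm((config$y_pos - spot$y_mm) / sigma_mm) -
    stats::pnorm((-config$y_neg - spot$y_mm) / sigma_mm)
  pmax(fx, 0) * pmax(fy, 0)
}

# ---- control-point geometry --------------------------------------------------

# beam direction and beam's-eye-view axes for a gantry angle; the gantry
# rotates in the axial (x, y) plane about the phantom's superior-inferior (z)
# axis, beams are parallel (no divergence)
beam_axes <- function(gantry_deg) {
  th <- gantry_deg * pi / 180
  list(d = c(sin(th), -cos(th), 0),      # downstream
       u = c(cos(th), sin(th), 0),       # IEC X in BEV
       v = c(0, 0, 1))                   # IEC Y in BEV
}

# per-voxel BEV coordinates and water-equivalent depth for one gantry angle,
# over the phantom's scored voxels; WED by ray marching at grid resolution.
# Memoized per (phantom, angle): the same angles recur across the pipeline's
# influence rebuilds.
.geom_cache <- new.env(parent = emptyenv())

cp_geometry <- function(phantom, gantry_deg) {
  key <- paste0(phantom$uid, "@", formatC(gantry_deg, digits = 10, format = "g"))
  if (!is.null(phantom$uid)) {
    hit <- .geom_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  out <- cp_geometry_compute(phantom, gantry_deg)
  if (!is.null(phantom$uid)) {
    if (length(ls(.geom_cache)) > 400) rm(list = ls(.geom_cache), envir = .geom_cache)
    .geom_cache[[key]] <- out
  }
  out
}

cp_geometry_compute <- function(phantom, gantry_deg) {
  ax <- beam_axes(gantry_deg)
  pc <- phantom_coords(phantom)
  h <- phantom$spacing_mm
  u <- pc %*% ax$u
  v <- pc[, 3]
  n_steps <- ceiling(2 * phantom$radius_mm / h) + 2L
  wed <- numeric(nrow(pc))
  dm <- dim(phantom$density)
  for (m in seq_len(n_steps) - 1L) {
    q <- pc - rep((m + 0.5) * h, nrow(pc)) * matrix(ax$d, nrow(pc), 3, byrow = TRUE)
    ijk <- sweep(q, 2, phantom$origin_mm, "-") / h
    i <- round(ijk[, 1]) + 1L; j <- round(ijk[, 2]) + 1L; kk <- round(ijk[, 3]) + 1L
    ok <- i >= 1 & i <= dm[1] & j >= 1 & j <= dm[2] & kk >= 1 & kk <= dm[3]
    lin <- (kk[ok] - 1L) * dm[1] * dm[2] + (j[ok] - 1L) * dm[1] + i[ok]
    wed[ok] <- wed[ok] + phantom$density[lin] * h
  }
  list(u = as.numeric(u), v = as.numeric(v), wed = wed)
}

# sparse dose column (Gy/MU at scored voxels) of one spot given precomputed
# control-point geometry
spot_column <- function(geom, spot, config, range_mm, model, spacing_mm) {
  h <- spacing_mm
  sig_max <- lateral_sigma(min(range_mm * 1.2, 400), model)
  cut <- model$lateral_cutoff_sigma * sig_max + h
  cand <- which(abs(geom$u - spot$x_mm) <= cut &
                abs(geom$v - spot$y_mm) <= cut &
                geom$wed <= range_mm + 6 * max(model$peak_width_min_mm,
                                               model$peak_width_frac * range_mm) &
                geom$wed > 0)
  if (!length(cand)) return(list(idx = integer(0), val = numeric(0)))
  z <- geom$wed[cand]
  sig <- lateral_sigma(z, model)
  lo_x <- -config$x_neg; hi_x <- config$x_pos
  lo_y <- -config$y_neg; hi_y <- config$y_pos
  u <- geom$u[cand]; v <- geom$v[cand]
  fx <- stats::pnorm((pmin(u + h / 2, hi_x) - spot$x_mm) / sig) -
    stats::pnorm((pmax(u - h / 2, lo_x) - spot$x_mm) / sig)
  fy <- stats::pnorm((pmin(v + h / 2, hi_y) - spot$y_mm) / sig) -
    stats::pnorm((pmax(v - h / 2, lo_y) - spot$y_mm) / sig)
  val <- model$dose_rate_gy_per_mu * depth_dose(z, range_mm, model) *
    pmax(fx, 0) * pmax(fy, 0)
  # absolute sparsity floor, relative to the uncollimated beamlet's peak voxel
  # value, so that closing an aperture can only shrink the retained support
  # (keeps collimation monotone through the sparsification)
  f_axis_max <- 1 - 2 * stats::pnorm(-h / 2 / model$sigma_air_mm)
  floor_abs <- model$column_floor_rel * model$dose_rate_gy_per_mu * f_axis_max^2
  keep <- val > floor_abs
  list(idx = cand[keep], val = val[keep])
}

#' Dose column of a single beamlet
#'
#' @param spot One-row spot `data.frame`.
#' @param cp The owning `control_point` (supplies gantry angle, energy and,
#'   unless `config` is given, the spot's configuration).
#' @param phantom A [make_phantom()] phantom.
#' @param model A [beam_model()].
#' @param config Optional configuration override.
#' @return Numeric vector over the full grid, Gy/MU (zero outside the
#'   beamlet's sparse support).
#' @export
beamlet_dose <- function(spot, cp, phantom, model = beam_model(), config = NULL) {
  if (is.null(config))
    config <- cp$configs[match(spot$config, cp$configs$id), , drop = FALSE]
  geom <- cp_geometry(phantom, cp$gantry_deg)
  col <- spot_column(geom, spot, config, 10 * energy_to_range(cp$energy_mev),
                     model, phantom$spacing_mm)
  out <- numeric(prod(phantom$dim))
  out[phantom$scored_idx[col$idx]] <- col$val
  out
}

#' Dose-influence matrix of a plan
#'
#' One sparse column per spot, Gy/MU at every scored voxel (voxels inside the
#' phantom). Dose is linear in the monitor units: the plan dose is the matrix
#' product of the influence with the MU vector.
#'
#' @param plan An `arc_plan`.
#' @param phantom A [make_phantom()] phantom.
#' @param model A [beam_model()].
#' @param scenario Optional delivery-uncertainty [sample_scenario()] to apply
#'   (shifted spots and trimmer edges, offset gantry angles, scaled ranges).
#' @return A list of class `dose_state`: `influence` (`dgCMatrix`, scored
#'   voxels x spots), `spots` (bookkeeping `data.frame` with `cp`, `id`,
#'   `mu`), `scored_idx`, `n_grid`, `voxel_cm3`, `prescription_gy`.
#' @export
influence_matrix <- function(plan, phantom, model = beam_model(), scenario = NULL) {
  cps <- plan$control_points
  ii <- list(); vv <- list(); jj <- list()
  bk_cp <- list(); bk_id <- list(); bk_mu <- list()
  col <- 0L
  spot_at <- 0L
  for (ci in seq_along(cps)) {
    cp <- cps[[ci]]
    gantry <- cp$gantry_deg +
      if (!is.null(scenario)) scenario$gantry_offset_deg[ci] else 0
    geom <- cp_geometry(phantom, gantry)
    range_mm <- 10 * energy_to_range(cp$energy_mev) *
      if (!is.null(scenario)) scenario$range_scale else 1
    cfgs <- cp$configs
    if (!is.null(scenario)) {
      noise <- scenario$bar_noise[[ci]]
      cfgs$x_neg <- cfgs$x_neg + noise[, 1] - scenario$dcs_dx
      cfgs$x_pos <- cfgs$x_pos + noise[, 2] + scenario$dcs_dx
      cfgs$y_neg <- cfgs$y_neg + noise[, 3] - scenario$dcs_dy
      cfgs$y_pos <- cfgs$y_pos + noise[, 4] + scenario$dcs_dy
    }
    n_sp <- nrow(cp$spots)
    xs <- cp$spots$x_mm; ys <- cp$spots$y_mm
    if (!is.null(scenario)) {
      xs <- xs + scenario$spot_dx[spot_at + seq_len(n_sp)]
      ys <- ys + scenario$spot_dy[spot_at + seq_len(n_sp)]
    }
    cfg_row <- match(cp$spots$config, cfgs$id)
    for (si in seq_len(n_sp)) {
      sc <- spot_column(geom,
                        list(x_mm = xs[si], y_mm = ys[si]),
                        list(x_neg = cfgs$x_neg[cfg_row[si]],
                             x_pos = cfgs$x_pos[cfg_row[si]],
                             y_neg = cfgs$y_neg[cfg_row[si]],
                             y_pos = cfgs$y_pos[cfg_row[si]]),
                        range_mm, model, phantom$spacing_mm)
      col <- col + 1L
      ii[[col]] <- sc$idx
      vv[[col]] <- sc$val
      jj[[col]] <- rep.int(col, length(sc$idx))
    }
    bk_cp[[ci]] <- rep.int(ci, n_sp)
    bk_id[[ci]] <- cp$spots$id
    bk_mu[[ci]] <- cp$spots$mu
    spot_at <- spot_at + n_sp
  }
  influence <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(vv),
    dims = c(length(phantom$scored_idx), col))
  structure(list(influence = influence,
                 spots = data.frame(cp = unlist(bk_cp),
                                    id = unlist(bk_id),
                                    mu = unlist(bk_mu),
                                    stringsAsFactors = FALSE),
                 scored_idx = phantom$scored_idx,
                 n_grid = prod(phantom$dim),
                 voxel_cm3 = (phantom$spacing_mm / 10)^3,
                 prescription_gy = plan$prescription_gy),
            class = "dose_state")
}

#' Dose of a plan from its influence matrix
#'
#' @param dose_state A [influence_matrix()] result.
#' @param mu Optional MU vector overriding the one recorded in `dose_state`.
#' @return Dose, Gy, as a full-grid vector.
#' @export
compute_dose <- function(dose_state, mu = NULL) {
  if (is.null(mu)) mu <- dose_state$spots$mu
  stopifnot(length(mu) == ncol(dose_state$influence))
  d <- as.numeric(dose_state$influence %*% mu)
  out <- numeric(dose_state$n_grid)
  out[dose_state$scored_idx] <- d
  out
}

# ---- DVH and indices ---------------------------------------------------------

#' Cumulative dose-volume histogram
#'
#' @param dose Full-grid dose vector, Gy.
#' @param mask Logical mask (array or vector) selecting the structure.
#' @param bins Dose levels to evaluate; defaults to 200 levels from 0 to just
#'   above the structure maximum.
#' @return `data.frame` with `dose` (Gy) and `volume` (fraction of the
#'   structure receiving at least that dose); monotone nonincreasing, 1 at 0.
#' @export
dvh <- function(dose, mask, bins = NULL) {
  d <- dose[as.logical(mask)]
  if (!length(d)) stop("empty structure mask", call. = FALSE)
  if (is.null(bins)) bins <- seq(0, max(d) * 1.05 + 1e-9, length.out = 200)
  vol <- vapply(bins, function(b) mean(d >= b), numeric(1))
  data.frame(dose = bins, volume = vol)
}

#' Dose-at-volume quantile
#'
#' `D_q` is the smallest dose received by at least `q`% of the structure's
#' volume (so `D2` is a near-maximum, `D98` a near-minimum).
#'
#' @param dose Full-grid dose vector, or the structure's own dose vector when
#'   `mask` is `NULL`.
#' @param q_pct Volume percentage in (0, 100].
#' @param mask Optional structure mask.
#' @return Dose, Gy.
#' @export
dose_at_volume <- function(dose, q_pct, mask = NULL) {
  if (any(q_pct <= 0 | q_pct > 100)) stop("q_pct must be in (0, 100]", call. = FALSE)
  d <- if (is.null(mask)) dose else dose[as.logical(mask)]
  if (!length(d)) stop("empty structure mask", call. = FALSE)
  ds <- sort(d, decreasing = TRUE)
  ds[pmax(1L, ceiling(q_pct / 100 * length(ds)))]
}

#' Volume at dose
#'
#' @param dose Full-grid dose vector, Gy.
#' @param level Dose level, Gy.
#' @param mask Optional mask; the whole grid when `NULL` (as used by the
#'   gradient index).
#' @param voxel_cm3 Voxel volume (0.027 cm^3 for the 3 mm grid).
#' @return Volume receiving at least `level`, cm^3.
#' @export
volume_at_dose <- function(dose, level, mask = NULL, voxel_cm3 = 0.027) {
  if (level < 0) stop("dose level must be nonnegative", call. = FALSE)
  d <- if (is.null(mask)) dose else dose[as.logical(mask)]
  sum(d >= level) * voxel_cm3
}

#' Plan-quality indices
#'
#' Homogeneity index `HI = (D2 - D98) / Dp` over the planning target volume;
#' Paddick gradient index `GI = V50 / V100` with volumes over the whole grid;
#' Paddick conformity index `CI = (TVPIV / TV) * (TVPIV / V100)` where `TVPIV`
#' is the target volume receiving at least the prescription. When no voxel
#' reaches the prescription (`V100 = 0`), GI and CI are undefined and reported
#' as `NA`.
#'
#' @param dose Full-grid dose vector, Gy.
#' @param phantom A phantom with a `ptv` mask.
#' @param Dp Prescription dose, Gy.
#' @return A list of class `dose_indices`: `D2`, `D50`, `D95`, `D98`, `Dmean`
#'   (Gy, PTV), `V50pct`, `V100pct` (cm^3, whole grid), `HI`, `CI`, `GI`.
#' @export
quality_indices <- function(dose, phantom, Dp) {
  stopifnot(Dp > 0)
  ptv <- phantom$masks$ptv
  if (!any(ptv)) stop("empty PTV mask", call. = FALSE)
  vox <- (phantom$spacing_mm / 10)^3
  d_ptv <- dose[as.logical(ptv)]
  D <- function(q) dose_at_volume(d_ptv, q)
  v100 <- volume_at_dose(dose, Dp, voxel_cm3 = vox)
  v50 <- volume_at_dose(dose, 0.5 * Dp, voxel_cm3 = vox)
  tv <- sum(ptv) * vox
  tvpiv <- volume_at_dose(dose, Dp, mask = ptv, voxel_cm3 = vox)
  structure(list(
    D2 = D(2), D50 = D(50), D95 = D(95), D98 = D(98), Dmean = mean(d_ptv),
    V50pct = v50, V100pct = v100,
    HI = (D(2) - D(98)) / Dp,
    CI = if (v100 > 0) (tvpiv / tv) * (tvpiv / v100) else NA_real_,
    GI = if (v100 > 0) v50 / v100 else NA_real_),
    class = "dose_indices")
}

#' @export
print.dose_indices <- function(x, ...) {
  cat(sprintf(paste0(
    "<dose_indices> PTV D2 %.2f | D50 %.2f | D95 %.2f | D98 %.2f Gy\n",
    "  HI %.3f | CI %.3f | GI %.3f | V50%% %.1f cm3 | V100%% %.1f cm3\n"),
    x$D2, x$D50, x$D95, x$D98, x$HI, x$CI, x$GI, x$V50pct, x$V100pct))
  invisible(x)
}

#' Per-structure dose summary
#'
#' @param dose Full-grid dose vector, Gy.
#' @param phantom A phantom with structure masks.
#' @param structures Mask names to summarize (default: all).
#' @return `data.frame` with one row per structure: `Dmean`, `D2`, `D50`,
#'   `D98` (Gy).
#' @export
structure_indices <- function(dose, phantom, structures = names(phantom$masks)) {
  do.call(rbind, lapply(structures, function(s) {
    d <- dose[as.logical(phantom$masks[[s]])]
    data.frame(structure = s, Dmean = mean(d),
               D2 = dose_at_volume(d, 2), D50 = dose_at_volume(d, 50),
               D98 = dose_at_volume(d, 98), stringsAsFactors = FALSE)
  }))
}

#' Normalize a plan to its prescription rule
#'
#' Scales every spot's monitor units by one global factor so the target dose
#' quantile meets the prescription level (default rule: `D95% = 100%` of the
#' prescription on the PTV).
#'
#' @param plan An `arc_plan`.
#' @param dose_state Its [influence_matrix()] dose state.
#' @param phantom The phantom (for the PTV mask).
#' @return List with the scaled `plan`, updated `dose_state`, the scale
#'   `factor`, and the normalized full-grid `dose`.
#' @export
normalize_to_prescription <- function(plan, dose_state, phantom) {
  dose <- compute_dose(dose_state)
  q <- plan$normalization$d_quantile_pct
  level <- plan$normalization$level_pct / 100 * plan$prescription_gy
  d95 <- dose_at_volume(dose, q, mask = phantom$masks$ptv)
  if (d95 <= 0) stop("target receives no dose; cannot normalize", call. = FALSE)
  factor <- level / d95
  plan <- set_plan_mu(plan, plan_mu(plan) * factor)
  dose_state$spots$mu <- dose_state$spots$mu * factor
  list(plan = plan, dose_state = dose_state, factor = factor,
       dose = dose * factor)
}
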