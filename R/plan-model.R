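# ---- trimmer configurations --------------------------------------------------

#' Trimmer configuration
#'
#' A trimmer configuration is the position of the four sliding trimmer bars of
#' a dynamic collimation system (DCS) in the beam's-eye view. Each field is the
#' signed distance (mm) of that bar's medial edge from the beam central axis on
#' its own side: positive values retract the bar away from the axis, negative
#' values over-travel past it. A bar at `off_mm` (65 mm = 6.5 cm) is fully
#' retracted and does not collimate.
#'
#' @param x_neg,x_pos,y_neg,y_pos Bar positions, mm, each in `[-20, 65]`.
#' @param id Opaque label used by spots to reference the configuration.
#' @return A one-row `data.frame` with columns `id`, `x_neg`, `x_pos`,
#'   `y_neg`, `y_pos`.
#' @seealso [trimmer_off()], [trimmer_travel()]
#' @export
trimmer_config <- function(x_neg, x_pos, y_neg, y_pos, id = "cfg1") {
  cfg <- data.frame(id = as.character(id), x_neg = x_neg, x_pos = x_pos,
                    y_neg = y_neg, y_pos = y_pos, stringsAsFactors = FALSE)
  check_config(cfg)
  cfg
}

#' Fully retracted ("off") trimmer configuration
#'
#' @param id Configuration label.
#' @param off_mm Retraction distance of the off position, mm (default 65).
#' @return A one-row configuration `data.frame` with all four bars at `off_mm`.
#' @export
trimmer_off <- function(id = "off", off_mm = 65) {
  trimmer_config(off_mm, off_mm, off_mm, off_mm, id = id)
}

#' Test whether a configuration is the canonical off configuration
#'
#' @param config One-row configuration `data.frame` (or a list with the four
#'   bar fields).
#' @param off_mm Off position, mm.
#' @param tol Position tolerance, mm.
#' @return Logical flag.
#' @export
is_off_config <- function(config, off_mm = 65, tol = 1e-9) {
  all(abs(c(config$x_neg, config$x_pos, config$y_neg, config$y_pos) - off_mm) < tol)
}

check_config <- function(cfg, lo = -20, hi = 65) {
  vals <- unlist(cfg[, c("x_neg", "x_pos", "y_neg", "y_pos")])
  if (any(!is.finite(vals)))
    stop("trimmer positions must be finite", call. = FALSE)
  if (any(vals < lo - 1e-9 | vals > hi + 1e-9))
    stop(sprintf("trimmer positions must lie in [%g, %g] mm", lo, hi), call. = FALSE)
  invisible(TRUE)
}

# ---- control points and plans ------------------------------------------------

#' Construct a control point
#'
#' One gantry position of a step-and-shoot arc, carrying exactly one energy
#' layer, its spots, and the trimmer configurations used to collimate them.
#' Configurations are delivered in the listed order; spots are delivered
#' grouped by configuration in that order.
#'
#' @param gantry_deg Gantry angle, degrees, IEC convention, in `[-180, 180]`.
#' @param energy_mev Beam energy, MeV (one energy layer per control point).
#' @param spots `data.frame` with columns `id`, `x_mm`, `y_mm` (beam's-eye-view
#'   position at isocenter), `mu` (monitor units, >= 0) and `config`
#'   (configuration id).
#' @param configs `data.frame` of trimmer configurations (see
#'   [trimmer_config()]), in delivery order.
#' @param index 0-based position in delivery order (set by [arc_plan()]).
#' @return A list of class `control_point`.
#' @export
control_point <- function(gantry_deg, energy_mev, spots, configs, index = 0L) {
  stopifnot(is.data.frame(spots), is.data.frame(configs))
  cp <- structure(
    list(index = as.integer(index), gantry_deg = gantry_deg,
         energy_mev = energy_mev, spots = spots, configs = configs),
    class = "control_point")
  check_control_point(cp)
  cp
}

check_control_point <- function(cp) {
  if (!is.finite(cp$gantry_deg) || cp$gantry_deg < -180 - 1e-9 || cp$gantry_deg > 180 + 1e-9)
    stop("gantry_deg must lie in [-180, 180]", call. = FALSE)
  if (!is.finite(cp$energy_mev) || length(cp$energy_mev) != 1 || cp$energy_mev <= 0)
    stop("control point must carry exactly one positive energy", call. = FALSE)
  if (nrow(cp$spots) == 0)
    stop("control point with zero spots is invalid", call. = FALSE)
  if (any(cp$spots$mu < 0))
    stop("spot MU must be nonnegative", call. = FALSE)
  if (anyDuplicated(cp$configs$id))
    stop("duplicate configuration ids within a control point", call. = FALSE)
  bad <- setdiff(cp$spots$config, cp$configs$id)
  if (length(bad))
    stop("spot config reference(s) do not resolve: ", paste(bad, collapse = ", "),
         call. = FALSE)
  check_config(cp$configs)
  invisible(TRUE)
}

#' Construct an arc plan
#'
#' An ordered sequence of control points forming a single step-and-shoot arc,
#' together with prescription and normalization metadata. Gantry angles must be
#' strictly monotone in delivery order. An arc designed with `n` inclusive
#' positions over 360 degrees has nominal resolution `360 / (n - 1)` degrees
#' (129 positions give 2.8125, reported as 2.8).
#'
#' @param control_points List of [control_point()] objects in delivery order.
#' @param prescription_gy Prescription dose, Gy (50 in the reference plans).
#' @param resolution_deg Nominal control-point spacing, degrees.
#' @param normalization Normalization rule: dose quantile (percent of volume)
#'   and level (percent of prescription); the default `D95% = 100%` scales the
#'   plan so 95% of the target receives the full prescription.
#' @return A list of class `arc_plan`.
#' @export
arc_plan <- function(control_points, prescription_gy = 50, resolution_deg = 2.8125,
                     normalization = list(d_quantile_pct = 95, level_pct = 100)) {
  stopifnot(is.list(control_points), length(control_points) >= 1)
  for (i in seq_along(control_points)) control_points[[i]]$index <- i - 1L
  plan <- structure(
    list(control_points = control_points,
         prescription_gy = prescription_gy,
         normalization = normalization,
         resolution_deg = resolution_deg,
         direction = infer_direction(control_points)),
    class = "arc_plan")
  check_arc_plan(plan)
  plan
}

infer_direction <- function(cps) {
  g <- vapply(cps, function(cp) cp$gantry_deg, numeric(1))
  if (length(g) < 2 || g[2] > g[1]) "cw" else "ccw"
}

check_arc_plan <- function(plan) {
  g <- gantry_angles(plan)
  if (length(g) > 1) {
    d <- diff(g)
    if (!(all(d > 0) || all(d < 0)))
      stop("gantry angles must be strictly monotone in delivery order", call. = FALSE)
  }
  for (cp in plan$control_points) check_control_point(cp)
  if (!is.finite(plan$prescription_gy) || plan$prescription_gy <= 0)
    stop("prescription_gy must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Validate an arc plan, including the monitor-unit floor
#'
#' Checks every structural invariant ([arc_plan()] already enforces those at
#' construction) plus the deliverability rule that every spot carries at least
#' `mu_floor` monitor units. Spot weights below 0.025 MU are not deliverable
#' and must be filtered with [remove_low_mu_spots()] first.
#'
#' @param plan An `arc_plan`.
#' @param mu_floor Minimum deliverable monitor units (default 0.025).
#' @return Invisibly `TRUE`; errors listing all failures otherwise.
#' @export
validate_plan <- function(plan, mu_floor = 0.025) {
  check_arc_plan(plan)
  failures <- character(0)
  for (cp in plan$control_points) {
    low <- cp$spots$mu < mu_floor
    if (any(low))
      failures <- c(failures, sprintf(
        "control point %d (gantry %.4g deg): %d spot(s) below %.3f MU",
        cp$index, cp$gantry_deg, sum(low), mu_floor))
  }
  if (length(failures))
    stop("plan validation failed:\n  ", paste(failures, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

# ---- accessors ---------------------------------------------------------------

#' @export
print.arc_plan <- function(x, ...) {
  cat(sprintf("<arc_plan> %d control points, %d spots, %d configs\n",
              length(x$control_points), n_spots(x), n_configs(x)))
  cat(sprintf("  gantry %.4g to %.4g deg (%s), resolution %.4g deg\n",
              x$control_points[[1]]$gantry_deg,
              x$control_points[[length(x$control_points)]]$gantry_deg,
              x$direction, x$resolution_deg))
  cat(sprintf("  prescription %.4g Gy, normalized to D%g%% = %g%%\n",
              x$prescription_gy, x$normalization$d_quantile_pct,
              x$normalization$level_pct))
  invisible(x)
}

#' Plan accessors
#'
#' Small helpers over an `arc_plan`: per-control-point gantry angles and
#' energies, and plan-wide spot/configuration counts.
#'
#' @param plan An `arc_plan`.
#' @return Numeric vector (angles, energies) or integer count.
#' @export
gantry_angles <- function(plan) {
  vapply(plan$control_points, function(cp) cp$gantry_deg, numeric(1))
}

#' @rdname gantry_angles
#' @export
plan_energies <- function(plan) {
  vapply(plan$control_points, function(cp) cp$energy_mev, numeric(1))
}

#' @rdname gantry_angles
#' @export
n_spots <- function(plan) {
  sum(vapply(plan$control_points, function(cp) nrow(cp$spots), integer(1)))
}

#' @rdname gantry_angles
#' @export
n_configs <- function(plan) {
  sum(vapply(plan$control_points, function(cp) nrow(cp$configs), integer(1)))
}

#' All spot monitor units of a plan, in delivery order
#'
#' @param plan An `arc_plan`.
#' @return Numeric vector of MU, one entry per spot.
#' @export
plan_mu <- function(plan) {
  unlist(lapply(plan$control_points, function(cp) cp$spots$mu), use.names = FALSE)
}

#' Replace all spot monitor units of a plan, in delivery order
#'
#' @param plan An `arc_plan`.
#' @param mu Numeric vector, one entry per spot, same order as [plan_mu()].
#' @return The plan with updated weights.
#' @export
set_plan_mu <- function(plan, mu) {
  stopifnot(length(mu) == n_spots(plan), all(mu >= 0))
  at <- 0L
  for (i in seq_along(plan$control_points)) {
    k <- nrow(plan$control_points[[i]]$spots)
    plan$control_points[[i]]$spots$mu <- mu[at + seq_len(k)]
    at <- at + k
  }
  plan
}

# ---- plan filters ------------------------------------------------------------

#' Remove undeliverable low-weight spots
#'
#' Drops every spot with fewer monitor units than `floor_mu`, then removes
#' control points left without any spot and configurations no surviving spot
#' references. The operation is idempotent and preserves delivery order.
#'
#' @param plan An `arc_plan`.
#' @param floor_mu Minimum deliverable monitor units (default 0.025).
#' @return The filtered `arc_plan`; may have fewer control points (or none, in
#'   which case a zero-control-point plan is returned).
#' @export
remove_low_mu_spots <- function(plan, floor_mu = 0.025) {
  kept <- list()
  for (cp in plan$control_points) {
    spots <- cp$spots[cp$spots$mu >= floor_mu, , drop = FALSE]
    if (nrow(spots) == 0) next
    cfgs <- cp$configs[cp$configs$id %in% spots$config, , drop = FALSE]
    rownames(spots) <- rownames(cfgs) <- NULL
    cp$spots <- spots
    cp$configs <- cfgs
    kept[[length(kept) + 1]] <- cp
  }
  if (length(kept) == 0) {
    plan$control_points <- list()
    return(plan)
  }
  for (i in seq_along(kept)) kept[[i]]$index <- i - 1L
  plan$control_points <- kept
  plan
}

#' Normalized control-point weights
#'
#' The weight of a control point is the sum of monitor units over its spots;
#' weights are normalized to the mean control-point weight, so the returned
#' sequence always averages to one. These weights drive the Cut stage
#' ([cut_control_points()]).
#'
#' @param plan An `arc_plan` with at least one control point.
#' @return Numeric vector of normalized weights, one per control point.
#' @export
control_point_weights <- function(plan) {
  if (length(plan$control_points) == 0)
    stop("cannot compute control-point weights of an empty plan", call. = FALSE)
  w <- vapply(plan$control_points, function(cp) sum(cp$spots$mu), numeric(1))
  w / mean(w)
}
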