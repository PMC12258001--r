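# Beam delivery time (BDT) model. All delivery events are strictly sequential:
# at each control point the machine switches energy, then alternates trimmer
# positioning and spot delivery, then the gantry moves to the next position.

#' Rest-to-rest gantry move time
#'
#' Trapezoidal velocity profile with symmetric acceleration and deceleration.
#' For a move of `d` degrees with top speed `v` and acceleration `a`, the
#' profile is trapezoidal (`d/v + v/a`) when the distance is long enough to
#' reach top speed (`d >= v^2/a`) and triangular (`2*sqrt(d/a)`) otherwise.
#' The two branches agree at `d = v^2/a`.
#'
#' @param distance_deg Nonnegative move distance(s), degrees. Vectorized.
#' @param machine A [machine_model()].
#' @return Move time(s), seconds.
#' @export
gantry_move_time <- function(distance_deg, machine = machine_model()) {
  if (any(distance_deg < 0)) stop("move distance must be nonnegative", call. = FALSE)
  v <- machine$v_max
  a <- machine$a_max
  ifelse(distance_deg >= v^2 / a,
         distance_deg / v + v / a,
         2 * sqrt(distance_deg / a))
}

#' Energy layer switch time
#'
#' Switching to a higher energy requires re-tuning the beamline upward and is
#' slow (`t_up`, 6 s by default); switching downward is fast (`t_down`,
#' 0.8 s). No time is charged when the energy does not change.
#'
#' @param e_from,e_to Energies, MeV. Vectorized.
#' @param machine A [machine_model()].
#' @return Switch time(s), seconds.
#' @export
energy_switch_time <- function(e_from, e_to, machine = machine_model()) {
  stopifnot(all(e_from > 0), all(e_to > 0))
  ifelse(e_to > e_from, machine$t_up, ifelse(e_to < e_from, machine$t_down, 0))
}

#' Spot delivery time
#'
#' Linear in the spot weight: `(slope * mu + slew) / 1000` seconds. The slew
#' term covers magnetic scanning between spot positions and applies to every
#' spot, including zero-weight ones.
#'
#' @param mu Monitor units, >= 0. Vectorized.
#' @param machine A [machine_model()].
#' @return Delivery time(s), seconds.
#' @export
spot_time <- function(mu, machine = machine_model()) {
  if (any(mu < 0)) stop("mu must be nonnegative", call. = FALSE)
  (machine$spot_slope * mu + machine$spot_slew) / 1000
}

#' Trimmer travel distance between two configurations
#'
#' @param a,b One-row configuration `data.frame`s.
#' @param metric `"max_bar"`: the largest single-bar displacement (bars move
#'   simultaneously, the slowest bar gates the pause); `"sum_bars"`: total
#'   displacement over the four bars.
#' @return Travel distance, mm.
#' @export
trimmer_travel <- function(a, b, metric = c("max_bar", "sum_bars")) {
  metric <- match.arg(metric)
  d <- abs(c(a$x_neg - b$x_neg, a$x_pos - b$x_pos,
             a$y_neg - b$y_neg, a$y_pos - b$y_pos))
  if (metric == "max_bar") max(d) else sum(d)
}

#' Trimmer repositioning time
#'
#' Second-order polynomial in the travel distance, `c0 + c1*d + c2*d^2`
#' seconds, with zero travel costing nothing (no motion, no pause).
#'
#' @param travel_mm Travel distance(s), mm, >= 0. Vectorized.
#' @param machine A [machine_model()].
#' @return Repositioning time(s), seconds.
#' @export
trimmer_move_time <- function(travel_mm, machine = machine_model()) {
  if (any(travel_mm < 0)) stop("travel must be nonnegative", call. = FALSE)
  p <- machine$trimmer_poly
  t <- p[1] + p[2] * travel_mm + p[3] * travel_mm^2
  t[travel_mm == 0] <- 0
  if (any(t < 0))
    stop("trimmer polynomial yields negative time; check coefficients", call. = FALSE)
  t
}

#' Per-component beam delivery time breakdown
#'
#' @param t_gantry,t_energy,t_trimmer,t_spot Component times, seconds.
#' @return A list of class `bdt_breakdown` whose `total` is the sum of the
#'   four components.
#' @export
bdt_breakdown <- function(t_gantry = 0, t_energy = 0, t_trimmer = 0, t_spot = 0) {
  stopifnot(t_gantry >= 0, t_energy >= 0, t_trimmer >= 0, t_spot >= 0)
  structure(list(t_gantry = t_gantry, t_energy = t_energy,
                 t_trimmer = t_trimmer, t_spot = t_spot,
                 total = t_gantry + t_energy + t_trimmer + t_spot),
            class = "bdt_breakdown")
}

#' @export
print.bdt_breakdown <- function(x, ...) {
  cat(sprintf(paste0(
    "<bdt_breakdown> total %.1f s (%.1f min)\n",
    "  gantry %.1f s | energy %.1f s | trimmer %.1f s | spot %.1f s\n"),
    x$total, x$total / 60, x$t_gantry, x$t_energy, x$t_trimmer, x$t_spot))
  invisible(x)
}

#' Estimate the beam delivery time of an arc plan
#'
#' Walks the plan in delivery order charging strictly sequential events: at
#' each control point an energy switch from the previous control point's
#' energy (nothing before the first), then, for each trimmer configuration in
#' delivery order, the trimmer move from the preceding configuration followed
#' by the delivery of that configuration's spots. Trimmer state threads across
#' control points and starts at the fully retracted off position. Gantry time
#' is the sum of rest-to-rest moves between consecutive control points; a
#' control point removed by the Cut stage therefore merges its two neighbouring
#' moves into one longer, cheaper move.
#'
#' @param plan An `arc_plan`.
#' @param machine A [machine_model()].
#' @param per_cp If `TRUE`, attach a per-control-point component `data.frame`
#'   as attribute `"per_cp"`.
#' @return A [bdt_breakdown()].
#' @export
plan_bdt <- function(plan, machine = machine_model(), per_cp = FALSE) {
  cps <- plan$control_points
  if (length(cps) == 0) return(bdt_breakdown())
  check_arc_plan(plan)

  prev_cfg <- trimmer_off(off_mm = machine$off_position_mm)
  prev_energy <- NULL
  t_energy <- t_trimmer <- t_spot <- numeric(length(cps))
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    if (!is.null(prev_energy))
      t_energy[i] <- energy_switch_time(prev_energy, cp$energy_mev, machine)
    for (j in seq_len(nrow(cp$configs))) {
      cfg <- cp$configs[j, ]
      t_trimmer[i] <- t_trimmer[i] + trimmer_move_time(
        trimmer_travel(prev_cfg, cfg, machine$trimmer_metric), machine)
      mu <- cp$spots$mu[cp$spots$config == cfg$id]
      t_spot[i] <- t_spot[i] + sum(spot_time(mu, machine))
      prev_cfg <- cfg
    }
    prev_energy <- cp$energy_mev
  }
  g <- gantry_angles(plan)
  moves <- abs(diff(g))
  t_gantry_cp <- c(0, gantry_move_time(moves, machine))

  out <- bdt_breakdown(sum(t_gantry_cp), sum(t_energy), sum(t_trimmer), sum(t_spot))
  if (per_cp) {
    attr(out, "per_cp") <- data.frame(
      index = vapply(cps, function(cp) cp$index, integer(1)),
      gantry_deg = g, t_gantry = t_gantry_cp, t_energy = t_energy,
      t_trimmer = t_trimmer, t_spot = t_spot,
      total = t_gantry_cp + t_energy + t_trimmer + t_spot)
  }
  out
}

#' Manual intervention time of a multi-beam IMPT plan
#'
#' Fixed-beam intensity-modulated proton plans require manual steps between
#' beams (alignment checks, re-imaging): 30 s per beam transition plus an
#' extra 120 s whenever the couch angle changes (a couch kick).
#'
#' @param beams `data.frame` with columns `gantry_deg` and `couch_deg`, one
#'   row per beam in delivery order.
#' @return Total intervention time, seconds.
#' @export
impt_intervention_time <- function(beams) {
  stopifnot(is.data.frame(beams), all(c("gantry_deg", "couch_deg") %in% names(beams)))
  if (nrow(beams) == 0) stop("at least one beam is required", call. = FALSE)
  if (any(!is.finite(beams$couch_deg)) || any(!is.finite(beams$gantry_deg)))
    stop("beam angles must be finite", call. = FALSE)
  if (nrow(beams) == 1) return(0)
  kicks <- diff(beams$couch_deg) != 0
  sum(30 + 120 * kicks)
}
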