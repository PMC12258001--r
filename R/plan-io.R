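# ---- machine model -----------------------------------------------------------

#' Delivery-system parameter set
#'
#' Every parameter of the beam-delivery-time model in one place. Defaults
#' describe an IBA ProteusPLUS-class step-and-shoot gantry with a dynamic
#' collimation system: maximum gantry velocity 6 deg/s and acceleration
#' 0.6 deg/s^2; spot delivery time linear in spot weight with slope 6.6 ms/MU
#' plus 2.2 ms magnetic-scanning slew per spot; energy switching 6 s upward
#' (low to high) and 0.8 s downward; trimmer repositioning time a second-order
#' polynomial in the travel distance.
#'
#' The default trimmer polynomial coefficients `(0.3, 0.008, 2e-5)` (seconds;
#' travel in mm) are a documented configuration choice sized so a full 65 mm
#' throw pauses delivery for about 0.9 s; sites with fitted log-file models
#' should substitute their own coefficients.
#'
#' @param v_max Maximum gantry velocity, deg/s.
#' @param a_max Gantry acceleration, deg/s^2.
#' @param t_up Low-to-high energy switch time, s.
#' @param t_down High-to-low energy switch time, s.
#' @param spot_slope Spot delivery slope, ms/MU.
#' @param spot_slew Per-spot magnetic scanning slew, ms.
#' @param trimmer_poly Coefficients `(c0, c1, c2)` of the trimmer travel-time
#'   polynomial `c0 + c1 * d + c2 * d^2` (d in mm, result in s).
#' @param trimmer_metric `"max_bar"` (bars move simultaneously; the slowest
#'   bar gates the pause) or `"sum_bars"` (sensitivity studies).
#' @param off_position_mm Fully retracted trimmer position, mm.
#' @return A list of class `machine_model`.
#' @export
machine_model <- function(v_max = 6, a_max = 0.6, t_up = 6, t_down = 0.8,
                          spot_slope = 6.6, spot_slew = 2.2,
                          trimmer_poly = c(0.3, 0.008, 2e-5),
                          trimmer_metric = c("max_bar", "sum_bars"),
                          off_position_mm = 65) {
  trimmer_metric <- match.arg(trimmer_metric)
  stopifnot(v_max > 0, a_max > 0, t_up >= 0, t_down >= 0,
            spot_slope >= 0, spot_slew >= 0, length(trimmer_poly) == 3)
  structure(list(v_max = v_max, a_max = a_max, t_up = t_up, t_down = t_down,
                 spot_slope = spot_slope, spot_slew = spot_slew,
                 trimmer_poly = as.numeric(trimmer_poly),
                 trimmer_metric = trimmer_metric,
                 off_position_mm = off_position_mm),
            class = "machine_model")
}

#' Read a machine parameter file
#'
#' Accepts YAML or JSON with fields mirroring [machine_model()]; missing
#' fields fall back to the defaults.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A `machine_model`.
#' @export
read_machine_model <- function(path) {
  if (!file.exists(path)) stop("machine file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(machine_model))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown machine parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(machine_model, raw)
}

#' @export
print.machine_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<machine_model> gantry %g deg/s @ %g deg/s^2; energy switch up %g s / down %g s\n",
    "  spot %g ms/MU + %g ms slew; trimmer poly (%g, %g, %g) s [%s], off %g mm\n"),
    x$v_max, x$a_max, x$t_up, x$t_down, x$spot_slope, x$spot_slew,
    x$trimmer_poly[1], x$trimmer_poly[2], x$trimmer_poly[3],
    x$trimmer_metric, x$off_position_mm))
  invisible(x)
}

# ---- plan JSON I/O -----------------------------------------------------------

# Canonical document layout: fixed key order, full-precision floats, so that
# write -> read -> write is byte-stable.
plan_to_document <- function(plan) {
  list(
    meta = list(
      prescription_gy = plan$prescription_gy,
      normalization = list(
        d_quantile_pct = plan$normalization$d_quantile_pct,
        level_pct = plan$normalization$level_pct),
      resolution_deg = plan$resolution_deg),
    control_points = lapply(plan$control_points, function(cp) {
      list(
        gantry_deg = cp$gantry_deg,
        energy_mev = cp$energy_mev,
        configs = lapply(seq_len(nrow(cp$configs)), function(i) {
          cfg <- cp$configs[i, ]
          list(id = cfg$id, x_neg = cfg$x_neg, x_pos = cfg$x_pos,
               y_neg = cfg$y_neg, y_pos = cfg$y_pos)
        }),
        spots = lapply(seq_len(nrow(cp$spots)), function(i) {
          sp <- cp$spots[i, ]
          list(id = sp$id, x_mm = sp$x_mm, y_mm = sp$y_mm, mu = sp$mu,
               config = sp$config)
        }))
    }))
}

#' Write an arc plan to canonical JSON
#'
#' Serializes with a fixed key order and full float precision so that
#' `write_plan(read_plan(path))` reproduces the file byte for byte. Refuses to
#' serialize a structurally invalid plan.
#'
#' @param plan A valid `arc_plan`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_plan()]
#' @export
write_plan <- function(plan, path) {
  check_arc_plan(plan)
  doc <- plan_to_document(plan)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read an arc plan from JSON
#'
#' Parses the plan document schema (see the package vignette), rebuilds the
#' `arc_plan`, and validates all invariants including the monitor-unit floor.
#'
#' @param path Input path.
#' @param mu_floor Minimum deliverable MU; spots below it make the document
#'   invalid (filter with [remove_low_mu_spots()] before writing instead).
#' @return A validated `arc_plan`.
#' @export
read_plan <- function(path, mu_floor = 0.025) {
  if (!file.exists(path)) stop("plan file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("meta", "control_points"))
    if (is.null(doc[[field]]))
      stop("plan document missing required field: ", field, call. = FALSE)
  meta <- doc$meta
  for (field in c("prescription_gy", "normalization", "resolution_deg"))
    if (is.null(meta[[field]]))
      stop("plan document missing required field: meta.", field, call. = FALSE)
  cps <- lapply(doc$control_points, function(cpdoc) {
    for (field in c("gantry_deg", "energy_mev", "configs", "spots"))
      if (is.null(cpdoc[[field]]))
        stop("control point missing required field: ", field, call. = FALSE)
    configs <- do.call(rbind, lapply(cpdoc$configs, function(c1)
      data.frame(id = as.character(c1$id), x_neg = c1$x_neg, x_pos = c1$x_pos,
                 y_neg = c1$y_neg, y_pos = c1$y_pos, stringsAsFactors = FALSE)))
    spots <- do.call(rbind, lapply(cpdoc$spots, function(s1)
      data.frame(id = as.character(s1$id), x_mm = s1$x_mm, y_mm = s1$y_mm,
                 mu = s1$mu, config = as.character(s1$config),
                 stringsAsFactors = FALSE)))
    if (is.null(spots))
      stop("control point with zero spots is invalid (gantry ",
           cpdoc$gantry_deg, " deg)", call. = FALSE)
    control_point(cpdoc$gantry_deg, cpdoc$energy_mev, spots, configs)
  })
  plan <- arc_plan(cps,
                   prescription_gy = meta$prescription_gy,
                   resolution_deg = meta$resolution_deg,
                   normalization = list(
                     d_quantile_pct = meta$normalization$d_quantile_pct,
                     level_pct = meta$normalization$level_pct))
  validate_plan(plan, mu_floor = mu_floor)
  plan
}
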