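# Spot-weight reoptimization (used after every CSG stage that changes plan
# geometry) and the end-to-end Cut -> Sort -> Group pipeline.

#' Quadratic dose objectives
#'
#' A convex weighted sum of per-structure quadratic terms driving spot-weight
#' optimization: a uniform-dose term on the target, a one-sided overdose term
#' on the rind (penalizing spill above a goal), and a mean-dose penalty per
#' organ at risk, all subject to nonnegative monitor units.
#'
#' @param target_gy Uniform dose goal on the target, Gy.
#' @param target_structure,target_weight Target mask name and term weight.
#' @param rind_structure,rind_goal_gy,rind_weight One-sided overdose term:
#'   dose above `rind_goal_gy` in this structure is penalized (`NULL`
#'   structure disables the term).
#' @param oar_structures,oar_weight Mean-dose penalty per listed structure.
#' @return A list of class `dose_objectives` with a `terms` list; each term
#'   has `type` (`"uniform"`, `"overdose"`, `"underdose"`, `"mean"`),
#'   `structure`, `goal` and `weight`.
#' @export
dose_objectives <- function(target_gy = 50, target_structure = "ptv",
                            target_weight = 1,
                            rind_structure = "rind10mm",
                            rind_goal_gy = 0.5 * target_gy, rind_weight = 0.05,
                            oar_structures = "oar", oar_weight = 0.02) {
  terms <- list(list(type = "uniform", structure = target_structure,
                     goal = target_gy, weight = target_weight))
  if (!is.null(rind_structure))
    terms <- c(terms, list(list(type = "overdose", structure = rind_structure,
                                goal = rind_goal_gy, weight = rind_weight)))
  for (s in oar_structures)
    terms <- c(terms, list(list(type = "mean", structure = s, goal = 0,
                                weight = oar_weight)))
  structure(list(terms = terms), class = "dose_objectives")
}

# rows of the (scored-voxel) influence matrix belonging to each term structure
term_rows <- function(objectives, dose_state, phantom) {
  lapply(objectives$terms, function(tm) {
    mask <- phantom$masks[[tm$structure]]
    if (is.null(mask)) stop("unknown structure in objectives: ", tm$structure,
                            call. = FALSE)
    which(mask[dose_state$scored_idx])
  })
}

#' Objective value for a monitor-unit vector
#'
#' @param mu Nonnegative MU vector (one entry per influence column).
#' @param dose_state A [influence_matrix()] result.
#' @param objectives A [dose_objectives()].
#' @param phantom The phantom carrying the structure masks.
#' @return Scalar objective value.
#' @export
objective_value <- function(mu, dose_state, objectives, phantom) {
  rows <- term_rows(objectives, dose_state, phantom)
  d <- as.numeric(dose_state$influence %*% mu)
  val <- 0
  for (ti in seq_along(objectives$terms)) {
    tm <- objectives$terms[[ti]]
    ds <- d[rows[[ti]]]
    n <- length(ds)
    if (n == 0) next
    val <- val + switch(tm$type,
      uniform = tm$weight / n * sum((ds - tm$goal)^2),
      overdose = tm$weight / n * sum(pmax(ds - tm$goal, 0)^2),
      underdose = tm$weight / n * sum(pmax(tm$goal - ds, 0)^2),
      mean = tm$weight * mean(ds)^2)
  }
  val
}

objective_gradient <- function(mu, dose_state, objectives, phantom, rows) {
  A <- dose_state$influence
  d <- as.numeric(A %*% mu)
  r <- numeric(length(d))
  extra <- numeric(length(mu))
  for (ti in seq_along(objectives$terms)) {
    tm <- objectives$terms[[ti]]
    idx <- rows[[ti]]
    n <- length(idx)
    if (n == 0) next
    ds <- d[idx]
    r[idx] <- r[idx] + switch(tm$type,
      uniform = 2 * tm$weight / n * (ds - tm$goal),
      overdose = 2 * tm$weight / n * pmax(ds - tm$goal, 0),
      underdose = -2 * tm$weight / n * pmax(tm$goal - ds, 0),
      mean = rep(2 * tm$weight * mean(ds) / n, n))
  }
  as.numeric(Matrix::crossprod(A, r)) + extra
}

# ---- Cut ---------------------------------------------------------------------

#' Cut low-weight control points from a plan
#'
#' Removes every control point whose normalized weight (sum of spot monitor
#' units over the control point, normalized to the plan mean; see
#' [control_point_weights()]) falls below the threshold. The surviving spots
#' should then be reoptimized to recover the dose objectives.
#'
#' @param plan An `arc_plan` with at least one control point.
#' @param threshold Normalized-weight threshold (default 0.30).
#' @return The cut `arc_plan`; attribute `"cut_indices"` lists the removed
#'   0-based control-point indices.
#' @export
cut_control_points <- function(plan, threshold = 0.30) {
  w <- control_point_weights(plan)
  drop <- w < threshold
  if (all(drop))
    stop("threshold ", threshold, " would cut every control point; ",
         "refusing to produce an empty plan", call. = FALSE)
  removed <- vapply(plan$control_points[drop], function(cp) cp$index, integer(1))
  kept <- plan$control_points[!drop]
  for (i in seq_along(kept)) kept[[i]]$index <- i - 1L
  plan$control_points <- kept
  attr(plan, "cut_indices") <- removed
  plan
}

# ---- reoptimization ----------------------------------------------------------

#' Reoptimize spot monitor units against the dose objectives
#'
#' Minimizes the convex quadratic [dose_objectives()] over nonnegative
#' monitor units by monotone projected gradient descent with backtracking
#' (the objective never increases across iterations; convergence when the
#' relative objective change drops below `tol`). Afterwards the 0.025 MU
#' deliverability floor is re-applied: undeliverable spots are removed and
#' emptied control points dropped.
#'
#' @param plan An `arc_plan` (supplies the starting weights).
#' @param dose_state Its [influence_matrix()].
#' @param objectives A [dose_objectives()].
#' @param phantom The phantom carrying the structure masks.
#' @param mu_floor Deliverability floor, MU.
#' @param max_iter,tol Solver controls.
#' @return A list: `mu` (the unfiltered solution, one entry per input spot),
#'   `plan` and `dose_state` (filtered to deliverable spots), `objective`
#'   (per-iteration trace), `converged`.
#' @export
reoptimize_weights <- function(plan, dose_state, objectives, phantom,
                               mu_floor = 0.025, max_iter = 400, tol = 1e-6) {
  rows <- term_rows(objectives, dose_state, phantom)
  if (all(lengths(rows) == 0))
    stop("objectives reference no scored voxels", call. = FALSE)
  f <- function(x) objective_value(x, dose_state, objectives, phantom)
  x <- pmax(plan_mu(plan), 0)
  fx <- f(x)
  trace <- fx
  step <- 1 / max(Matrix::colSums(dose_state$influence^2), 1e-12)
  converged <- FALSE
  n_small <- 0L
  g <- objective_gradient(x, dose_state, objectives, phantom, rows)
  for (it in seq_len(max_iter)) {
    repeat {
      x_new <- pmax(x - step * g, 0)
      f_new <- f(x_new)
      if (f_new <= fx || max(abs(x_new - x)) == 0) break
      step <- step / 2
    }
    g_new <- objective_gradient(x_new, dose_state, objectives, phantom, rows)
    # Barzilai-Borwein step for the next iterate (backtracking above keeps
    # the objective monotone regardless)
    dx <- x_new - x
    dg <- g_new - g
    denom <- sum(dx * dg)
    step <- if (denom > 1e-300) sum(dx * dx) / denom else step * 1.25
    # BB step lengths oscillate, so demand a small relative change on three
    # consecutive iterations before declaring convergence
    small <- fx - f_new < tol * max(fx, 1e-12)
    n_small <- if (small) n_small + 1L else 0L
    x <- x_new; fx <- f_new; g <- g_new; trace <- c(trace, fx)
    if (n_small >= 3L) { converged <- TRUE; break }
  }
  plan_new <- set_plan_mu(plan, x)
  keep <- x >= mu_floor
  plan_new <- remove_low_mu_spots(plan_new, floor_mu = mu_floor)
  ds_new <- subset_dose_state(dose_state, keep)
  ds_new$spots$mu <- x[keep]
  # control points emptied by the floor disappear from the plan; renumber the
  # bookkeeping so column -> control point references stay aligned
  ds_new$spots$cp <- match(ds_new$spots$cp, sort(unique(ds_new$spots$cp)))
  list(mu = x, plan = plan_new, dose_state = ds_new, objective = trace,
       converged = converged)
}

subset_dose_state <- function(dose_state, keep) {
  dose_state$influence <- dose_state$influence[, keep, drop = FALSE]
  dose_state$spots <- dose_state$spots[keep, , drop = FALSE]
  rownames(dose_state$spots) <- NULL
  dose_state
}

# ---- pipeline ----------------------------------------------------------------

#' Run the full Cut-Sort-Group pipeline
#'
#' Stage order: Cut (drop low-weight control points, then reoptimize spot
#' weights), Sort (sliding-window energy layer sorting, regenerate the spot
#' lattices for the remapped energies, reoptimize), Group (shared trimmer
#' configurations and travel-minimizing sequencing; trimmer positions are not
#' reoptimized afterwards, the plan is only renormalized to its prescription
#' rule). Stages that cannot change the plan under the given parameters (a
#' zero cut threshold, a window smaller than the resolution, group size one
#' with no uncollimated spots) are skipped, so neutral parameters compose to
#' the identity. After every active stage the plan is renormalized.
#'
#' @param plan A baseline `arc_plan`, normalized to its prescription.
#' @param phantom A [make_phantom()] phantom.
#' @param machine A [machine_model()].
#' @param cut_threshold Normalized-weight threshold for Cut.
#' @param swels A [swels_params()]; defaults to a 25 degree window at the
#'   plan's resolution.
#' @param grouping A [grouping_params()].
#' @param objectives A [dose_objectives()]; defaults target the prescription.
#' @param model A [beam_model()].
#' @param seed Integer seed (ant colony).
#' @return A list of class `csg_result`: `stages` (named list with, per
#'   stage, the `plan`, its [plan_bdt()] `bdt` and [quality_indices()]
#'   `indices`), and `plan`, the final processed plan.
#' @export
csg_pipeline <- function(plan, phantom, machine = machine_model(),
                         cut_threshold = 0.30,
                         swels = swels_params(25, plan$resolution_deg),
                         grouping = grouping_params(),
                         objectives = NULL, model = beam_model(), seed = 1) {
  if (is.null(objectives))
    objectives <- dose_objectives(target_gy = plan$prescription_gy)

  ds <- attr(plan, "dose_state")
  if (is.null(ds)) ds <- influence_matrix(plan, phantom, model)
  attr(plan, "dose_state") <- NULL
  stage_record <- function(plan, ds) {
    list(plan = plan, bdt = plan_bdt(plan, machine),
         indices = quality_indices(compute_dose(ds), phantom,
                                   plan$prescription_gy))
  }
  stages <- list(baseline = stage_record(plan, ds))

  # Cut
  cut_plan <- cut_control_points(plan, cut_threshold)
  removed <- attr(cut_plan, "cut_indices")   # original 0-based positions
  if (length(removed)) {
    keep <- !(ds$spots$cp %in% (removed + 1L))
    ds <- subset_dose_state(ds, keep)
    ds$spots$cp <- match(ds$spots$cp, sort(unique(ds$spots$cp)))
    fit <- reoptimize_weights(cut_plan, ds, objectives, phantom)
    norm <- normalize_to_prescription(fit$plan, fit$dose_state, phantom)
    plan <- norm$plan; ds <- norm$dose_state
  }
  stages$cut <- stage_record(plan, ds)

  # Sort
  if (window_capacity(swels) >= 2 && length(plan$control_points) >= 2) {
    sorted <- sort_energies(plan, swels)
    if (!identical(attr(sorted, "swels_order"),
                   seq_along(plan$control_points))) {
      sorted <- regenerate_lattices(sorted, phantom, machine)
      ds <- influence_matrix(sorted, phantom, model)
      fit <- reoptimize_weights(sorted, ds, objectives, phantom)
      norm <- normalize_to_prescription(fit$plan, fit$dose_state, phantom)
      plan <- norm$plan; ds <- norm$dose_state
    }
  }
  stages$sort <- stage_record(plan, ds)

  # Group (no reoptimization afterwards; renormalization only)
  neutral_group <- grouping$target_mean_group_size <= 1 &&
    !plan_has_uncollimated(plan, grouping)
  if (!neutral_group) {
    plan <- group_plan(plan, grouping, machine, seed = seed)
    ds <- influence_matrix(plan, phantom, model)
    norm <- normalize_to_prescription(plan, ds, phantom)
    plan <- norm$plan; ds <- norm$dose_state
    if (any(plan_mu(plan) < 0.025)) {
      plan <- remove_low_mu_spots(plan)
      ds <- influence_matrix(plan, phantom, model)
      norm <- normalize_to_prescription(plan, ds, phantom)
      plan <- norm$plan; ds <- norm$dose_state
    }
  }
  stages$group <- stage_record(plan, ds)

  structure(list(stages = stages, plan = plan), class = "csg_result")
}

plan_has_uncollimated <- function(plan, grouping) {
  for (cp in plan$control_points)
    if (any(uncollimated_flags(cp, grouping$sigma_mm,
                               grouping$uncollimated_sigma_mult)))
      return(TRUE)
  FALSE
}

# rebuild each control point's spot lattice and per-spot configurations for
# its (possibly remapped) energy, keeping gantry angle and energy
regenerate_lattices <- function(plan, phantom, machine,
                                spot_spacing_mm = 3, expansion_mm = 6) {
  for (i in seq_along(plan$control_points)) {
    cp <- plan$control_points[[i]]
    lattice <- make_spot_lattice(phantom, cp$gantry_deg, spot_spacing_mm,
                                 expansion_mm)
    plan$control_points[[i]] <- lattice_control_point(
      lattice, cp$gantry_deg, cp$energy_mev, machine, index = cp$index)
  }
  plan
}

#' Stage-by-stage report of a pipeline run
#'
#' @param result A [csg_pipeline()] result.
#' @return `data.frame` with one row per stage: control point, spot and
#'   configuration counts, the four delivery-time components and total
#'   (seconds), and the quality indices.
#' @export
stage_report <- function(result) {
  do.call(rbind, lapply(names(result$stages), function(s) {
    st <- result$stages[[s]]
    data.frame(stage = s,
               n_cp = length(st$plan$control_points),
               n_spots = n_spots(st$plan),
               n_configs = n_configs(st$plan),
               t_gantry = st$bdt$t_gantry, t_energy = st$bdt$t_energy,
               t_trimmer = st$bdt$t_trimmer, t_spot = st$bdt$t_spot,
               total_s = st$bdt$total, total_min = st$bdt$total / 60,
               HI = st$indices$HI, CI = st$indices$CI, GI = st$indices$GI,
               D98 = st$indices$D98, D2 = st$indices$D2,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.csg_result <- function(x, ...) {
  rep <- stage_report(x)
  cat("<csg_result>\n")
  print(rep[, c("stage", "n_cp", "n_spots", "n_configs", "total_min", "HI", "D98")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
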