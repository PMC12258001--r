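# Group stage: share trimmer configurations among spots to cut trimmer travel
# time. Uncollimated spots are gathered under a single fully retracted "off"
# configuration; collimated spots are clustered into groups of a target mean
# size, each bound to the least-collimating envelope of its members, and the
# resulting configurations are sequenced with ant colony optimization to
# minimize total trimmer travel time.

#' Grouping parameters
#'
#' @param target_mean_group_size Desired mean number of collimated spots per
#'   shared configuration (>= 1). Studied up to ~16; 6-10 gives the best
#'   efficiency/quality balance.
#' @param uncollimated_sigma_mult A bar farther than this many spot sigmas
#'   from the spot centre (on its side) does not clip the spot; a spot all of
#'   whose bars pass this test is effectively uncollimated. Default 3
#'   (~99.7% of a Gaussian spot unclipped); the boundary is inclusive.
#' @param sigma_mm Nominal spot sigma at isocenter, mm.
#' @param method Collimated-group formation: `"agglomerative"` merges the pair
#'   of groups with the smallest aperture-relaxation increase until the target
#'   mean size is reached; `"greedy"` chunks spots in spatial order (fast
#'   fallback for tests).
#' @param n_ants,n_iters,alpha,beta,rho,q Ant colony settings: colony size,
#'   iterations, pheromone weight, visibility weight, evaporation rate in
#'   (0,1), and deposit scale.
#' @param seed Integer seed for the ant colony; required when grouping runs.
#' @return A list of class `grouping_params`.
#' @export
grouping_params <- function(target_mean_group_size = 8,
                            uncollimated_sigma_mult = 3,
                            sigma_mm = 3.2,
                            method = c("agglomerative", "greedy"),
                            n_ants = 20, n_iters = 200,
                            alpha = 1, beta = 2, rho = 0.1, q = 1,
                            seed = NULL) {
  method <- match.arg(method)
  stopifnot(target_mean_group_size >= 1, uncollimated_sigma_mult >= 0,
            sigma_mm > 0, n_ants >= 1, n_iters >= 1,
            alpha >= 0, beta >= 0, rho > 0, rho < 1, q > 0)
  structure(list(target_mean_group_size = target_mean_group_size,
                 uncollimated_sigma_mult = uncollimated_sigma_mult,
                 sigma_mm = sigma_mm, method = method,
                 aco = list(n_ants = n_ants, n_iters = n_iters, alpha = alpha,
                            beta = beta, rho = rho, q = q),
                 seed = seed),
            class = "grouping_params")
}

#' Is a spot effectively uncollimated by its configuration?
#'
#' True when every bar's medial edge sits at least `mult * sigma_mm` away from
#' the spot centre on its own side (inclusive boundary), so the aperture
#' passes essentially the whole Gaussian spot.
#'
#' @param spot One-row spot `data.frame` (`x_mm`, `y_mm`).
#' @param config One-row configuration `data.frame`.
#' @param sigma_mm Spot sigma, mm (> 0).
#' @param mult Clearance multiple.
#' @return Logical flag.
#' @export
is_effectively_uncollimated <- function(spot, config, sigma_mm = 3.2, mult = 3) {
  stopifnot(sigma_mm > 0)
  clearance <- mult * sigma_mm
  (spot$x_mm + config$x_neg >= clearance) &
    (config$x_pos - spot$x_mm >= clearance) &
    (spot$y_mm + config$y_neg >= clearance) &
    (config$y_pos - spot$y_mm >= clearance)
}

# vectorized over the spots of a control point (own configuration per spot)
uncollimated_flags <- function(cp, sigma_mm, mult) {
  row <- match(cp$spots$config, cp$configs$id)
  is_effectively_uncollimated(
    cp$spots,
    list(x_neg = cp$configs$x_neg[row], x_pos = cp$configs$x_pos[row],
         y_neg = cp$configs$y_neg[row], y_pos = cp$configs$y_pos[row]),
    sigma_mm = sigma_mm, mult = mult)
}

#' Least-collimating shared configuration of a group
#'
#' Per bar, the farthest-retracted member position: the envelope under which
#' no member spot is clipped more tightly than its own planned configuration
#' allowed. A group flagged uncollimated gets exactly the off configuration.
#'
#' @param configs `data.frame` of member configurations (>= 1 row).
#' @param uncollimated If `TRUE`, return the off configuration.
#' @param off_mm Off position, mm.
#' @param id Id for the shared configuration.
#' @return One-row configuration `data.frame`.
#' @export
shared_config <- function(configs, uncollimated = FALSE, off_mm = 65, id = "shared") {
  if (!is.data.frame(configs) || nrow(configs) == 0)
    stop("shared_config requires a nonempty group", call. = FALSE)
  if (uncollimated) return(trimmer_off(id = id, off_mm = off_mm))
  trimmer_config(max(configs$x_neg), max(configs$x_pos),
                 max(configs$y_neg), max(configs$y_pos), id = id)
}

# total aperture relaxation of binding each spot's own config to `env`
relaxation_cost <- function(env, own_configs) {
  sum(pmax(env$x_neg - own_configs$x_neg, 0)) +
    sum(pmax(env$x_pos - own_configs$x_pos, 0)) +
    sum(pmax(env$y_neg - own_configs$y_neg, 0)) +
    sum(pmax(env$y_pos - own_configs$y_pos, 0))
}

# ---- configuration sequencing ------------------------------------------------

config_cost_matrix <- function(configs, prev_config, machine) {
  bars <- c("x_neg", "x_pos", "y_neg", "y_pos")
  m4 <- rbind(as.matrix(prev_config[, bars]), as.matrix(configs[, bars]))
  m <- nrow(m4)
  travel <- matrix(0, m, m)
  for (b in 1:4) {
    d <- abs(outer(m4[, b], m4[, b], "-"))
    travel <- if (machine$trimmer_metric == "max_bar") pmax(travel, d)
              else travel + d
  }
  cost <- matrix(trimmer_move_time(as.numeric(travel), machine), m, m)
  cost
}

# trimmer time of visiting configs in their listed order from prev_config
path_cost <- function(configs, prev_config, machine) {
  n <- nrow(configs)
  if (n == 0) return(0)
  cost <- config_cost_matrix(configs, prev_config, machine)
  path <- c(1L, seq_len(n) + 1L)
  sum(cost[cbind(path[-length(path)], path[-1])])
}

#' Exhaustive optimal configuration order (oracle)
#'
#' Enumerates all orderings of the configurations and returns the one with the
#' smallest total trimmer repositioning time starting from `prev_config`.
#' Feasible only for small instances; used as the reference the ant colony is
#' checked against.
#'
#' @param configs `data.frame` of configurations to sequence.
#' @param prev_config Trimmer state on arrival (one-row `data.frame`).
#' @param machine A [machine_model()].
#' @return List with `order` (row permutation of `configs`) and `cost`
#'   (seconds).
#' @export
sequence_configs_exhaustive <- function(configs, prev_config, machine = machine_model()) {
  n <- nrow(configs)
  if (n > 8) stop("exhaustive sequencing is limited to 8 configurations", call. = FALSE)
  if (n <= 1) return(list(order = seq_len(n), cost = if (n == 1)
    config_cost_matrix(configs, prev_config, machine)[1, 2] else 0))
  cost <- config_cost_matrix(configs, prev_config, machine)
  perms <- permutations_of(n)
  best <- NULL; best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    path <- c(1L, p + 1L)
    cst <- sum(cost[cbind(path[-length(path)], path[-1])])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(order = best, cost = best_cost)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Ant colony configuration sequencing
#'
#' Sequences trimmer configurations to minimize total repositioning time from
#' a fixed starting state (an open travelling-salesman path). Construction
#' graph: configuration visit order; visibility is the reciprocal of the move
#' time; pheromone update follows an elitist ant system (global evaporation,
#' deposit by the best-so-far ant). Reproducible for a fixed seed.
#'
#' @inheritParams sequence_configs_exhaustive
#' @param params A [grouping_params()] providing the colony settings.
#' @param seed Integer seed (falls back to `params$seed`; required).
#' @return List with `order` and `cost` as in [sequence_configs_exhaustive()].
#' @export
sequence_configs_aco <- function(configs, prev_config, machine = machine_model(),
                                 params = grouping_params(), seed = NULL) {
  seed <- if (is.null(seed)) params$seed else seed
  if (is.null(seed)) stop("ant colony sequencing requires a seed", call. = FALSE)
  n <- nrow(configs)
  if (n <= 1) return(list(order = seq_len(n), cost = if (n == 1)
    config_cost_matrix(configs, prev_config, machine)[1, 2] else 0))
  if (n == 2) return(sequence_configs_exhaustive(configs, prev_config, machine))

  cost <- config_cost_matrix(configs, prev_config, machine)
  eps <- 1e-6
  eta <- 1 / (eps + cost)
  a <- params$aco
  with_seed(seed, {
    tau <- matrix(1, n + 1L, n + 1L)
    best <- NULL; best_cost <- Inf
    for (iter in seq_len(a$n_iters)) {
      for (ant in seq_len(a$n_ants)) {
        visited <- logical(n)
        path <- integer(n)
        cur <- 1L                     # virtual start node = prev_config
        for (step in seq_len(n)) {
          cand <- which(!visited) + 1L
          w <- tau[cur, cand]^a$alpha * eta[cur, cand]^a$beta
          if (!any(is.finite(w)) || sum(w) <= 0) w <- rep(1, length(cand))
          nxt <- if (length(cand) == 1) cand else
            cand[sample.int(length(cand), 1, prob = w)]
          path[step] <- nxt - 1L
          visited[nxt - 1L] <- TRUE
          cur <- nxt
        }
        nodes <- c(1L, path + 1L)
        cst <- sum(cost[cbind(nodes[-length(nodes)], nodes[-1])])
        if (cst < best_cost) { best_cost <- cst; best <- path }
      }
      tau <- (1 - a$rho) * tau
      nodes <- c(1L, best + 1L)
      idx <- cbind(nodes[-length(nodes)], nodes[-1])
      tau[idx] <- tau[idx] + a$q / (eps + best_cost)
    }
    list(order = best, cost = best_cost)
  })
}

# ---- grouping ----------------------------------------------------------------

#' Group the spots of one control point into shared trimmer configurations
#'
#' Spots whose own configuration already leaves them effectively uncollimated
#' are pooled under a single off configuration. The remaining (collimated)
#' spots are clustered into groups of approximately the target mean size; each
#' group is assigned its least-collimating envelope ([shared_config()]), so no
#' spot is ever clipped more tightly than its planned configuration allowed.
#' Group configurations are then sequenced to minimize trimmer travel from the
#' arriving trimmer state. Spot ids, positions and weights are untouched.
#'
#' @param cp A `control_point`.
#' @param params A [grouping_params()].
#' @param machine A [machine_model()].
#' @param prev_config Trimmer state on arrival at this control point.
#' @param seed Integer seed for the sequencer (falls back to `params$seed`).
#' @return The regrouped `control_point`; attribute `"n_collimated_groups"`
#'   holds the number of collimated groups formed.
#' @export
group_control_point <- function(cp, params = grouping_params(),
                                machine = machine_model(),
                                prev_config = trimmer_off(), seed = NULL) {
  spots <- cp$spots
  cfg_of <- cp$configs[match(spots$config, cp$configs$id), , drop = FALSE]
  uncol <- uncollimated_flags(cp, params$sigma_mm, params$uncollimated_sigma_mult)

  groups <- list()   # each: list(spot_idx, config)
  col_idx <- which(!uncol)
  if (length(col_idx)) {
    membership <- form_groups(spots[col_idx, , drop = FALSE],
                              cfg_of[col_idx, , drop = FALSE], params)
    for (gid in sort(unique(membership))) {
      members <- col_idx[membership == gid]
      env <- shared_config(cfg_of[match(members, seq_len(nrow(spots))), , drop = FALSE],
                           off_mm = machine$off_position_mm,
                           id = sprintf("g%03d", length(groups) + 1L))
      groups[[length(groups) + 1L]] <- list(spot_idx = members, config = env)
    }
  }
  n_col_groups <- length(groups)
  if (any(uncol)) {
    off <- trimmer_off(id = "off", off_mm = machine$off_position_mm)
    groups[[length(groups) + 1L]] <- list(spot_idx = which(uncol), config = off)
  }

  cfgs <- do.call(rbind, lapply(groups, `[[`, "config"))
  seqd <- if (nrow(cfgs) <= 6)
    sequence_configs_exhaustive(cfgs, prev_config, machine)
  else
    sequence_configs_aco(cfgs, prev_config, machine, params, seed = seed)

  # grouping must never cost trimmer time: when the original per-spot layout
  # is cheaper to traverse from the arriving state, keep it (the efficiency
  # plateau — larger groups stop paying)
  orig_cost <- path_cost(cp$configs, prev_config, machine)
  if (orig_cost <= seqd$cost + 1e-12) {
    out <- cp
    attr(out, "n_collimated_groups") <- length(unique(cp$spots$config[!uncol]))
    return(out)
  }

  groups <- groups[seqd$order]
  cfgs <- do.call(rbind, lapply(groups, `[[`, "config"))
  rownames(cfgs) <- NULL
  new_spots <- do.call(rbind, lapply(seq_along(groups), function(g) {
    s <- spots[groups[[g]]$spot_idx, , drop = FALSE]
    s$config <- groups[[g]]$config$id
    s
  }))
  rownames(new_spots) <- NULL
  out <- control_point(cp$gantry_deg, cp$energy_mev, new_spots, cfgs,
                       index = cp$index)
  attr(out, "n_collimated_groups") <- n_col_groups
  out
}

# cluster collimated spots; returns an integer membership vector
form_groups <- function(spots, own_configs, params) {
  n <- nrow(spots)
  target <- params$target_mean_group_size
  n_target <- max(1L, as.integer(floor(n / target)))
  if (target <= 1 || n <= 1) return(seq_len(n))

  if (params$method == "greedy") {
    ord <- order(spots$x_mm, spots$y_mm)
    membership <- integer(n)
    membership[ord] <- ((seq_len(n) - 1L) %/% ceiling(n / n_target)) + 1L
    return(membership)
  }

  # agglomerative: merge the pair whose shared envelope relaxes member
  # apertures the least, until the mean group size reaches the target.
  # A group's relaxation cost is size * sum(envelope) - sum(member bars),
  # so pair costs are O(1) from per-group envelope/size/bar-sum summaries.
  bars <- as.matrix(own_configs[, c("x_neg", "x_pos", "y_neg", "y_pos")])
  membership <- seq_len(n)
  env <- bars                      # per-group envelope (rows indexed by id)
  size <- rep(1L, n)
  barsum <- rowSums(bars)
  cost <- numeric(n)               # current relaxation cost per group id
  alive <- rep(TRUE, n)
  while (sum(alive) > n_target) {
    ids <- which(alive)
    best <- NULL; best_inc <- Inf
    for (ai in seq_along(ids)) {
      a <- ids[ai]
      for (bi in seq_len(ai - 1L)) {
        b <- ids[bi]
        env_m <- pmax(env[a, ], env[b, ])
        inc <- (size[a] + size[b]) * sum(env_m) - (barsum[a] + barsum[b]) -
          cost[a] - cost[b]
        if (inc < best_inc) { best_inc <- inc; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    env[a, ] <- pmax(env[a, ], env[b, ])
    size[a] <- size[a] + size[b]
    barsum[a] <- barsum[a] + barsum[b]
    cost[a] <- size[a] * sum(env[a, ]) - barsum[a]
    alive[b] <- FALSE
    membership[membership == b] <- a
  }
  match(membership, unique(membership))
}

#' Group an entire plan
#'
#' Applies [group_control_point()] to every control point in delivery order,
#' threading the trimmer state across control points (the state the trimmers
#' are left in at the end of one control point is the starting state of the
#' next; the fully retracted off position before the first). Dose-relevant
#' content (spot ids, positions, monitor units) is unchanged.
#'
#' @param plan An `arc_plan`.
#' @param params A [grouping_params()].
#' @param machine A [machine_model()].
#' @param seed Integer seed (falls back to `params$seed`; required).
#' @return The grouped `arc_plan`. Attributes: `"mean_group_size"` (achieved
#'   mean number of collimated spots per collimated group over the whole
#'   plan), `"n_configs_before"`, `"n_configs_after"`.
#' @export
group_plan <- function(plan, params = grouping_params(), machine = machine_model(),
                       seed = NULL) {
  seed <- if (is.null(seed)) params$seed else seed
  if (is.null(seed)) stop("group_plan requires a seed", call. = FALSE)
  n_before <- n_configs(plan)
  prev_cfg <- trimmer_off(off_mm = machine$off_position_mm)
  n_col_spots <- 0L; n_col_groups <- 0L
  for (i in seq_along(plan$control_points)) {
    cp_seed <- (as.integer(seed) %% 1000003L) * 1009L + i
    cp <- group_control_point(plan$control_points[[i]], params, machine,
                              prev_config = prev_cfg, seed = cp_seed)
    g <- attr(cp, "n_collimated_groups")
    if (g > 0) {
      off_ids <- cp$configs$id[vapply(seq_len(nrow(cp$configs)), function(j)
        is_off_config(cp$configs[j, ], off_mm = machine$off_position_mm), logical(1))]
      n_col_spots <- n_col_spots + sum(!(cp$spots$config %in% off_ids))
      n_col_groups <- n_col_groups + g
    }
    plan$control_points[[i]] <- cp
    prev_cfg <- cp$configs[nrow(cp$configs), , drop = FALSE]
  }
  attr(plan, "mean_group_size") <-
    if (n_col_groups > 0) n_col_spots / n_col_groups else NA_real_
  attr(plan, "n_configs_before") <- n_before
  attr(plan, "n_configs_after") <- n_configs(plan)
  plan
}
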