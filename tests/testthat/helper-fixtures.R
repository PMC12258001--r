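# shared fixtures, built in code and memoised for the test run

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small desk-scale phantom used by all dose tests
test_phantom <- function() {
  memo("phantom", make_phantom(phantom_spec(
    phantom_radius_mm = 33, ptv_radii_mm = c(7, 6, 8),
    oar_center_mm = c(0, 13, 0), oar_radius_mm = 5)))
}

# baseline plan on the test phantom (with its dose state attached)
test_baseline_plan <- function() {
  memo("baseline", make_baseline_plan(test_phantom(), n_positions = 13, seed = 42))
}

# a geometric plan (no dose): one control point per energy, one off-config
# spot each, gantry equally spaced from -180
geometric_plan <- function(energies, mu = rep(1, length(energies)),
                           prescription_gy = 50) {
  n <- length(energies)
  gantry <- seq(-180, 180, length.out = max(n, 2))[seq_len(n)]
  cps <- lapply(seq_len(n), function(i) {
    control_point(gantry[i], energies[i],
                  spots = data.frame(id = paste0("s", i), x_mm = 0, y_mm = 0,
                                     mu = mu[i], config = "off",
                                     stringsAsFactors = FALSE),
                  configs = trimmer_off())
  })
  arc_plan(cps, prescription_gy = prescription_gy,
           resolution_deg = if (n > 1) diff(gantry)[1] else 2.8125)
}

# a random small plan with several configs and spots per control point,
# exercising the delivery-order bookkeeping (no dose involved)
random_delivery_plan <- function(seed, n_cp = 6, max_spots = 5) {
  set.seed(seed)
  gantry <- seq(-180, 180, length.out = n_cp)
  cps <- lapply(seq_len(n_cp), function(i) {
    n_cfg <- sample(1:3, 1)
    configs <- do.call(rbind, lapply(seq_len(n_cfg), function(j)
      trimmer_config(runif(1, -5, 65), runif(1, -5, 65),
                     runif(1, -5, 65), runif(1, -5, 65),
                     id = paste0("c", i, "_", j))))
    n_sp <- sample(seq_len(max_spots), 1)
    spots <- data.frame(
      id = paste0("s", i, "_", seq_len(n_sp)),
      x_mm = runif(n_sp, -20, 20), y_mm = runif(n_sp, -20, 20),
      mu = runif(n_sp, 0.03, 30),
      config = sample(configs$id, n_sp, replace = TRUE),
      stringsAsFactors = FALSE)
    # spots delivered grouped by config in config order
    spots <- spots[order(match(spots$config, configs$id)), , drop = FALSE]
    rownames(spots) <- NULL
    configs <- configs[configs$id %in% spots$config, , drop = FALSE]
    rownames(configs) <- NULL
    control_point(gantry[i], runif(1, 70, 230), spots, configs)
  })
  arc_plan(cps, resolution_deg = diff(gantry)[1])
}

# independent event-list BDT simulator (oracle for plan_bdt): builds the
# explicit timeline of energy / trimmer / spot / gantry events
event_list_bdt <- function(plan, machine) {
  events <- data.frame(kind = character(0), t = numeric(0))
  add <- function(kind, t) rbind(events, data.frame(kind = kind, t = t))
  prev_cfg <- trimmer_off(off_mm = machine$off_position_mm)
  prev_energy <- NA
  for (cp in plan$control_points) {
    if (!is.na(prev_energy)) {
      t <- if (cp$energy_mev > prev_energy) machine$t_up
           else if (cp$energy_mev < prev_energy) machine$t_down else 0
      events <- add("energy", t)
    }
    for (j in seq_len(nrow(cp$configs))) {
      cfg <- cp$configs[j, ]
      d <- abs(c(prev_cfg$x_neg - cfg$x_neg, prev_cfg$x_pos - cfg$x_pos,
                 prev_cfg$y_neg - cfg$y_neg, prev_cfg$y_pos - cfg$y_pos))
      travel <- if (machine$trimmer_metric == "max_bar") max(d) else sum(d)
      p <- machine$trimmer_poly
      t_tr <- if (travel == 0) 0 else p[1] + p[2] * travel + p[3] * travel^2
      events <- add("trimmer", t_tr)
      for (mu in cp$spots$mu[cp$spots$config == cfg$id])
        events <- add("spot", (machine$spot_slope * mu + machine$spot_slew) / 1000)
      prev_cfg <- cfg
    }
    prev_energy <- cp$energy_mev
  }
  g <- vapply(plan$control_points, function(cp) cp$gantry_deg, numeric(1))
  for (d in abs(diff(g))) {
    v <- machine$v_max; a <- machine$a_max
    t <- if (d >= v^2 / a) d / v + v / a else 2 * sqrt(d / a)
    events <- add("gantry", t)
  }
  list(t_gantry = sum(events$t[events$kind == "gantry"]),
       t_energy = sum(events$t[events$kind == "energy"]),
       t_trimmer = sum(events$t[events$kind == "trimmer"]),
       t_spot = sum(events$t[events$kind == "spot"]),
       total = sum(events$t))
}

# random trimmer configurations for sequencing tests
random_configs <- function(seed, n) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i)
    trimmer_config(runif(1, 0, 65), runif(1, 0, 65),
                   runif(1, 0, 65), runif(1, 0, 65), id = paste0("r", i))))
}
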