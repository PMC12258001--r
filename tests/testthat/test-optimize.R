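test_that("cutting removes exactly the below-threshold control points", {
  uniform <- geometric_plan(c(150, 140, 130), mu = c(2, 2, 2))
  expect_equal(length(cut_control_points(uniform, 0.3)$control_points), 3)

  plan <- geometric_plan(c(150, 140, 130, 120), mu = c(1, 1, 1, 0.2))
  cut <- cut_control_points(plan, 0.30)       # weights 1.25,1.25,1.25,0.25
  expect_equal(length(cut$control_points), 3)
  expect_equal(attr(cut, "cut_indices"), 3L)
  expect_equal(plan_energies(cut), c(150, 140, 130))

  expect_equal(cut_control_points(plan, 0), plan, ignore_attr = TRUE)
  expect_error(cut_control_points(uniform, 1.5), "every control point")

  # oracle: independent filter over random plans
  for (seed in 1:5) {
    p <- random_delivery_plan(seed, n_cp = 8)
    w <- vapply(p$control_points, function(cp) sum(cp$spots$mu), numeric(1))
    w <- w / mean(w)
    got <- cut_control_points(p, 0.8)
    expect_equal(length(got$control_points), sum(w >= 0.8))
    expect_equal(plan_energies(got), plan_energies(p)[w >= 0.8])
  }
})

test_that("a separable quadratic recovers the exact per-spot solution", {
  # one spot per voxel, unit-diagonal influence, pure target term
  ph <- test_phantom()
  n <- 6
  ptv_rows <- which(ph$masks$ptv[ph$scored_idx])[1:n]
  infl <- Matrix::sparseMatrix(i = ptv_rows, j = 1:n, x = c(2, 1, 4, 1, 2, 1),
                               dims = c(length(ph$scored_idx), n))
  ds <- structure(list(influence = infl,
                       spots = data.frame(cp = 1, id = paste0("s", 1:n), mu = 1),
                       scored_idx = ph$scored_idx, n_grid = prod(ph$dim),
                       voxel_cm3 = 0.027, prescription_gy = 50),
                  class = "dose_state")
  # target restricted to those voxels: objectives over a bespoke mask
  ph2 <- ph
  ph2$masks$ptv <- rep(FALSE, prod(ph$dim))
  ph2$masks$ptv[ph$scored_idx[ptv_rows]] <- TRUE
  obj <- dose_objectives(target_gy = 40, rind_structure = NULL,
                         oar_structures = character(0))
  start <- geometric_plan(rep(100, n), mu = rep(1, n))
  fit <- reoptimize_weights(start, ds, obj, ph2, tol = 1e-12, max_iter = 2000)
  expect_equal(fit$mu, 40 / c(2, 1, 4, 1, 2, 1), tolerance = 1e-6)
  expect_true(all(diff(fit$objective) <= 1e-12))
})

test_that("the reoptimizer matches a box-constrained quasi-Newton oracle", {
  ph <- test_phantom()
  plan <- test_baseline_plan()
  ds <- attr(plan, "dose_state")
  attr(plan, "dose_state") <- NULL
  # truncate to a <= 20-spot instance
  n <- 18
  keep <- rep(FALSE, n_spots(plan)); keep[seq_len(n)] <- TRUE
  ds_small <- csgarc:::subset_dose_state(ds, keep)
  obj <- dose_objectives(target_gy = 50)
  small_start <- geometric_plan(rep(100, n), mu = rep(1, n))
  fit <- reoptimize_weights(small_start, ds_small, obj, ph,
                            tol = 1e-10, max_iter = 3000)
  oracle <- stats::optim(
    rep(1, n),
    fn = function(x) objective_value(x, ds_small, obj, ph),
    method = "L-BFGS-B", lower = rep(0, n),
    control = list(maxit = 500, factr = 1e4))
  f_hat <- objective_value(fit$mu, ds_small, obj, ph)
  expect_equal(f_hat, oracle$value, tolerance = 1e-4)
  # monotone descent trace
  expect_true(all(diff(fit$objective) <= 1e-12))
})

test_that("neutral parameters compose to the identity pipeline", {
  ph <- test_phantom()
  # plan in which every spot is collimated (no effectively uncollimated spot)
  gantry <- seq(-180, 180, length.out = 4)
  cps <- lapply(1:4, function(i) {
    configs <- rbind(trimmer_config(5, 5, 5, 5, id = "tight1"),
                     trimmer_config(6, 4, 6, 4, id = "tight2"))
    spots <- data.frame(id = paste0("s", i, "_", 1:2),
                        x_mm = c(0, 1), y_mm = c(0, -1), mu = c(4, 5),
                        config = c("tight1", "tight2"), stringsAsFactors = FALSE)
    control_point(gantry[i], 74 - i, spots, configs)
  })
  plan <- arc_plan(cps, resolution_deg = 120)
  res <- csg_pipeline(plan, ph, cut_threshold = 0,
                      swels = swels_params(1, plan$resolution_deg),
                      grouping = grouping_params(target_mean_group_size = 1),
                      seed = 3)
  expect_equal(res$plan, plan, ignore_attr = TRUE)
  expect_equal(res$stages$group$bdt$total, res$stages$baseline$bdt$total)
})

test_that("the pipeline reduces delivery time while holding coverage", {
  ph <- test_phantom()
  plan <- test_baseline_plan()
  res <- csg_pipeline(plan, ph, cut_threshold = 0.3,
                      swels = swels_params(2 * plan$resolution_deg,
                                           plan$resolution_deg),
                      grouping = grouping_params(target_mean_group_size = 6,
                                                 n_ants = 8, n_iters = 30),
                      seed = 42)
  rep <- stage_report(res)
  expect_lt(rep$total_s[rep$stage == "group"], rep$total_s[rep$stage == "baseline"])
  expect_gte(rep$D98[rep$stage == "group"],
             0.98 * rep$D98[rep$stage == "baseline"])
  # component conservation at every stage
  for (st in res$stages)
    expect_equal(st$bdt$total,
                 st$bdt$t_gantry + st$bdt$t_energy + st$bdt$t_trimmer +
                   st$bdt$t_spot)
})
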