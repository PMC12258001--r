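machine <- machine_model()

test_that("effective-uncollimation tests all four bars with an inclusive boundary", {
  spot <- data.frame(x_mm = 0, y_mm = 0)
  expect_true(is_effectively_uncollimated(spot, trimmer_off(), 3.2, 3))
  # one bar with its edge on the spot axis clips half the spot
  edge_on <- trimmer_config(65, 0, 65, 65)
  expect_false(is_effectively_uncollimated(spot, edge_on, 3.2, 3))
  # boundary exactly at mult * sigma counts as uncollimated
  at_bound <- trimmer_config(65, 3 * 3.2, 65, 65)
  expect_true(is_effectively_uncollimated(spot, at_bound, 3.2, 3))
  expect_false(is_effectively_uncollimated(spot, trimmer_config(65, 3 * 3.2 - 0.01, 65, 65),
                                           3.2, 3))
})

test_that("shared configurations are the least-collimating envelope", {
  a <- trimmer_config(10, 5, 12, 20, id = "a")
  b <- trimmer_config(8, 8, 15, 18, id = "b")
  expect_equal(shared_config(a)$x_pos, 5)          # singleton unchanged
  env <- shared_config(rbind(a, b))
  expect_equal(env$x_pos, 8)
  expect_equal(env$x_neg, 10)
  expect_equal(env$y_neg, 15)
  expect_equal(env$y_pos, 20)
  off <- shared_config(rbind(a, b), uncollimated = TRUE)
  expect_true(is_off_config(off))
  expect_error(shared_config(a[0, ]), "nonempty")
})

test_that("ant colony sequencing attains the exhaustive optimum on small instances", {
  prev <- trimmer_off()
  for (seed in 1:10) {
    n <- sample(3:6, 1)
    cfgs <- random_configs(seed, n)
    exact <- sequence_configs_exhaustive(cfgs, prev, machine)
    aco <- sequence_configs_aco(cfgs, prev, machine,
                                grouping_params(n_ants = 20, n_iters = 100),
                                seed = seed)
    expect_equal(aco$cost, exact$cost, tolerance = 1e-12)
  }
  # reproducibility under a fixed seed
  cfgs <- random_configs(77, 8)
  r1 <- sequence_configs_aco(cfgs, prev, machine, seed = 5)
  r2 <- sequence_configs_aco(cfgs, prev, machine, seed = 5)
  expect_identical(r1, r2)
  expect_error(sequence_configs_aco(cfgs, prev, machine), "seed")
})

test_that("group size one keeps collimated configs and pools uncollimated spots", {
  spots <- data.frame(
    id = paste0("s", 1:4),
    x_mm = c(10, -10, 0, 2), y_mm = c(0, 0, 0, 1),
    mu = c(1, 2, 3, 4),
    config = c("t1", "t2", "off", "off"), stringsAsFactors = FALSE)
  configs <- rbind(trimmer_config(65, 10, 65, 65, id = "t1"),
                   trimmer_config(10, 65, 65, 65, id = "t2"),
                   trimmer_off())
  cp <- control_point(0, 120, spots, configs)
  out <- group_control_point(cp, grouping_params(target_mean_group_size = 1),
                             machine, seed = 1)
  expect_equal(attr(out, "n_collimated_groups"), 2)
  expect_equal(nrow(out$configs), 3)
  # spot payload untouched (order may change)
  expect_setequal(out$spots$id, spots$id)
  expect_equal(out$spots$mu[match(spots$id, out$spots$id)], spots$mu)
  # the two uncollimated spots share one off config
  off_id <- out$configs$id[vapply(seq_len(nrow(out$configs)),
                                  function(i) is_off_config(out$configs[i, ]),
                                  logical(1))]
  expect_length(off_id, 1)
  expect_setequal(out$spots$id[out$spots$config == off_id], c("s3", "s4"))
})

test_that("grouping approaches the target mean size and reduces trimmer time", {
  plan <- test_baseline_plan()
  attr(plan, "dose_state") <- NULL
  before <- plan_bdt(plan, machine)
  params <- grouping_params(target_mean_group_size = 6, n_ants = 8, n_iters = 30)
  grouped <- group_plan(plan, params, machine, seed = 4)
  after <- plan_bdt(grouped, machine)
  expect_lt(after$t_trimmer, before$t_trimmer)
  expect_lte(attr(grouped, "n_configs_after"), attr(grouped, "n_configs_before"))
  expect_equal(attr(grouped, "mean_group_size"), 6, tolerance = 0.2)
  # dose-relevant content unchanged
  expect_equal(sort(plan_mu(grouped)), sort(plan_mu(plan)))
  expect_equal(n_spots(grouped), n_spots(plan))
  # no spot collimated tighter than its baseline configuration
  for (i in seq_along(plan$control_points)) {
    cp0 <- plan$control_points[[i]]; cp1 <- grouped$control_points[[i]]
    own <- cp0$configs[match(cp0$spots$config, cp0$configs$id), ]
    new <- cp1$configs[match(cp1$spots$config[match(cp0$spots$id, cp1$spots$id)],
                             cp1$configs$id), ]
    expect_true(all(new$x_neg >= own$x_neg - 1e-9))
    expect_true(all(new$x_pos >= own$x_pos - 1e-9))
    expect_true(all(new$y_neg >= own$y_neg - 1e-9))
    expect_true(all(new$y_pos >= own$y_pos - 1e-9))
  }
})

test_that("a plan of only uncollimated spots collapses to one off config per control point", {
  plan <- geometric_plan(c(150, 140, 130), mu = c(5, 5, 5))
  grouped <- group_plan(plan, grouping_params(target_mean_group_size = 4),
                        machine_model(), seed = 2)
  for (cp in grouped$control_points) {
    expect_equal(nrow(cp$configs), 1)
    expect_true(is_off_config(cp$configs[1, ]))
  }
  expect_equal(plan_bdt(grouped, machine)$t_trimmer, 0)
})

test_that("grouping with a fixed seed is reproducible", {
  plan <- test_baseline_plan()
  attr(plan, "dose_state") <- NULL
  params <- grouping_params(target_mean_group_size = 5, n_ants = 6, n_iters = 20)
  g1 <- group_plan(plan, params, machine, seed = 9)
  g2 <- group_plan(plan, params, machine, seed = 9)
  expect_identical(g1, g2)
})
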