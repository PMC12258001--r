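test_that("trimmer configurations enforce the travel bounds and off state", {
  cfg <- trimmer_config(0, 12.5, -5, 65, id = "a")
  expect_equal(cfg$x_pos, 12.5)
  expect_error(trimmer_config(-30, 0, 0, 0), "\\[-20, 65\\]")
  expect_error(trimmer_config(0, 70, 0, 0), "\\[-20, 65\\]")
  off <- trimmer_off()
  expect_true(is_off_config(off))
  expect_false(is_off_config(cfg))
})

test_that("plan construction rejects invariant violations", {
  spots <- data.frame(id = "s1", x_mm = 0, y_mm = 0, mu = 1, config = "off",
                      stringsAsFactors = FALSE)
  cp <- control_point(-180, 100, spots, trimmer_off())
  # zero spots
  expect_error(control_point(0, 100, spots[0, ], trimmer_off()),
               "zero spots")
  # dangling config reference
  bad <- spots; bad$config <- "missing"
  expect_error(control_point(0, 100, bad, trimmer_off()), "resolve")
  # more than one energy / nonpositive energy
  expect_error(control_point(0, -5, spots, trimmer_off()), "positive energy")
  # non-monotone gantry
  cp2 <- control_point(-90, 100, spots, trimmer_off())
  cp3 <- control_point(-120, 100, spots, trimmer_off())
  expect_error(arc_plan(list(cp, cp2, cp3)), "monotone")
  expect_s3_class(arc_plan(list(cp, cp2)), "arc_plan")
})

test_that("plan JSON round-trips byte for byte and validates on read", {
  plan <- random_delivery_plan(11)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_plan(plan, f1)
  back <- read_plan(f1, mu_floor = 0)
  write_plan(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(plan_mu(back), plan_mu(plan))
  expect_equal(gantry_angles(back), gantry_angles(plan))
  # off configs serialize with all bars at 65
  doc <- jsonlite::fromJSON(f1, simplifyVector = FALSE)
  expect_true(!is.null(doc$meta$prescription_gy))
})

test_that("a full synthetic arc survives write-read-write unchanged", {
  plan <- test_baseline_plan()
  attr(plan, "dose_state") <- NULL
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_plan(plan, f1)
  write_plan(read_plan(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reading rejects undeliverable weights and malformed documents", {
  plan <- geometric_plan(c(120, 100))
  plan$control_points[[1]]$spots$mu <- 0.01
  f <- tempfile(fileext = ".json")
  write_plan(plan, f)                       # structurally valid, writes fine
  expect_error(read_plan(f), "below 0.025 MU")
  writeLines('{"control_points": []}', f)
  expect_error(read_plan(f), "meta")
  writeLines('{"meta": {"prescription_gy": 50, "normalization":
    {"d_quantile_pct": 95, "level_pct": 100}},
    "control_points": []}', f)
  expect_error(read_plan(f), "resolution_deg")
})

test_that("write_plan refuses a structurally invalid plan", {
  plan <- geometric_plan(c(120, 100))
  plan$control_points[[2]]$spots <- plan$control_points[[2]]$spots[0, ]
  expect_error(write_plan(plan, tempfile()), "zero spots")
})

test_that("low-MU filtering matches an independent scan and is idempotent", {
  plan <- geometric_plan(c(150, 140, 130, 120), mu = c(1, 0.5, 2, 1))
  expect_equal(length(remove_low_mu_spots(plan)$control_points), 4)

  # control point whose spots are all below the floor disappears
  plan$control_points[[2]]$spots$mu <- 0.01
  cut <- remove_low_mu_spots(plan)
  expect_equal(length(cut$control_points), 3)
  expect_equal(plan_energies(cut), c(150, 130, 120))

  # random plans with injected low weights: survivors equal a brute filter
  for (seed in 1:5) {
    p <- random_delivery_plan(seed, n_cp = 8)
    set.seed(seed + 100)
    p <- set_plan_mu(p, ifelse(runif(n_spots(p)) < 0.3, 0.001, plan_mu(p)))
    filtered <- remove_low_mu_spots(p)
    expected_spots <- sum(plan_mu(p) >= 0.025)
    expected_cps <- sum(vapply(p$control_points,
                               function(cp) any(cp$spots$mu >= 0.025),
                               logical(1)))
    expect_equal(n_spots(filtered), expected_spots)
    expect_equal(length(filtered$control_points), expected_cps)
    # configs no surviving spot references are gone
    for (cp in filtered$control_points)
      expect_setequal(cp$configs$id, unique(cp$spots$config))
    # idempotent
    expect_equal(remove_low_mu_spots(filtered), filtered)
  }
})

test_that("control-point weights normalize to unit mean", {
  uniform <- geometric_plan(c(150, 140, 130), mu = c(2, 2, 2))
  expect_equal(control_point_weights(uniform), c(1, 1, 1))

  plan <- geometric_plan(c(150, 140, 130, 120), mu = c(1, 1, 1, 0.2))
  expect_equal(control_point_weights(plan), c(1.25, 1.25, 1.25, 0.25))

  for (seed in 1:5) {
    p <- random_delivery_plan(seed)
    expect_equal(mean(control_point_weights(p)), 1)
  }
  empty <- remove_low_mu_spots(geometric_plan(100, mu = 0.001))
  expect_error(control_point_weights(empty), "empty")
})

test_that("machine model reads from YAML and JSON with defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines("v_max: 5\ntrimmer_poly: [0.2, 0.01, 0]", f)
  m <- read_machine_model(f)
  expect_equal(m$v_max, 5)
  expect_equal(m$trimmer_poly, c(0.2, 0.01, 0))
  expect_equal(m$t_up, 6)        # default retained
  writeLines("bogus_field: 1", f)
  expect_error(read_machine_model(f), "bogus_field")
  expect_error(read_machine_model("/nonexistent/machine.yaml"), "not found")
})
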