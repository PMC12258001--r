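test_that("energy-range mapping is the stated power law and monotone", {
  expect_equal(energy_to_range(100), 0.0022 * 100^1.77)
  expect_equal(round(energy_to_range(100), 2), 7.63)
  es <- seq(70, 230, by = 1)
  expect_true(all(diff(energy_to_range(es)) > 0))
  expect_equal(range_to_energy(energy_to_range(150)), 150)
  expect_error(energy_to_range(0), "positive")
})

test_that("aperture transmission matches brute-force 2D quadrature", {
  quadrature <- function(spot, cfg, sigma) {
    hx <- seq(-cfg$x_neg, cfg$x_pos, length.out = 4001)
    hy <- seq(-cfg$y_neg, cfg$y_pos, length.out = 4001)
    gx <- stats::dnorm(hx, spot$x_mm, sigma)
    gy <- stats::dnorm(hy, spot$y_mm, sigma)
    # trapezoid rule per axis; the 2D integral separates
    ix <- sum((gx[-1] + gx[-length(gx)]) / 2 * diff(hx))
    iy <- sum((gy[-1] + gy[-length(gy)]) / 2 * diff(hy))
    ix * iy
  }
  set.seed(31)
  for (trial in 1:10) {
    spot <- data.frame(x_mm = runif(1, -10, 10), y_mm = runif(1, -10, 10))
    cfg <- trimmer_config(runif(1, 5, 65), runif(1, 5, 65),
                          runif(1, 5, 65), runif(1, 5, 65))
    sigma <- runif(1, 2, 6)
    expect_equal(aperture_transmission(spot, cfg, sigma),
                 quadrature(spot, cfg, sigma), tolerance = 1e-6)
  }
  # a bar edge exactly on the spot axis halves the lateral integral
  spot <- data.frame(x_mm = 4, y_mm = 0)
  half <- aperture_transmission(spot, trimmer_config(65, 4, 65, 65), 3.2)
  open <- aperture_transmission(spot, trimmer_off(), 3.2)
  expect_equal(half / open, 0.5, tolerance = 1e-4)
})

test_that("an off configuration reproduces the open beam and collimation only removes dose", {
  ph <- test_phantom()
  cp <- control_point(0, 70,
                      spots = data.frame(id = "s", x_mm = 2, y_mm = 1, mu = 1,
                                         config = "off", stringsAsFactors = FALSE),
                      configs = trimmer_off())
  spot <- cp$spots[1, ]
  open <- beamlet_dose(spot, cp, ph, config = trimmer_config(65, 65, 65, 65))
  wide <- beamlet_dose(spot, cp, ph, config = trimmer_config(64, 64, 64, 64))
  expect_equal(open, wide, tolerance = 1e-3)

  # moving any bar toward the axis never increases dose anywhere
  tight1 <- beamlet_dose(spot, cp, ph, config = trimmer_config(65, 6, 65, 65))
  tight2 <- beamlet_dose(spot, cp, ph, config = trimmer_config(65, 2, 65, 65))
  expect_true(all(tight1 <= open + 1e-12))
  expect_true(all(tight2 <= tight1 + 1e-12))
  expect_lt(sum(tight2), sum(tight1))
})

test_that("influence is linear and superposes", {
  ph <- test_phantom()
  plan <- geometric_plan(c(75, 72), mu = c(2, 3))
  ds <- influence_matrix(plan, ph)
  expect_true(all(ds$influence@x >= 0))
  d1 <- compute_dose(ds, c(1, 0))
  d2 <- compute_dose(ds, c(0, 1))
  expect_equal(compute_dose(ds, c(2, 3)), 2 * d1 + 3 * d2)
  expect_equal(compute_dose(ds), 2 * d1 + 3 * d2)
})

test_that("DVH and dose quantiles match sorting-based oracles", {
  mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  uniform <- rep(50, 5)
  curve <- dvh(uniform, mask)
  expect_equal(curve$volume[curve$dose <= 50], rep(1, sum(curve$dose <= 50)))
  expect_equal(curve$volume[curve$dose > 50], rep(0, sum(curve$dose > 50)))

  two <- dvh(c(40, 60), c(TRUE, TRUE), bins = c(0, 39, 41, 59, 61))
  expect_equal(two$volume, c(1, 1, 0.5, 0.5, 0))

  expect_equal(dose_at_volume(uniform, 2), 50)
  expect_equal(dose_at_volume(uniform, 98), 50)
  expect_equal(volume_at_dose(rep(1, 10), 0), 10 * 0.027)

  set.seed(8)
  for (trial in 1:5) {
    d <- runif(500, 0, 60)
    ds_sorted <- sort(d, decreasing = TRUE)
    for (q in c(2, 50, 95, 98))
      expect_equal(dose_at_volume(d, q), ds_sorted[ceiling(q / 100 * 500)])
    lvl <- runif(1, 10, 50)
    expect_equal(volume_at_dose(d, lvl), sum(d >= lvl) * 0.027)
  }
  expect_error(dose_at_volume(uniform, 0), "\\(0, 100\\]")
  expect_error(dvh(uniform, rep(FALSE, 5)), "empty")
})

test_that("quality indices reproduce hand-computed values", {
  ph <- test_phantom()
  ptv <- ph$masks$ptv

  # ideal plan: exactly the prescription on the PTV, nothing elsewhere
  dose <- numeric(prod(ph$dim))
  dose[ptv] <- 50
  qi <- quality_indices(dose, ph, 50)
  expect_equal(qi$HI, 0)
  expect_equal(qi$CI, 1)
  expect_equal(qi$GI, 1)

  # V50 = 2 * V100 gives GI = 2
  dose2 <- numeric(prod(ph$dim))
  dose2[ptv] <- 50
  rind_idx <- which(ph$masks$rind10mm)[seq_len(sum(ptv))]
  dose2[rind_idx] <- 30
  qi2 <- quality_indices(dose2, ph, 50)
  expect_equal(qi2$GI, 2)

  # no voxel at prescription: GI and CI undefined
  qi3 <- quality_indices(dose2 * 0.5, ph, 50)
  expect_true(is.na(qi3$GI) && is.na(qi3$CI))

  # quantile ordering invariant
  plan <- test_baseline_plan()
  d <- compute_dose(attr(plan, "dose_state"))
  qi4 <- quality_indices(d, ph, 50)
  expect_gte(qi4$D2, qi4$D50)
  expect_gte(qi4$D50, qi4$D98)
  expect_gte(qi4$GI, 1)
  expect_true(qi4$CI >= 0 && qi4$CI <= 1)
})

test_that("the homogeneity formula reproduces printed-style inputs", {
  # HI = (D2 - D98) / Dp on quantile values directly
  expect_equal(round((53.8 - 49.5) / 50, 2), 0.09)
  ph <- test_phantom()
  dose <- numeric(prod(ph$dim))
  n_ptv <- sum(ph$masks$ptv)
  # synthetic PTV dose field whose 2% / 98% quantiles are 53.8 and 49.5
  n_hot <- ceiling(0.03 * n_ptv)
  dose[ph$masks$ptv] <- c(rep(53.8, n_hot), rep(49.5, n_ptv - n_hot))
  qi <- quality_indices(dose, ph, 50)
  expect_equal(qi$D2, 53.8)
  expect_equal(qi$D98, 49.5)
  expect_equal(round(qi$HI, 2), 0.09)
})

test_that("prescription normalization is an exact fixed point", {
  ph <- test_phantom()
  plan <- test_baseline_plan()
  ds <- attr(plan, "dose_state")
  attr(plan, "dose_state") <- NULL
  norm <- normalize_to_prescription(plan, ds, ph)
  expect_equal(norm$factor, 1, tolerance = 1e-9)   # already normalized

  halved <- set_plan_mu(plan, plan_mu(plan) / 2)
  ds_h <- ds; ds_h$spots$mu <- ds$spots$mu / 2
  norm2 <- normalize_to_prescription(halved, ds_h, ph)
  expect_equal(norm2$factor, 2, tolerance = 1e-9)
  expect_equal(dose_at_volume(norm2$dose, 95, mask = ph$masks$ptv), 50,
               tolerance = 1e-6)
})

test_that("collimation lowers the rind dose relative to the same plan uncollimated", {
  ph <- test_phantom()
  plan <- test_baseline_plan()
  ds <- attr(plan, "dose_state")
  attr(plan, "dose_state") <- NULL
  uncol <- plan
  for (i in seq_along(uncol$control_points)) {
    cp <- uncol$control_points[[i]]
    cp$configs <- trimmer_off()
    cp$spots$config <- "off"
    uncol$control_points[[i]] <- cp
  }
  d_col <- compute_dose(ds)
  d_open <- compute_dose(influence_matrix(uncol, ph))
  expect_lt(mean(d_col[ph$masks$rind10mm]), mean(d_open[ph$masks$rind10mm]))
})
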