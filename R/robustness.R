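# Delivery-uncertainty robustness analysis: sample perturbation scenarios,
# recompute the dose under each, and summarize per-structure dose-index
# deviations from the nominal plan. Patient setup error is deliberately
# excluded; only uncertainties inherent to the delivery system are modeled.

#' Delivery-uncertainty model
#'
#' Magnitudes of the sampled perturbations: proton range (its two-sided 95th
#' percentile, as a percent), per-spot lateral placement (Gaussian sigma,
#' mm), per-control-point gantry angle (uniform half-width, degrees), a
#' systematic collimator-mount alignment shift per scenario (Gaussian sigma
#' in the IEC X and Y directions, mm), and per-bar trimmer positioning noise
#' (Gaussian sigma, mm). Defaults follow mechanical characterization of the
#' dynamic collimation system and standard clinical range/spot assumptions.
#'
#' @param range_pct_95 Range uncertainty, percent at the 95th percentile
#'   (3.5). With `range_mode = "sampled"` the per-scenario scale factor is
#'   Gaussian with sigma `range_pct_95 / 1.96` percent; with `"systematic"`
#'   scenarios alternate between the fixed +/- scale pair.
#' @param spot_sigma_mm Spot placement sigma, mm (0.5), i.i.d. per spot.
#' @param gantry_halfwidth_deg Gantry offset half-width, degrees (1.0),
#'   uniform per control point.
#' @param dcs_align_sigma_x_mm,dcs_align_sigma_y_mm Collimator alignment
#'   shift sigmas, mm (0.05 X, 0.1 Y), one systematic draw per scenario.
#' @param trimmer_sigma_mm Trimmer bar position sigma, mm (0.3), i.i.d. per
#'   bar per configuration.
#' @param n_samples Number of recalculated scenarios (100).
#' @param seed Integer seed.
#' @param range_mode `"sampled"` or `"systematic"`.
#' @return A list of class `uncertainty_model`.
#' @export
uncertainty_model <- function(range_pct_95 = 3.5, spot_sigma_mm = 0.5,
                              gantry_halfwidth_deg = 1.0,
                              dcs_align_sigma_x_mm = 0.05,
                              dcs_align_sigma_y_mm = 0.1,
                              trimmer_sigma_mm = 0.3,
                              n_samples = 100, seed = 1,
                              range_mode = c("sampled", "systematic")) {
  range_mode <- match.arg(range_mode)
  stopifnot(range_pct_95 >= 0, spot_sigma_mm >= 0, gantry_halfwidth_deg >= 0,
            dcs_align_sigma_x_mm >= 0, dcs_align_sigma_y_mm >= 0,
            trimmer_sigma_mm >= 0, n_samples >= 1)
  structure(list(range_pct_95 = range_pct_95, spot_sigma_mm = spot_sigma_mm,
                 gantry_halfwidth_deg = gantry_halfwidth_deg,
                 dcs_align_sigma_x_mm = dcs_align_sigma_x_mm,
                 dcs_align_sigma_y_mm = dcs_align_sigma_y_mm,
                 trimmer_sigma_mm = trimmer_sigma_mm,
                 n_samples = n_samples, seed = seed, range_mode = range_mode),
            class = "uncertainty_model")
}

#' Sample one delivery-uncertainty scenario
#'
#' Fully determined by the model's seed and the scenario index; independent
#' of the order in which scenarios are drawn.
#'
#' @param unc An [uncertainty_model()].
#' @param index 1-based scenario index, `<= n_samples`.
#' @param plan The plan the scenario will perturb (fixes the number of spots,
#'   control points and configurations).
#' @return A list of class `scenario`: `range_scale`, `spot_dx`/`spot_dy`
#'   (per spot, plan delivery order), `gantry_offset_deg` (per control
#'   point), `dcs_dx`/`dcs_dy` (mm), `bar_noise` (per control point, an
#'   `n_configs x 4` matrix of bar offsets, mm).
#' @export
sample_scenario <- function(unc, index, plan) {
  if (index < 1 || index > unc$n_samples)
    stop("scenario index out of range", call. = FALSE)
  n_sp <- n_spots(plan)
  n_cp <- length(plan$control_points)
  with_seed((as.integer(unc$seed) %% 1000003L) * 2011L + index, {
    range_scale <- if (unc$range_mode == "systematic") {
      1 + (if (index %% 2 == 0) 1 else -1) * unc$range_pct_95 / 100
    } else {
      1 + stats::rnorm(1, 0, unc$range_pct_95 / 1.96 / 100)
    }
    structure(list(
      range_scale = range_scale,
      spot_dx = stats::rnorm(n_sp, 0, unc$spot_sigma_mm),
      spot_dy = stats::rnorm(n_sp, 0, unc$spot_sigma_mm),
      gantry_offset_deg = stats::runif(n_cp, -unc$gantry_halfwidth_deg,
                                       unc$gantry_halfwidth_deg),
      dcs_dx = stats::rnorm(1, 0, unc$dcs_align_sigma_x_mm),
      dcs_dy = stats::rnorm(1, 0, unc$dcs_align_sigma_y_mm),
      bar_noise = lapply(plan$control_points, function(cp)
        matrix(stats::rnorm(nrow(cp$configs) * 4, 0, unc$trimmer_sigma_mm),
               ncol = 4))),
      class = "scenario")
  })
}

identity_scenario <- function(plan) {
  structure(list(
    range_scale = 1,
    spot_dx = numeric(n_spots(plan)), spot_dy = numeric(n_spots(plan)),
    gantry_offset_deg = numeric(length(plan$control_points)),
    dcs_dx = 0, dcs_dy = 0,
    bar_noise = lapply(plan$control_points, function(cp)
      matrix(0, nrow(cp$configs), 4))),
    class = "scenario")
}

#' Recompute the dose under a perturbation scenario
#'
#' Rebuilds the influence with ranges scaled, spots and trimmer edges
#' shifted, and gantry angles offset, then applies the plan's monitor units.
#' The identity (all-zero) scenario reproduces the nominal dose exactly.
#'
#' @param plan An `arc_plan`.
#' @param phantom A [make_phantom()] phantom.
#' @param scenario A [sample_scenario()] result.
#' @param model A [beam_model()].
#' @return Full-grid dose vector, Gy.
#' @export
apply_scenario <- function(plan, phantom, scenario, model = beam_model()) {
  ds <- influence_matrix(plan, phantom, model, scenario = scenario)
  compute_dose(ds)
}

#' Robustness analysis of a plan
#'
#' Draws `n_samples` scenarios, recomputes the dose under each, and compares
#' per-structure dose indices (`D2`, `D50`, `D98`, `Dmean`) to the nominal
#' dose: the mean of (sample - nominal) and the standard deviation over
#' scenarios, plus DVH band curves per structure for plotting.
#'
#' @param plan An `arc_plan`.
#' @param phantom A [make_phantom()] phantom.
#' @param unc An [uncertainty_model()].
#' @param model A [beam_model()].
#' @param structures Structure mask names to track.
#' @param band_probs Quantiles of the per-bin volume fractions in the DVH
#'   bands.
#' @return A list of class `robustness_result`: `table` (`data.frame` with
#'   `structure`, `index`, `nominal`, `mean_diff`, `sd`), `bands` (per
#'   structure, a `data.frame` of dose bins and volume-fraction quantiles
#'   across scenarios), `n_samples`.
#' @export
robustness_analysis <- function(plan, phantom, unc, model = beam_model(),
                                structures = c("ctv", "ptv", "rind10mm", "oar"),
                                band_probs = c(0, 0.05, 0.5, 0.95, 1)) {
  structures <- intersect(structures, names(phantom$masks))
  nominal <- compute_dose(influence_matrix(plan, phantom, model))
  idx_fun <- function(dose, s) {
    d <- dose[as.logical(phantom$masks[[s]])]
    c(D2 = dose_at_volume(d, 2), D50 = dose_at_volume(d, 50),
      D98 = dose_at_volume(d, 98), Dmean = mean(d))
  }
  nom_idx <- lapply(structures, function(s) idx_fun(nominal, s))
  names(nom_idx) <- structures
  bins <- seq(0, max(nominal) * 1.1 + 1e-9, length.out = 120)

  samp_idx <- vector("list", unc$n_samples)
  samp_dvh <- vector("list", unc$n_samples)
  for (k in seq_len(unc$n_samples)) {
    sc <- sample_scenario(unc, k, plan)
    dose_k <- apply_scenario(plan, phantom, sc, model)
    samp_idx[[k]] <- lapply(structures, function(s) idx_fun(dose_k, s))
    samp_dvh[[k]] <- lapply(structures, function(s)
      dvh(dose_k, phantom$masks[[s]], bins = bins)$volume)
  }

  table <- do.call(rbind, lapply(seq_along(structures), function(si) {
    s <- structures[si]
    do.call(rbind, lapply(names(nom_idx[[s]]), function(ix) {
      vals <- vapply(samp_idx, function(x) x[[si]][[ix]], numeric(1))
      data.frame(structure = s, index = ix, nominal = nom_idx[[s]][[ix]],
                 mean_diff = mean(vals) - nom_idx[[s]][[ix]],
                 sd = stats::sd(vals), stringsAsFactors = FALSE)
    }))
  }))
  rownames(table) <- NULL

  bands <- lapply(seq_along(structures), function(si) {
    mat <- do.call(rbind, lapply(samp_dvh, `[[`, si))
    qs <- apply(mat, 2, stats::quantile, probs = band_probs, names = FALSE)
    out <- data.frame(dose = bins, t(qs))
    names(out) <- c("dose", paste0("q", band_probs * 100))
    out
  })
  names(bands) <- structures

  structure(list(table = table, bands = bands, n_samples = unc$n_samples),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness_result> %d scenarios\n", x$n_samples))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
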