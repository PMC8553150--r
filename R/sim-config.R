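#' Configuration for the synthetic-study generator
#'
#' Collects every tunable parameter of [simulate_study()] in one validated
#' list. Defaults reproduce the sampling design and summary statistics of the
#' boreal forest-tundra ecotone wildfire study the package models: 48 burned
#' plots with 12 sampling points each (4 soil monoliths + 8 probe points),
#' 15 unburned control plots carrying 50 soil monoliths, a mean organic-soil
#' burn depth of 10.57 +/- 4.48 cm, a residual-surface bulk density of
#' 0.14 g cm-3, a presence-absence turnover target of 0.34, and
#' negative-binomial regeneration counts whose log-scale treatment effects are
#' the seeding-experiment coefficients (seeded 5.52, burned 1.99, scarified
#' 0.62, seeded x burned -1.83 around an intercept of -4.40).
#'
#' @param n_plots Number of burned plots (default 48).
#' @param n_control Number of unburned control plots (default 15).
#' @param points_per_plot Soil sampling points per burned plot (default 12).
#' @param monolith_points How many of those points carry a soil monolith
#'   (default 4; the remainder are knife-probe points).
#' @param burn_depth_mean,burn_depth_sd Mean and standard deviation (cm) of the
#'   zero-truncated normal burn-depth distribution. `burn_depth_sd = 0` makes
#'   every burn depth exactly `burn_depth_mean`.
#' @param residual_mean,residual_sd Residual (post-fire) soil organic layer
#'   depth distribution (cm).
#' @param residual_moisture_shift Additive shift (cm) of residual SOL depth for
#'   the three moisture classes (mesic, mesic-subhygric, subhygric). Wetter
#'   classes accumulate deeper organic layers.
#' @param control_sol_mean,control_sol_sd Pre-fire SOL depth distribution (cm)
#'   for control-plot monoliths.
#' @param bd_surface_mean,bd_surface_sd Surface bulk density distribution
#'   (g cm-3) of organic-soil increments.
#' @param bd_depth_slope Linear increase of bulk density with depth
#'   (g cm-3 per cm).
#' @param carbon_beta_d,carbon_beta_d2 Coefficients of the quadratic
#'   cumulative-carbon truth curve C(d) = beta_d * d + beta_d2 * d^2
#'   (kg C m-2, d in cm) used to generate increment carbon.
#' @param carbon_moisture_slope_shift Additive shift of `carbon_beta_d` per
#'   moisture class (depth x moisture interaction in the generating model).
#' @param carbon_sigma_plot,carbon_sigma_mono,carbon_sigma_resid Log-scale
#'   standard deviations of plot-level, monolith-level, and residual
#'   multiplicative noise on increment carbon.
#' @param arh_offset,tch_offset True calibration offsets (cm): adventitious
#'   root depth below the green moss surface and unburned tussock crown
#'   height.
#' @param proxy_sd Within-point spread (cm) of individual root/tussock
#'   measurements. @param n_proxy Measurements per sampling point (default 5).
#' @param offset_sd Spread (cm) of unburned calibration measurements.
#' @param turnover_target Expected presence-absence species turnover between
#'   pre- and post-fire communities (default 0.34).
#' @param richness Per-site species richness of the union community.
#' @param species_pool Size of the regional species pool.
#' @param density_base Mesic-plot conifer density (stems m-2) at the reference
#'   equivalent latitude. @param density_eqlat_slope Change in density per
#'   degree of equivalent latitude. @param density_moisture_shift Additive
#'   density shift per moisture class. @param density_sd Plot-level density
#'   noise.
#' @param seedrain_coefs Log-scale coefficients (intercept, burned,
#'   conifer-density) of the NB2 per-trap-collection seed count model.
#' @param seedrain_theta NB2 dispersion for seed-trap counts.
#' @param seeding_coefs Log-scale coefficients (intercept, seeded, burned,
#'   scarified, seeded:burned) of the NB1 seeding-experiment count model.
#' @param seeding_alpha NB1 dispersion (variance = mu * (1 + alpha)).
#' @param survival First-to-second-year seedling survival probability.
#' @param natregen_coefs Log-scale coefficients (intercept, conifer-density)
#'   of the NB2 natural-regeneration count model.
#' @param natregen_theta NB2 dispersion for natural regeneration.
#' @param seeds_per_quadrat Seeds sown per seeded quadrat (default 250).
#' @param viability Seed viability fraction (default 0.16).
#' @param n_seed_plots Plots in the seed-rain / seeding design (default 12,
#'   split evenly burned / control). @param n_blocks Blocks per seeding plot.
#' @param n_traps Seed traps per plot. @param trap_dims Trap length and width
#'   (m). @param collection_exposures Named vector of exposure durations
#'   (years) per trap collection.
#' @param plot_area Plot area in m2 (default 201).
#' @param seedling_area Natural-regeneration survey area per plot in m2
#'   (default 16 = four 4-m2 quadrats).
#' @param latitude_mean,latitude_sd,slope_mean,slope_sd,elevation_mean,elevation_sd
#'   Topographic distributions (degrees / m).
#' @param moisture_probs Probabilities of the mesic, mesic-subhygric and
#'   subhygric classes.
#' @param diameter_meanlog,diameter_sdlog Log-normal tree diameter parameters
#'   (cm). @param prop_black_spruce Fraction of conifer stems that are black
#'   spruce. @param combustion_probs Combustion-class probabilities (classes
#'   0-3) for trees in burned plots.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_plots = 8, n_control = 4)
#' cfg$burn_depth_mean
sim_config <- function(n_plots = 48L,
                       n_control = 15L,
                       points_per_plot = 12L,
                       monolith_points = 4L,
                       burn_depth_mean = 10.57,
                       burn_depth_sd = 4.48,
                       residual_mean = 16.06,
                       residual_sd = 9.83,
                       residual_moisture_shift = c(mesic = -4, `mesic-subhygric` = 0,
                                                   subhygric = 4),
                       control_sol_mean = 27.95,
                       control_sol_sd = 9.71,
                       bd_surface_mean = 0.14,
                       bd_surface_sd = 0.07,
                       bd_depth_slope = 0.004,
                       carbon_beta_d = 0.1207,
                       carbon_beta_d2 = 0.00612,
                       carbon_moisture_slope_shift = c(mesic = 0,
                                                       `mesic-subhygric` = 0.012,
                                                       subhygric = 0.025),
                       carbon_sigma_plot = 0.10,
                       carbon_sigma_mono = 0.07,
                       carbon_sigma_resid = 0.05,
                       arh_offset = 2.19,
                       tch_offset = 11.51,
                       proxy_sd = 1.0,
                       n_proxy = 5L,
                       offset_sd = 0.6,
                       turnover_target = 0.34,
                       richness = 50L,
                       species_pool = 80L,
                       density_base = 0.04,
                       density_eqlat_slope = -0.004,
                       density_moisture_shift = c(mesic = 0, `mesic-subhygric` = -0.02,
                                                  subhygric = -0.04),
                       density_sd = 0.03,
                       seedrain_coefs = c(intercept = -0.64, burned = -0.08,
                                          density = 22.78),
                       seedrain_theta = 1.5,
                       seeding_coefs = c(intercept = -4.40, seeded = 5.52,
                                         burned = 1.99, scarified = 0.62,
                                         seeded_burned = -1.83),
                       seeding_alpha = 1,
                       survival = 0.75,
                       natregen_coefs = c(intercept = 0.34, density = 11.16),
                       natregen_theta = 0.8,
                       seeds_per_quadrat = 250L,
                       viability = 0.16,
                       n_seed_plots = 12L,
                       n_blocks = 5L,
                       n_traps = 10L,
                       trap_dims = c(0.54, 0.28),
                       collection_exposures = c(`2016-08` = 0.08, `2017-06` = 0.83,
                                                `2017-08` = 0.17, `2018-06` = 0.83,
                                                `2018-08` = 0.17),
                       plot_area = 201,
                       seedling_area = 16,
                       latitude_mean = 63.7,
                       latitude_sd = 0.03,
                       slope_mean = 4,
                       slope_sd = 4,
                       elevation_mean = 527.71,
                       elevation_sd = 47.63,
                       moisture_probs = c(0.40, 0.35, 0.25),
                       diameter_meanlog = log(8),
                       diameter_sdlog = 0.5,
                       prop_black_spruce = 0.7,
                       combustion_probs = c(0.05, 0.15, 0.3, 0.5)) {
  cfg <- as.list(environment())

  counts <- c("n_plots", "n_control", "points_per_plot", "monolith_points",
              "n_proxy", "richness", "species_pool", "seeds_per_quadrat",
              "n_seed_plots", "n_blocks", "n_traps")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      abort(sprintf("`%s` must be an integer >= 1.", nm))
    }
    cfg[[nm]] <- as.integer(v)
  }
  sds <- c("burn_depth_sd", "residual_sd", "control_sol_sd", "bd_surface_sd",
           "carbon_sigma_plot", "carbon_sigma_mono", "carbon_sigma_resid",
           "proxy_sd", "offset_sd", "density_sd", "latitude_sd", "slope_sd",
           "elevation_sd")
  for (nm in sds) assert_number(cfg[[nm]], nm, lower = 0)
  assert_number(cfg$viability, "viability", lower = 0, upper = 1)
  assert_number(cfg$survival, "survival", lower = 0, upper = 1)
  assert_number(cfg$turnover_target, "turnover_target", lower = 0, upper = 1)
  assert_number(cfg$burn_depth_mean, "burn_depth_mean", lower = 0)
  assert_number(cfg$plot_area, "plot_area", lower = 1e-9)
  assert_number(cfg$seedling_area, "seedling_area", lower = 1e-9)
  if (cfg$monolith_points > cfg$points_per_plot) {
    abort("`monolith_points` cannot exceed `points_per_plot`.")
  }
  if (length(cfg$trap_dims) != 2 || any(cfg$trap_dims <= 0)) {
    abort("`trap_dims` must be two positive lengths (m).")
  }
  if (cfg$n_seed_plots %% 2 != 0) {
    abort("`n_seed_plots` must be even (half burned, half control).")
  }
  if (any(cfg$collection_exposures <= 0)) {
    abort("`collection_exposures` must be positive durations (years).")
  }
  if (length(cfg$moisture_probs) != 3 || any(cfg$moisture_probs < 0) ||
      sum(cfg$moisture_probs) <= 0) {
    abort("`moisture_probs` must be three non-negative weights.")
  }
  cfg$moisture_probs <- cfg$moisture_probs / sum(cfg$moisture_probs)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d burned plots x %d points (%d monolith), %d control plots\n",
              x$n_plots, x$points_per_plot, x$monolith_points, x$n_control))
  cat(sprintf("  burn depth %.2f +/- %.2f cm; surface bulk density %.2f g cm-3\n",
              x$burn_depth_mean, x$burn_depth_sd, x$bd_surface_mean))
  cat(sprintf("  turnover target %.2f; seed viability %.2f\n",
              x$turnover_target, x$viability))
  invisible(x)
}
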