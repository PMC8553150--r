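# Synthetic-study generator. One RNG stream per study, consumed in a fixed
# substream order (plots -> soils -> trees -> communities -> regeneration) so
# that a given seed always yields byte-identical tables.

# Largest-remainder apportionment of `total` items over integer weights.
#' @noRd
apportion <- function(weights, total) {
  q <- weights / sum(weights) * total
  f <- floor(q)
  r <- total - sum(f)
  if (r > 0) {
    idx <- order(q - f, decreasing = TRUE)[seq_len(r)]
    f[idx] <- f[idx] + 1
  }
  as.integer(f)
}

# Cumulative-carbon truth curve (kg C m-2 at depth d cm) for a moisture class.
#' @noRd
cum_carbon_truth <- function(d, moisture, config) {
  bd <- config$carbon_beta_d + config$carbon_moisture_slope_shift[[moisture]]
  bd * d + config$carbon_beta_d2 * d^2
}

#' Simulate one soil-monolith profile
#'
#' Generates the 5-cm increment series of a single organic-soil monolith:
#' increments partition `[0, total_depth]`, all but the last are 5 cm, and the
#' last has variable thickness. Bulk density is drawn around a surface mean of
#' `config$bd_surface_mean` (default 0.14 g cm-3) increasing linearly with
#' depth; percent carbon is back-computed so that the increment carbon follows
#' the configured quadratic cumulative-carbon curve (with multiplicative
#' plot/monolith/residual noise).
#'
#' @param moisture One of `"mesic"`, `"mesic-subhygric"`, `"subhygric"`.
#' @param total_depth Monolith depth in cm (> 0).
#' @param config A [sim_config()].
#' @param depth_offset Depth (cm) of the monolith surface below the original
#'   pre-fire surface; 0 for unburned monoliths, the burn depth for residual
#'   monoliths in burned plots.
#' @param plot_effect,mono_effect Log-scale random effects carried by all
#'   increments of this plot / monolith.
#' @param plot_id,monolith_id Identifier columns copied into the output.
#'
#' @return A tibble with one row per increment: `plot_id`, `monolith_id`,
#'   `top_depth`, `bottom_depth`, `dry_fine_mass` (g), `sample_volume` (cm3),
#'   `rock_volume` (cm3), `pct_carbon` (fraction).
#' @export
#' @examples
#' set.seed(1)
#' prof <- simulate_soil_profile("mesic", 27, sim_config())
#' prof$bottom_depth - prof$top_depth  # 5,5,5,5,5,2
simulate_soil_profile <- function(moisture, total_depth, config,
                                  depth_offset = 0,
                                  plot_effect = 0, mono_effect = 0,
                                  plot_id = "P1", monolith_id = "M1") {
  if (!moisture %in% MOISTURE_LEVELS) {
    abort("`moisture` must be one of mesic, mesic-subhygric, subhygric.")
  }
  assert_number(total_depth, "total_depth", lower = 1e-9)
  n5 <- floor(total_depth / 5)
  bounds <- seq(0, 5 * n5, by = 5)
  if (total_depth - 5 * n5 > 1e-9) bounds <- c(bounds, total_depth)
  if (length(bounds) < 2) bounds <- c(0, total_depth)
  top <- bounds[-length(bounds)]
  bottom <- bounds[-1]
  thick <- bottom - top
  n <- length(top)

  area_cm2 <- 10 * 5  # monolith face, 10 x 5 cm
  # bulk density runs from the monolith's own surface: the residual SOL
  # surface of burned profiles carries the configured surface mean
  bd <- rtruncnorm0(n,
                    mean = config$bd_surface_mean + config$bd_depth_slope * top,
                    sd = config$bd_surface_sd)
  bd <- pmax(bd, 0.01)
  sample_volume <- area_cm2 * thick
  rock_volume <- runif(n, 0, 0.03) * sample_volume

  target_c <- (cum_carbon_truth(bottom + depth_offset, moisture, config) -
                 cum_carbon_truth(top + depth_offset, moisture, config)) *
    exp(plot_effect + mono_effect +
          rnorm(n, 0, config$carbon_sigma_resid))
  pct <- target_c / (thick * bd * GCM2_TO_KGM2)
  pct <- pmin(pmax(pct, 0.005), 0.95)

  tibble(
    plot_id = plot_id,
    monolith_id = monolith_id,
    top_depth = top,
    bottom_depth = bottom,
    dry_fine_mass = bd * (sample_volume - rock_volume),
    sample_volume = sample_volume,
    rock_volume = rock_volume,
    pct_carbon = pct
  )
}

#' Simulate a paired pre-/post-fire community for one site
#'
#' Draws a union species list of size `richness` from the regional pool and
#' marks each species as changed (gained or lost across the fire) with
#' probability `turnover_target`, so the expected presence-absence turnover of
#' the pair equals the target. Cover values for present species are log-normal
#' percent covers.
#'
#' @param richness Union richness of the site (>= 2).
#' @param turnover_target Expected turnover in `[0, 1]`.
#' @param config A [sim_config()].
#' @return A tibble with columns `species`, `pre`, `post` (percent cover,
#'   0 = absent).
#' @export
#' @examples
#' set.seed(1)
#' pair <- simulate_community_pair(10, 0.34, sim_config())
simulate_community_pair <- function(richness, turnover_target, config) {
  if (!is.numeric(richness) || richness < 2 || richness != floor(richness)) {
    abort("`richness` must be an integer >= 2.")
  }
  assert_number(turnover_target, "turnover_target", lower = 0, upper = 1)
  if (richness > config$species_pool) {
    abort("`richness` exceeds the configured species pool.")
  }
  species <- sort(sample(sprintf("sp%03d", seq_len(config$species_pool)),
                         richness))
  changed <- runif(richness) < turnover_target
  gained <- changed & (runif(richness) < 0.5)
  lost <- changed & !gained
  # keep both assemblages non-empty
  if (all(gained)) gained[1] <- FALSE else if (all(lost)) lost[1] <- FALSE
  if (any(changed) && !any(gained) && turnover_target >= 1) {
    gained[which(lost)[1]] <- TRUE
    lost[which(gained)[1]] <- FALSE
  }
  pre_present <- !gained
  post_present <- !lost
  draw_cover <- function(present) {
    cov <- numeric(length(present))
    cov[present] <- pmin(round(stats::rlnorm(sum(present), log(3), 1), 1), 95)
    cov[present] <- pmax(cov[present], 0.5)
    cov
  }
  tibble(species = species,
         pre = draw_cover(pre_present),
         post = draw_cover(post_present))
}

#' Simulate the factorial seeding experiment
#'
#' Builds the 2 x 2 (seeded x scarified) factorial crossed with burn status:
#' `n_seed_plots` plots (half burned, half control), `n_blocks` blocks per
#' plot, one quadrat per treatment per block. First-year seedling counts are
#' NB1 draws (variance increasing linearly with the mean) from the log-linear
#' mean defined by `config$seeding_coefs`; second-year counts are binomial
#' survivors at rate `config$survival`.
#'
#' @param config A [sim_config()].
#' @param plot_ids Optional character vector of plot identifiers (length
#'   `n_seed_plots`, first half burned). Defaults to generated ids.
#' @return A tibble with one row per quadrat.
#' @export
simulate_seeding_experiment <- function(config, plot_ids = NULL) {
  nb <- config$n_seed_plots / 2
  if (is.null(plot_ids)) {
    plot_ids <- c(sprintf("B%02d", seq_len(nb)), sprintf("C%02d", seq_len(nb)))
  }
  if (length(plot_ids) != config$n_seed_plots) {
    abort("`plot_ids` must have length `n_seed_plots`.")
  }
  design <- tidyr::expand_grid(
    plot_id = plot_ids,
    block = seq_len(config$n_blocks),
    seeded = c(FALSE, TRUE),
    scarified = c(FALSE, TRUE)
  ) %>%
    mutate(burned = .data$plot_id %in% plot_ids[seq_len(nb)])

  cf <- config$seeding_coefs
  term <- function(flag, beta) if_else(flag, beta, 0)
  lp <- cf[["intercept"]] +
    term(design$seeded, cf[["seeded"]]) +
    term(design$burned, cf[["burned"]]) +
    term(design$scarified, cf[["scarified"]]) +
    term(design$seeded & design$burned, cf[["seeded_burned"]])
  mu <- exp(lp)
  mu[is.na(mu)] <- 0
  y1 <- rnb1(nrow(design), mu, config$seeding_alpha)
  y2 <- rbinom(nrow(design), y1, config$survival)
  design %>%
    mutate(
      seeds_sown = if_else(.data$seeded, as.integer(config$seeds_per_quadrat),
                           0L),
      seedlings_2017 = y1,
      seedlings_2018 = y2,
      quadrat_area = 0.25
    )
}

#' Simulate depth-carbon data directly from the hierarchical model
#'
#' Draws cumulative carbon-by-depth observations from the linear mixed model
#' `cum = b0 + b_d * depth + b_d2 * depth^2 + u_plot + u_mono + e` with
#' independent plot and monolith-within-plot random intercepts. Used for
#' parameter-recovery checks of [fit_depth_carbon_model()].
#'
#' @param n_plots Number of plots. @param monoliths_per_plot Monoliths within
#'   each plot (scalar or vector recycled over plots).
#' @param depths Depth grid (cm) observed in every monolith.
#' @param beta Numeric vector `c(b0, b_d, b_d2)`.
#' @param sigma_plot,sigma_mono,sigma_resid Standard deviations of the two
#'   random intercepts and the residual.
#' @return A tibble with `plot_id`, `monolith_id`, `moisture`, `depth`,
#'   `cum_carbon`.
#' @export
simulate_depth_carbon_data <- function(n_plots = 15, monoliths_per_plot = 4,
                                       depths = seq(5, 25, by = 5),
                                       beta = c(0, 0.1207, 0.00612),
                                       sigma_plot = 0.5, sigma_mono = 0.3,
                                       sigma_resid = 0.3) {
  u_plot <- rnorm(n_plots, 0, sigma_plot)
  monoliths_per_plot <- rep_len(monoliths_per_plot, n_plots)
  purrr::map_dfr(seq_len(n_plots), function(p) {
    purrr::map_dfr(seq_len(monoliths_per_plot[p]), function(m) {
      u_mono <- rnorm(1, 0, sigma_mono)
      tibble(
        plot_id = sprintf("P%02d", p),
        monolith_id = sprintf("P%02d-M%d", p, m),
        moisture = "mesic",
        depth = depths,
        cum_carbon = beta[1] + beta[2] * depths + beta[3] * depths^2 +
          u_plot[p] + u_mono + rnorm(length(depths), 0, sigma_resid)
      )
    })
  })
}

#' Simulate a complete synthetic wildfire study
#'
#' Generates all tables the downstream analysis consumes, with the sampling
#' design of the field study the package models: burned plots with 12 soil
#' sampling points each (4 monolith + 8 probe), unburned control plots
#' carrying the soil monoliths used to fit the depth-carbon model and the
#' proxy measurements used to calibrate burn-depth offsets, a tree census
#' with combustion classes, paired pre-/post-fire community matrices, and the
#' seed-rain and seeding-experiment designs. At the default configuration the
#' design arithmetic matches the study: 48 x 12 = 576 depth/ALT measurement
#' points, 470 of them usable for active-layer analysis, 170 points with a
#' burn-depth estimate, 50 control monoliths, and 240 seeding quadrats.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical studies.
#' @return An object of class `synthetic_study`: a list of tibbles (`plots`,
#'   `points`, `soil`, `proxies`, `trees`, `community_pre`, `community_post`,
#'   `seed_traps`, `quadrats`) plus `ground_truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_plots = 6, n_control = 4), seed = 1)
#' names(study)
simulate_study <- function(config = sim_config(), seed = 1L) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  set.seed(as.integer(seed))
  np <- config$n_plots
  nc <- config$n_control
  ppp <- config$points_per_plot
  mpp <- config$monolith_points

  ## ---- plots (burned + control) -----------------------------------------
  plot_tbl <- function(ids, grid, burned) {
    n <- length(ids)
    slope <- pmin(rtruncnorm0(n, config$slope_mean, config$slope_sd), 89)
    aspect <- runif(n, 0, 360)
    lat <- rnorm(n, config$latitude_mean, config$latitude_sd)
    moisture <- sample(MOISTURE_LEVELS, n, replace = TRUE,
                       prob = config$moisture_probs)
    eqlat <- equivalent_latitude(slope, aspect, lat)
    dens <- pmax(0, config$density_base +
                   config$density_eqlat_slope * (eqlat - config$latitude_mean) +
                   config$density_moisture_shift[moisture] +
                   rnorm(n, 0, config$density_sd))
    tibble(plot_id = ids, grid_id = grid, burned = burned,
           slope = slope, aspect = aspect, latitude = lat,
           elevation = rnorm(n, config$elevation_mean, config$elevation_sd),
           moisture = moisture, conifer_density = dens)
  }
  burned_ids <- sprintf("B%02d", seq_len(np))
  control_ids <- sprintf("C%02d", seq_len(nc))
  plots <- bind_rows(
    plot_tbl(burned_ids, rep(c("ET", "WC"), each = ceiling(np / 2))[seq_len(np)],
             TRUE),
    plot_tbl(control_ids, rep(c("ET", "WC"), each = ceiling(nc / 2))[seq_len(nc)],
             FALSE)
  )

  ## ---- burned sampling points -------------------------------------------
  # Burn-depth availability pattern (plots with 4/3/2/1/0 estimable points)
  # and frozen-ground pattern scale with the design from the 48-plot study.
  grp_counts <- apportion(c(37, 5, 3, 1, 2), np)
  k_per_plot <- rep(c(4L, 3L, 2L, 1L, 0L), times = grp_counts)
  k_per_plot <- pmin(k_per_plot, mpp)

  n_frozen_plots <- round(np * 4 / 48)
  frozen_plots <- burned_ids[frozen_plot_indices(np, n_frozen_plots)]

  points <- tidyr::expand_grid(plot_id = burned_ids,
                               point = seq_len(ppp)) %>%
    mutate(point_id = sprintf("%s-%02d", .data$plot_id, .data$point),
           monolith = .data$point <= mpp) %>%
    left_join(select(plots, "plot_id", "moisture"), by = "plot_id")

  bd_true <- rtruncnorm0(nrow(points), config$burn_depth_mean,
                         config$burn_depth_sd)
  resid_true <- rtruncnorm0(
    nrow(points),
    config$residual_mean + config$residual_moisture_shift[points$moisture],
    config$residual_sd
  )
  points$burn_depth_true <- bd_true
  points$residual_cm <- round(resid_true, 1)

  # frozen-ground bookkeeping: whole plots always frozen, plus scattered hits
  points$hit <- "mineral"
  points$hit[points$plot_id %in% frozen_plots] <- "frozen"
  open_idx <- which(points$hit == "mineral")
  n_scatter <- round(length(open_idx) * 58 / 528)
  if (n_scatter > 0) {
    points$hit[sample(open_idx, n_scatter)] <- "frozen"
  }
  points$alt_cm <- round(pmax(rnorm(nrow(points), 51.15, 22.34), 5), 1)

  # which monolith points get a burn-depth estimate
  points$has_burn_depth <- FALSE
  for (i in seq_len(np)) {
    k <- k_per_plot[i]
    if (k > 0) {
      idx <- which(points$plot_id == burned_ids[i] & points$monolith)[seq_len(k)]
      points$has_burn_depth[idx] <- TRUE
    }
  }

  # proxy availability per plot: both / TCH-only / ARH-only (25/15/6 of 46)
  with_bd <- burned_ids[k_per_plot > 0]
  avail_counts <- apportion(c(25, 15, 6), length(with_bd))
  proxy_type <- rep(c("both", "tch", "arh"), times = avail_counts)
  names(proxy_type) <- with_bd

  ## ---- soils -------------------------------------------------------------
  u_plot_c <- setNames(rnorm(nc, 0, config$carbon_sigma_plot), control_ids)
  u_plot_b <- setNames(rnorm(np, 0, config$carbon_sigma_plot), burned_ids)
  monos_per_control <- apportion(rep(1, nc), round(50 * nc / 15))
  control_moisture <- setNames(
    plots$moisture[match(control_ids, plots$plot_id)], control_ids)

  soil_control <- purrr::map_dfr(seq_len(nc), function(p) {
    pid <- control_ids[p]
    purrr::map_dfr(seq_len(monos_per_control[p]), function(m) {
      depth <- max(rtruncnorm0(1, config$control_sol_mean,
                               config$control_sol_sd), 6)
      simulate_soil_profile(
        control_moisture[[pid]], depth, config,
        depth_offset = 0,
        plot_effect = u_plot_c[[pid]],
        mono_effect = rnorm(1, 0, config$carbon_sigma_mono),
        plot_id = pid, monolith_id = sprintf("%s-M%d", pid, m)
      )
    })
  })

  mono_pts <- points %>% filter(.data$monolith, .data$residual_cm > 0.5)
  soil_burned <- purrr::map_dfr(seq_len(nrow(mono_pts)), function(i) {
    row <- mono_pts[i, ]
    simulate_soil_profile(
      row$moisture, row$residual_cm, config,
      depth_offset = row$burn_depth_true,
      plot_effect = u_plot_b[[row$plot_id]],
      mono_effect = rnorm(1, 0, config$carbon_sigma_mono),
      plot_id = row$plot_id, monolith_id = row$point_id
    )
  })
  soil <- bind_rows(
    mutate(soil_control, context = "unburned"),
    mutate(soil_burned, context = "burned")
  )

  ## ---- proxies -----------------------------------------------------------
  bd_points <- points %>% filter(.data$has_burn_depth)
  proxies_burned <- purrr::map_dfr(seq_len(nrow(bd_points)), function(i) {
    row <- bd_points[i, ]
    type <- proxy_type[[row$plot_id]]
    out <- list()
    if (type %in% c("both", "arh")) {
      out$arh <- tibble(
        plot_id = row$plot_id, point_id = row$point_id, context = "burned",
        proxy = "arh",
        value_cm = pmax(rnorm(config$n_proxy,
                              row$burn_depth_true - config$arh_offset,
                              config$proxy_sd), 0)
      )
    }
    if (type %in% c("both", "tch")) {
      out$tch <- tibble(
        plot_id = row$plot_id, point_id = row$point_id, context = "burned",
        proxy = "tch",
        value_cm = pmax(rnorm(config$n_proxy,
                              row$burn_depth_true + config$tch_offset,
                              config$proxy_sd), 0)
      )
    }
    bind_rows(out)
  })
  proxies_control <- purrr::map_dfr(control_ids, function(pid) {
    purrr::map_dfr(seq_len(mpp), function(pt) {
      tibble(
        plot_id = pid,
        point_id = sprintf("%s-%02d", pid, pt),
        context = "unburned",
        proxy = rep(c("arh", "tch"), each = config$n_proxy),
        value_cm = c(
          rtruncnorm0(config$n_proxy, config$arh_offset, config$offset_sd),
          rtruncnorm0(config$n_proxy, config$tch_offset, config$offset_sd)
        )
      )
    })
  })
  proxies <- bind_rows(proxies_burned, proxies_control)

  ## ---- trees -------------------------------------------------------------
  burned_plots <- plots %>% filter(.data$burned)
  trees <- purrr::map_dfr(seq_len(nrow(burned_plots)), function(i) {
    row <- burned_plots[i, ]
    n <- rpois(1, row$conifer_density * config$plot_area)
    if (n == 0) return(NULL)
    tibble(
      plot_id = row$plot_id,
      tree_id = sprintf("%s-T%03d", row$plot_id, seq_len(n)),
      species = sample(c("black spruce", "white spruce"), n, replace = TRUE,
                       prob = c(config$prop_black_spruce,
                                1 - config$prop_black_spruce)),
      diameter = round(stats::rlnorm(n, config$diameter_meanlog,
                                     config$diameter_sdlog), 1),
      combustion_class = sample(0:3, n, replace = TRUE,
                                prob = config$combustion_probs)
    )
  })

  ## ---- communities -------------------------------------------------------
  comm <- purrr::map(burned_ids, function(pid) {
    simulate_community_pair(config$richness, config$turnover_target, config) %>%
      mutate(plot_id = pid)
  }) %>% bind_rows()
  community_pre <- comm %>%
    select("plot_id", "species", cover = "pre") %>%
    tidyr::pivot_wider(names_from = "species", values_from = "cover",
                       values_fill = 0, names_sort = TRUE)
  community_post <- comm %>%
    select("plot_id", "species", cover = "post") %>%
    tidyr::pivot_wider(names_from = "species", values_from = "cover",
                       values_fill = 0, names_sort = TRUE)
  # paired matrices share one species universe
  all_sp <- union(names(community_pre), names(community_post))
  for (sp in setdiff(all_sp, names(community_pre))) community_pre[[sp]] <- 0
  for (sp in setdiff(all_sp, names(community_post))) community_post[[sp]] <- 0
  community_pre <- community_pre[, sort(all_sp)] %>%
    select("plot_id", dplyr::everything())
  community_post <- community_post[, sort(all_sp)] %>%
    select("plot_id", dplyr::everything())

  ## ---- regeneration ------------------------------------------------------
  nb_seed <- min(config$n_seed_plots %/% 2, np, nc)
  seed_plot_ids <- c(head(burned_ids, nb_seed), head(control_ids, nb_seed))
  trap_area <- prod(config$trap_dims)
  exposures <- config$collection_exposures
  seed_design <- tidyr::expand_grid(
    plot_id = seed_plot_ids,
    trap_id = seq_len(config$n_traps),
    collection = names(exposures)
  ) %>%
    left_join(select(plots, "plot_id", "burned", "conifer_density"),
              by = "plot_id") %>%
    mutate(exposure_yr = exposures[.data$collection],
           trap_length = config$trap_dims[1],
           trap_width = config$trap_dims[2])
  # coefficients act on the seeds m-2 yr-1 scale; trap area x exposure is
  # the offset converting the rate to a per-trap-collection count mean
  cf <- config$seedrain_coefs
  mu_seed <- exp(cf[["intercept"]] +
                   if_else(seed_design$burned, cf[["burned"]], 0) +
                   cf[["density"]] * seed_design$conifer_density) *
    trap_area * seed_design$exposure_yr
  seed_traps <- seed_design %>%
    mutate(seed_count = rnb2(dplyr::n(), mu_seed, config$seedrain_theta)) %>%
    select("plot_id", "trap_id", "collection", "seed_count",
           "trap_length", "trap_width", "exposure_yr")

  cfg_seed <- config
  cfg_seed$n_seed_plots <- as.integer(2 * nb_seed)
  quadrats <- simulate_seeding_experiment(cfg_seed, plot_ids = seed_plot_ids)

  nat_mu <- exp(config$natregen_coefs[["intercept"]] +
                  config$natregen_coefs[["density"]] *
                  burned_plots$conifer_density)
  seedlings <- setNames(rnb2(np, nat_mu, config$natregen_theta), burned_ids)
  plots$seedlings <- as.integer(seedlings[plots$plot_id])

  structure(list(
    plots = plots,
    points = select(points, "plot_id", "point_id", "monolith", "moisture",
                    "residual_cm", "hit", "alt_cm", "has_burn_depth"),
    soil = soil,
    proxies = proxies,
    trees = trees,
    community_pre = community_pre,
    community_post = community_post,
    seed_traps = seed_traps,
    quadrats = quadrats,
    ground_truth = list(
      config = config, seed = as.integer(seed),
      point_truth = select(points, "plot_id", "point_id", "monolith",
                           "burn_depth_true", "residual_cm", "has_burn_depth"),
      arh_offset = config$arh_offset, tch_offset = config$tch_offset,
      carbon_beta_d = config$carbon_beta_d,
      carbon_beta_d2 = config$carbon_beta_d2,
      carbon_moisture_slope_shift = config$carbon_moisture_slope_shift,
      plot_effects = c(u_plot_c, u_plot_b)
    )
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  for (nm in setdiff(names(x), "ground_truth")) {
    cat(sprintf("  %-14s %6d rows\n", nm, nrow(x[[nm]])))
  }
  cat(sprintf("  seed %d\n", x$ground_truth$seed))
  invisible(x)
}

#' Write the study tables to CSV and the ground truth to JSON
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synthetic_study")) abort("`study` must be a synthetic_study.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in setdiff(names(study), "ground_truth")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(study[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  gt <- study$ground_truth
  gt$config <- unclass(gt$config)
  gt$point_truth <- NULL
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt, p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}
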