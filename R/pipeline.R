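# End-to-end orchestration: simulate -> burn depth -> soil / tree carbon ->
# budgets -> community change -> regeneration, with stage-level record counts
# so the study's sample-size bookkeeping is auditable from the report.

#' Closed-form design expectations for a configuration
#'
#' The sampling-design arithmetic implied by a [sim_config()]: measurement
#' locations (`n_plots x points_per_plot`), burn-depth points from the
#' per-plot availability pattern, active-layer-usable points after the
#' frozen-ground pattern, quadrat and sown-seed totals, and the
#' natural-regeneration survey area. At the default configuration these are
#' 576, 170, 470, 240, 30,000 and 16.
#'
#' @param config A [sim_config()].
#' @return A named list of integer expectations.
#' @export
design_expectations <- function(config) {
  np <- config$n_plots
  ppp <- config$points_per_plot
  grp <- apportion(c(37, 5, 3, 1, 2), np)
  k <- pmin(c(4L, 3L, 2L, 1L, 0L), config$monolith_points)
  n_frozen_plots <- round(np * 4 / 48)
  open <- (np - n_frozen_plots) * ppp
  scatter <- round(open * 58 / 528)
  n_quadrats <- config$n_seed_plots * config$n_blocks * 4L
  list(
    n_measurement_locations = np * ppp,
    n_burn_depth_points = sum(k * grp),
    n_alt_usable = open - scatter,
    n_quadrats = n_quadrats,
    seeds_sown = config$seeds_per_quadrat * n_quadrats / 2L,
    seedling_survey_area_m2 = config$seedling_area
  )
}

#' @noRd
frozen_plot_indices <- function(np, nf) {
  if (nf <= 0) return(integer(0))
  idx <- round(seq(2, max(np - 1, 2), length.out = nf))
  if (anyDuplicated(idx) || length(idx) != nf) idx <- seq_len(nf) + 1L
  idx
}

# Bray-Curtis distance matrix over the rows of a non-negative matrix.
#' @noRd
bray_curtis_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(mat[i, ], mat[j, ])
    }
  }
  stats::as.dist(d)
}

#' Run the full synthetic-study analysis
#'
#' Simulates a study (or accepts one), then runs every analysis stage:
#' offset calibration and burn-depth reconstruction, SOL partition, the
#' hierarchical depth-carbon model fitted on unburned monoliths, prediction
#' of combusted belowground carbon at every burn-depth point, residual-pool
#' carbon from burned monoliths, aboveground pools from the tree census,
#' plot-level carbon budgets with a study summary, community change
#' (Bray-Curtis, turnover, strata-respecting PerMANOVA of pre vs post), and
#' regeneration summaries. Identical seeds give identical reports.
#'
#' @param config A [sim_config()]. @param seed Integer seed.
#' @param study Optionally, an existing `synthetic_study` (then `config` and
#'   `seed` are taken from its ground truth).
#' @param n_perm Permutations for the PerMANOVA stage (default 499).
#' @param community Run the community-change stage (default `TRUE`; the
#'   pairwise distance matrix is quadratic in the number of sites, so very
#'   large simulated studies can skip it).
#' @return A list of class `fire_report`; see the elements returned.
#' @export
#' @examples
#' \donttest{
#' rep <- run_fire_analysis(sim_config(n_plots = 12, n_control = 6), seed = 1,
#'                          n_perm = 99)
#' rep$budget_summary
#' }
run_fire_analysis <- function(config = sim_config(), seed = 1L, study = NULL,
                              n_perm = 499, community = TRUE) {
  if (is.null(study)) {
    study <- simulate_study(config, seed = seed)
  } else {
    config <- study$ground_truth$config
    seed <- study$ground_truth$seed
  }
  log <- list()
  note <- function(stage, n) log[[stage]] <<- n

  ## severity ---------------------------------------------------------------
  any_burned_proxies <- any(study$proxies$context == "burned")
  if (any_burned_proxies) {
    offsets <- calibrate_offsets(study$proxies)
    bd <- burn_depth_table(study$proxies, study$points)
    note("burn_depth_points", nrow(bd))
  } else {
    offsets <- NULL
    bd <- NULL
    note("burn_depth_points", 0L)
  }

  ## soil carbon ------------------------------------------------------------
  unburned_inc <- filter(study$soil, .data$context == "unburned")
  profile <- cumulative_profile(unburned_inc)
  model <- fit_depth_carbon_model(
    profile, moisture_by_plot = select(study$plots, "plot_id", "moisture"))
  note("model_increments", model$n_increments)

  report <- list(study = study, offsets = offsets, burn_depth = bd,
                 depth_model = model)

  if (!is.null(bd) && nrow(bd) > 0) {
    burned_inc <- filter(study$soil, .data$context == "burned")
    residual_c <- cumulative_profile(burned_inc) %>%
      group_by(.data$plot_id, .data$monolith_id) %>%
      summarise(residual_c = max(.data$cum_carbon), .groups = "drop") %>%
      rename(point_id = "monolith_id")
    below_points <- bd %>%
      left_join(residual_c, by = c("plot_id", "point_id")) %>%
      mutate(residual_c = dplyr::coalesce(.data$residual_c, 0)) %>%
      left_join(select(study$plots, "plot_id", "moisture"), by = "plot_id")
    # moisture classes absent from the unburned training set are predicted
    # at the reference level (population surface)
    moist_used <- if_else(below_points$moisture %in% model$moisture_levels,
                          below_points$moisture, model$moisture_levels[1])
    pred <- predict_combusted_carbon(model, below_points$bd_cm, moist_used)
    below_points <- below_points %>%
      mutate(combusted_c = pred$combusted_c,
             prefire_c = prefire_sol_carbon(.data$residual_c,
                                            .data$combusted_c))
    note("below_points", nrow(below_points))

    below_plot <- below_points %>%
      group_by(.data$plot_id) %>%
      summarise(below_prefire = mean(.data$prefire_c),
                below_combusted = mean(.data$combusted_c), .groups = "drop")
    above_plot <- plot_aboveground_pools(study$trees,
                                         plot_area = config$plot_area)
    above_plot <- tibble(plot_id = below_plot$plot_id) %>%
      left_join(above_plot, by = "plot_id") %>%
      mutate(across(c("above_prefire", "above_combusted"),
                    ~dplyr::coalesce(.x, 0)))
    budgets <- assemble_budget(above_plot, below_plot)
    report$below_points <- below_points
    report$budgets <- budgets
    report$budget_summary <- summarize_study(budgets)
    note("budget_plots", nrow(budgets))
  } else {
    report$skipped <- c(report$skipped,
                        "severity/budget stages skipped: no burned proxies")
  }

  ## community --------------------------------------------------------------
  if (community) {
  sp <- setdiff(names(study$community_pre), "plot_id")
  mat <- rbind(as.matrix(study$community_pre[, sp]),
               as.matrix(study$community_post[, sp]))
  rownames(mat) <- c(paste0(study$community_pre$plot_id, "-pre"),
                     paste0(study$community_post$plot_id, "-post"))
  groups <- rep(c("pre", "post"), each = nrow(study$community_pre))
  strata <- rep(study$community_pre$plot_id, 2)
  report$community <- community_change(study$community_pre,
                                       study$community_post)
  report$permanova <- permanova(bray_curtis_matrix(mat), groups,
                                strata = strata, n_perm = n_perm,
                                seed = seed)
  note("community_sites", nrow(report$community))
  }

  ## regeneration -----------------------------------------------------------
  rate_by_status <- study$seed_traps %>%
    left_join(select(study$plots, "plot_id", "burned"), by = "plot_id") %>%
    group_by(.data$burned) %>%
    group_modify(~tibble(rate = seed_rain_rate(.x))) %>%
    ungroup() %>%
    mutate(viable_rate = viable_seed_rain(.data$rate, config$viability))
  report$seed_rain <- rate_by_status
  report$regen <- experiment_summary(study$quadrats)
  report$seedling_density <- study$plots %>%
    filter(.data$burned) %>%
    mutate(density_stems_m2 = seedling_density(.data$seedlings,
                                               config$seedling_area)) %>%
    select("plot_id", "seedlings", "density_stems_m2")
  note("quadrats", nrow(study$quadrats))

  ## bookkeeping ------------------------------------------------------------
  report$design_counts <- list(
    n_measurement_locations = nrow(study$points),
    n_burn_depth_points = sum(study$points$has_burn_depth),
    n_alt_usable = sum(study$points$hit == "mineral"),
    n_quadrats = nrow(study$quadrats),
    seeds_sown = sum(study$quadrats$seeds_sown),
    seedling_survey_area_m2 = config$seedling_area
  )
  report$log <- log
  report$seed <- as.integer(seed)
  report$config_hash <- rlang::hash(unclass(config))
  class(report) <- "fire_report"
  report
}

#' @export
print.fire_report <- function(x, ...) {
  cat("<fire_report>  seed", x$seed, " config", substr(x$config_hash, 1, 8),
      "\n")
  for (nm in names(x$log)) cat(sprintf("  %-22s %d\n", nm, x$log[[nm]]))
  if (!is.null(x$skipped)) cat("  skipped:", x$skipped, "\n")
  invisible(x)
}

#' Check in-study arithmetic against the published design
#'
#' Recomputes, from package functions at run time, the printed arithmetic of
#' the study the package models (germination rates from 883 and 660 seedlings
#' over 250 seeds x 120 quadrats, ~25% interannual mortality, 30,000 sown
#' seeds, design counts 576 / 470 / 170 / 240, 16 m2 survey area) and, for a
#' report, compares the realized design counts with the closed-form
#' expectations of its configuration.
#'
#' @param report Optionally, a `fire_report`; when supplied its realized
#'   design counts are checked against [design_expectations()].
#' @return A tibble: `target`, `value`, `expected`, `pass`.
#' @export
#' @examples
#' acceptance_check()
acceptance_check <- function(report = NULL) {
  rows <- list(
    tibble(target = "germination_2017_pct",
           value = germination_rate(883, 250, 120), expected = 2.9),
    tibble(target = "germination_2018_pct",
           value = germination_rate(660, 250, 120), expected = 2.2),
    tibble(target = "mortality_pct",
           value = interannual_mortality(883, 660), expected = 25),
    tibble(target = "seedling_density_max",
           value = seedling_density(20, 16), expected = 1.25)
  )
  if (!is.null(report)) {
    exp_counts <- design_expectations(report$study$ground_truth$config)
    got <- report$design_counts
    for (nm in names(exp_counts)) {
      rows <- c(rows, list(tibble(target = nm,
                                  value = as.numeric(got[[nm]]),
                                  expected = as.numeric(exp_counts[[nm]]))))
    }
  } else {
    defaults <- design_expectations(sim_config())
    paper_counts <- c(n_measurement_locations = 576, n_burn_depth_points = 170,
                      n_alt_usable = 470, n_quadrats = 240,
                      seeds_sown = 30000, seedling_survey_area_m2 = 16)
    for (nm in names(paper_counts)) {
      rows <- c(rows, list(tibble(target = nm,
                                  value = as.numeric(defaults[[nm]]),
                                  expected = as.numeric(paper_counts[[nm]]))))
    }
  }
  bind_rows(rows) %>%
    mutate(pass = abs(.data$value - .data$expected) < 1e-9)
}

#' Conservation identities of a report
#'
#' For every burn-depth point and every plot budget, verifies the exact
#' accounting identities: pre-fire SOL depth = burn depth + residual depth;
#' pre-fire carbon = residual + combusted carbon; and
#' prop_from_sol x total combusted = belowground combusted.
#'
#' @param report A `fire_report`.
#' @return A tibble `identity`, `n`, `max_abs_error`, `pass`.
#' @export
conservation_check <- function(report) {
  bd <- report$burn_depth
  bp <- report$below_points
  bu <- report$budgets
  out <- list()
  if (!is.null(bd)) {
    out$depth <- tibble(
      identity = "prefire_depth = burn + residual", n = nrow(bd),
      max_abs_error = max(abs(bd$prefire_cm - bd$bd_cm - bd$residual_cm)))
  }
  if (!is.null(bp)) {
    out$carbon <- tibble(
      identity = "prefire_C = residual + combusted", n = nrow(bp),
      max_abs_error = max(abs(bp$prefire_c - bp$residual_c - bp$combusted_c)))
  }
  if (!is.null(bu)) {
    def <- bu[bu$prop_from_sol_defined, ]
    out$sol <- tibble(
      identity = "prop_from_sol * total = below_combusted", n = nrow(def),
      max_abs_error = max(abs(def$prop_from_sol * def$total_combusted -
                                def$below_combusted)))
  }
  bind_rows(out) %>% mutate(pass = .data$max_abs_error < 1e-9)
}
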