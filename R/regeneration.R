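# Seed-rain rates, seedling densities, and seeding-experiment accounting.

#' Seedling density on an area basis
#'
#' @param count Seedling count (>= 0). @param area Survey area in m2
#'   (default 16 = four 4-m2 quadrats).
#' @return Stems m-2 (vectorized).
#' @export
#' @examples
#' seedling_density(20)  # 1.25 stems m-2
seedling_density <- function(count, area = 16) {
  assert_number(count, "count", lower = 0)
  assert_number(area, "area", lower = 1e-12)
  count / area
}

#' Seed rain rate from trap collections
#'
#' Total seeds over total trap-area x exposure:
#' `sum(counts) / (sum(trap_area * exposure))`, in seeds m-2 yr-1.
#'
#' @param traps Data frame with `seed_count`, `trap_length`, `trap_width` (m)
#'   and `exposure_yr` per trap-collection row.
#' @return The pooled rate (seeds m-2 yr-1).
#' @export
#' @examples
#' seed_rain_rate(data.frame(seed_count = c(3, 4),
#'                           trap_length = 0.54, trap_width = 0.28,
#'                           exposure_yr = 1))
seed_rain_rate <- function(traps) {
  traps <- as_tibble(traps)
  need <- c("seed_count", "trap_length", "trap_width", "exposure_yr")
  if (!all(need %in% names(traps))) {
    abort("`traps` needs seed_count, trap_length, trap_width, exposure_yr.")
  }
  if (nrow(traps) == 0) abort("Need at least one trap record.")
  if (any(traps$exposure_yr <= 0)) abort("Exposures must be positive.")
  if (any(traps$seed_count < 0)) abort("Counts must be >= 0.")
  sum(traps$seed_count) /
    sum(traps$trap_length * traps$trap_width * traps$exposure_yr)
}

#' Viable seed rain
#'
#' @param rate Seed rain (seeds m-2 yr-1, >= 0). @param viability Viable
#'   fraction in `[0, 1]` (default 0.16 from laboratory germination trials).
#' @return Viable seeds m-2 yr-1.
#' @export
viable_seed_rain <- function(rate, viability = 0.16) {
  assert_number(rate, "rate", lower = 0)
  assert_number(viability, "viability", lower = 0, upper = 1)
  rate * viability
}

#' Germination rate of sown seeds
#'
#' `100 * total_seedlings / (seeds_per_quadrat * n_quadrats)`, reported to one
#' decimal place.
#'
#' @param total_seedlings Total seedlings counted. @param seeds_per_quadrat
#'   Seeds sown per quadrat (default 250). @param n_quadrats Number of seeded
#'   quadrats (default 120).
#' @return Percent germination (1 decimal).
#' @export
#' @examples
#' germination_rate(883)  # 2.9
#' germination_rate(660)  # 2.2
germination_rate <- function(total_seedlings, seeds_per_quadrat = 250,
                             n_quadrats = 120) {
  assert_number(total_seedlings, "total_seedlings", lower = 0)
  assert_number(seeds_per_quadrat, "seeds_per_quadrat", lower = 1)
  assert_number(n_quadrats, "n_quadrats", lower = 1)
  round(100 * total_seedlings / (seeds_per_quadrat * n_quadrats), 1)
}

#' Interannual seedling mortality
#'
#' `100 * (n_year1 - n_year2) / n_year1`, to the nearest whole percent.
#' A second-year count exceeding the first is flagged with a warning
#' (recruitment would be confounded with survival) and yields a negative
#' value.
#'
#' @param n_year1,n_year2 Seedling counts in consecutive years (`n_year1` > 0).
#' @return Percent mortality (nearest whole percent).
#' @export
#' @examples
#' interannual_mortality(883, 660)  # 25
interannual_mortality <- function(n_year1, n_year2) {
  assert_number(n_year1, "n_year1", lower = 1e-12)
  assert_number(n_year2, "n_year2", lower = 0)
  if (any(n_year2 > n_year1)) {
    warn("Second-year count exceeds first-year count; mortality is negative.")
  }
  round(100 * (n_year1 - n_year2) / n_year1)
}

#' Summarize the seeding experiment
#'
#' Verifies the factorial design (each seeded x scarified treatment replicated
#' equally, split over burned and control plots), totals seedling counts by
#' treatment and year, and derives germination and mortality rates from the
#' seeded quadrats.
#'
#' @param quadrats Data frame with `plot_id`, `burned`, `seeded`, `scarified`,
#'   `seeds_sown`, `seedlings_2017`, `seedlings_2018`.
#' @return A list of class `regen_summary`: `by_treatment` (totals per
#'   treatment x year), `design` (replicate counts), `germination_2017_pct`,
#'   `germination_2018_pct`, `mortality_pct`, `seeds_sown_total`.
#' @export
experiment_summary <- function(quadrats) {
  quadrats <- as_tibble(quadrats)
  need <- c("plot_id", "burned", "seeded", "scarified", "seeds_sown",
            "seedlings_2017", "seedlings_2018")
  if (!all(need %in% names(quadrats))) {
    abort(sprintf("`quadrats` needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (any(quadrats$seedlings_2017 < 0) || any(quadrats$seedlings_2018 < 0)) {
    abort("Seedling counts must be >= 0.")
  }
  design <- quadrats %>%
    count(.data$seeded, .data$scarified, name = "n_quadrats")
  if (nrow(design) != 4 || dplyr::n_distinct(design$n_quadrats) != 1) {
    abort("Malformed design: the four treatments must be equally replicated.")
  }
  by_treatment <- quadrats %>%
    group_by(.data$seeded, .data$scarified) %>%
    summarise(n_quadrats = n(),
              total_2017 = sum(.data$seedlings_2017),
              total_2018 = sum(.data$seedlings_2018),
              .groups = "drop")
  seeded_q <- quadrats %>% filter(.data$seeded)
  n_seeded <- nrow(seeded_q)
  spq <- unique(seeded_q$seeds_sown)
  if (length(spq) != 1 || spq <= 0) {
    abort("Seeded quadrats must share one positive seeds_sown value.")
  }
  tot1 <- sum(seeded_q$seedlings_2017)
  tot2 <- sum(seeded_q$seedlings_2018)
  structure(list(
    by_treatment = by_treatment,
    design = design,
    seeds_sown_total = spq * n_seeded,
    germination_2017_pct = germination_rate(tot1, spq, n_seeded),
    germination_2018_pct = germination_rate(tot2, spq, n_seeded),
    mortality_pct = if (tot1 > 0) interannual_mortality(tot1, tot2) else
      NA_real_
  ), class = "regen_summary")
}

#' @export
print.regen_summary <- function(x, ...) {
  cat("<regen_summary>\n")
  print(x$by_treatment)
  cat(sprintf("  seeds sown: %d | germination %s%% (yr 1), %s%% (yr 2) | mortality %s%%\n",
              x$seeds_sown_total, x$germination_2017_pct,
              x$germination_2018_pct, x$mortality_pct))
  invisible(x)
}

#' @rdname experiment_summary
#' @param x A `regen_summary`. @param ... Unused.
#' @exportS3Method generics::glance
glance.regen_summary <- function(x, ...) {
  tibble(seeds_sown_total = x$seeds_sown_total,
         germination_2017_pct = x$germination_2017_pct,
         germination_2018_pct = x$germination_2018_pct,
         mortality_pct = x$mortality_pct)
}

#' Treatment-effect plot for the seeding experiment
#'
#' @param quadrats Seeding-quadrat table (see [experiment_summary()]).
#' @return A ggplot of seedling counts by treatment, year and burn status.
#' @export
plot_seeding_experiment <- function(quadrats) {
  long <- as_tibble(quadrats) %>%
    tidyr::pivot_longer(c("seedlings_2017", "seedlings_2018"),
                        names_to = "year", names_prefix = "seedlings_",
                        values_to = "seedlings") %>%
    mutate(treatment = paste0(if_else(.data$seeded, "seeded", "unseeded"),
                              if_else(.data$scarified, "+scarified", "")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$treatment, y = .data$seedlings,
                                     colour = .data$year)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5) +
    ggplot2::facet_wrap(~if_else(.data$burned, "burned", "control")) +
    ggplot2::labs(x = NULL, y = "Seedlings per 0.25 m² quadrat",
                  colour = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
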