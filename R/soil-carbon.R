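# Soil-monolith carbon arithmetic. Canonical units: depth cm, bulk density
# g cm-3, carbon pools kg C m-2 (conversion factor GCM2_TO_KGM2 = 10).

#' Bulk density of a soil increment
#'
#' Dry fine mass divided by the sample volume excluding rock volume.
#'
#' @param increments Data frame with columns `dry_fine_mass` (g),
#'   `sample_volume` (cm3), `rock_volume` (cm3).
#' @return The input as a tibble with a `bulk_density` column (g cm-3).
#' @export
#' @examples
#' bulk_density(data.frame(dry_fine_mass = 7, sample_volume = 50,
#'                         rock_volume = 0))
bulk_density <- function(increments) {
  increments <- as_tibble(increments)
  need <- c("dry_fine_mass", "sample_volume", "rock_volume")
  if (!all(need %in% names(increments))) {
    abort("`increments` needs dry_fine_mass, sample_volume, rock_volume.")
  }
  eff <- increments$sample_volume - increments$rock_volume
  if (any(eff <= 0)) abort("Effective volume (sample - rock) must be > 0.")
  if (any(increments$dry_fine_mass < 0)) abort("Mass must be >= 0.")
  mutate(increments, bulk_density = .data$dry_fine_mass / eff)
}

#' Carbon content of soil increments
#'
#' Increment carbon is thickness x bulk density x fraction carbon, converted
#' from g C cm-2 to kg C m-2 (factor 10).
#'
#' @param increments Data frame with `top_depth`, `bottom_depth` (cm),
#'   `dry_fine_mass`, `sample_volume`, `rock_volume`, `pct_carbon` (fraction).
#' @return The input with `bulk_density` and `carbon_kg_m2` columns.
#' @export
#' @examples
#' increment_carbon(data.frame(top_depth = 0, bottom_depth = 5,
#'                             dry_fine_mass = 35, sample_volume = 250,
#'                             rock_volume = 0, pct_carbon = 0.45))
increment_carbon <- function(increments) {
  increments <- bulk_density(increments)
  need <- c("top_depth", "bottom_depth", "pct_carbon")
  if (!all(need %in% names(increments))) {
    abort("`increments` needs top_depth, bottom_depth, pct_carbon.")
  }
  thick <- increments$bottom_depth - increments$top_depth
  if (any(thick < 0)) abort("bottom_depth must be >= top_depth.")
  if (any(increments$pct_carbon < 0 | increments$pct_carbon > 1)) {
    abort("pct_carbon must be a fraction in [0, 1].")
  }
  mutate(increments,
         carbon_kg_m2 = thick * .data$bulk_density * .data$pct_carbon *
           GCM2_TO_KGM2)
}

#' Cumulative carbon-by-depth profile of monoliths
#'
#' Running sum of increment carbon from the surface down, evaluated at each
#' increment bottom. Increments within a monolith must be contiguous from 0.
#'
#' @param increments Data frame of increments (as for [increment_carbon()])
#'   with `plot_id` and `monolith_id` identifying monoliths.
#' @return A tibble: `plot_id`, `monolith_id`, `depth` (cm), `cum_carbon`
#'   (kg C m-2), one row per increment.
#' @export
cumulative_profile <- function(increments) {
  inc <- increment_carbon(increments)
  if (!all(c("plot_id", "monolith_id") %in% names(inc))) {
    abort("`increments` needs plot_id and monolith_id columns.")
  }
  inc %>%
    group_by(.data$plot_id, .data$monolith_id) %>%
    arrange(.data$top_depth, .by_group = TRUE) %>%
    group_modify(function(df, key) {
      expected_top <- c(0, df$bottom_depth[-nrow(df)])
      if (any(abs(df$top_depth - expected_top) > 1e-6)) {
        abort(sprintf("Monolith %s: increments must be contiguous from 0.",
                      key$monolith_id))
      }
      tibble(depth = df$bottom_depth, cum_carbon = cumsum(df$carbon_kg_m2))
    }) %>%
    ungroup()
}

#' Sum residual and modelled combusted carbon to the pre-fire pool
#'
#' @param residual_c Measured residual SOL carbon (kg C m-2, >= 0).
#' @param combusted_c Modelled combusted carbon (kg C m-2, >= 0).
#' @return Pre-fire SOL carbon, their sum (vectorized).
#' @export
#' @examples
#' prefire_sol_carbon(6, 2)  # 8
prefire_sol_carbon <- function(residual_c, combusted_c) {
  assert_number(residual_c, "residual_c", lower = 0)
  assert_number(combusted_c, "combusted_c", lower = 0)
  residual_c + combusted_c
}

#' @importFrom dplyr group_modify
NULL
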