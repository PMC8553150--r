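# Plot-level carbon-budget assembly and proportional-combustion metrics.
# Units are kg C m-2 throughout.

#' Assemble plot-level carbon budgets
#'
#' Joins aboveground and belowground pools (both kg C m-2) by plot and
#' computes total pre-fire carbon, total combusted carbon, the proportion of
#' total carbon combusted, and the proportion of combusted carbon attributed
#' to the belowground (SOL) component. Plots present in only one input get 0
#' for the missing component.
#'
#' @param above Tibble `plot_id`, `above_prefire`, `above_combusted`.
#' @param below Tibble `plot_id`, `below_prefire`, `below_combusted`
#'   (plot-level means over the plot's point estimates).
#' @return A `carbon_budget` tibble, one row per plot, with
#'   `prop_total_combusted` and `prop_from_sol` (`NA` and flagged via
#'   `prop_from_sol_defined` when nothing combusted).
#' @export
#' @examples
#' assemble_budget(
#'   tibble::tibble(plot_id = "B01", above_prefire = 0.5, above_combusted = 0.3),
#'   tibble::tibble(plot_id = "B01", below_prefire = 8, below_combusted = 2)
#' )
assemble_budget <- function(above, below) {
  above <- as_tibble(above)
  below <- as_tibble(below)
  if (!all(c("plot_id", "above_prefire", "above_combusted") %in% names(above))) {
    abort("`above` needs plot_id, above_prefire, above_combusted.")
  }
  if (!all(c("plot_id", "below_prefire", "below_combusted") %in% names(below))) {
    abort("`below` needs plot_id, below_prefire, below_combusted.")
  }
  out <- dplyr::full_join(above, below, by = "plot_id") %>%
    mutate(across(c("above_prefire", "above_combusted",
                    "below_prefire", "below_combusted"),
                  ~dplyr::coalesce(.x, 0)))
  if (any(out$above_prefire < 0 | out$above_combusted < 0 |
            out$below_prefire < 0 | out$below_combusted < 0)) {
    abort("Carbon pools must be >= 0.")
  }
  if (any(out$above_combusted > out$above_prefire + 1e-9) ||
      any(out$below_combusted > out$below_prefire + 1e-9)) {
    abort("Combusted carbon cannot exceed the pre-fire pool.")
  }
  out <- out %>%
    mutate(
      total_prefire = .data$above_prefire + .data$below_prefire,
      total_combusted = .data$above_combusted + .data$below_combusted,
      prop_total_combusted = .data$total_combusted / .data$total_prefire,
      prop_from_sol = if_else(.data$total_combusted > 0,
                              .data$below_combusted / .data$total_combusted,
                              NA_real_),
      prop_from_sol_defined = .data$total_combusted > 0
    )
  if (any(out$total_prefire <= 0)) {
    abort("Total pre-fire carbon must be positive for every plot.")
  }
  class(out) <- c("carbon_budget", class(out))
  out
}

#' Study-level summary of carbon budgets
#'
#' Mean, standard deviation, minimum, maximum and n for each budget quantity,
#' in the style of a burned-plot characteristics summary table.
#'
#' @param budgets A [assemble_budget()] tibble (or any data frame with the
#'   budget columns).
#' @return A tibble with one row per variable: `variable`, `mean`, `sd`
#'   (`NA` for a single plot), `min`, `max`, `n`.
#' @export
summarize_study <- function(budgets) {
  budgets <- as_tibble(budgets)
  if (nrow(budgets) == 0) abort("Need at least one budget row.")
  vars <- intersect(c("above_prefire", "above_combusted", "below_prefire",
                      "below_combusted", "total_prefire", "total_combusted",
                      "prop_total_combusted", "prop_from_sol"),
                    names(budgets))
  purrr::map_dfr(vars, function(v) {
    x <- budgets[[v]]
    x <- x[!is.na(x)]
    tibble(variable = v, mean = mean(x),
           sd = if (length(x) > 1) sd(x) else NA_real_,
           min = min(x), max = max(x), n = length(x))
  })
}

#' Bar plot of per-plot combusted carbon
#'
#' @param budgets A budget tibble.
#' @return A ggplot: per-plot aboveground and belowground combusted carbon.
#' @export
plot_budget <- function(budgets) {
  long <- as_tibble(budgets) %>%
    select("plot_id", "above_combusted", "below_combusted") %>%
    tidyr::pivot_longer(-"plot_id", names_to = "pool",
                        values_to = "combusted")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$plot_id, y = .data$combusted,
                                     fill = .data$pool)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Combusted carbon (kg C m⁻²)",
                  fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
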