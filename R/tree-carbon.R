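# Aboveground biomass via configurable power-law allometry and
# combustion-class carbon-loss accounting. Biomass carbon content is 50%.

C_FRACTION_BIOMASS <- 0.5
TREE_COMPONENTS <- c("total", "bark", "main_branches", "fine_branches",
                     "foliage")

#' Default allometry coefficient table
#'
#' Power-law coefficients `mass = a * diameter^b` (kg dry matter, diameter in
#' cm) per species and component. These are synthetic, literature-style
#' placeholder values for *Picea*; real applications should supply the
#' coefficients appropriate to their region and diameter convention via
#' `allometry_table()`.
#'
#' @return A tibble: `species`, `component`, `a`, `b`.
#' @export
default_allometry <- function() {
  comp <- function(species, a_total) {
    # component shares roughly: bark 10%, main branches 15%, fine 10%,
    # foliage 15% of total at reference diameter; same exponent
    tibble(species = species,
           component = TREE_COMPONENTS,
           a = a_total * c(1, 0.10, 0.15, 0.10, 0.15),
           b = 2.2)
  }
  bind_rows(comp("black spruce", 0.11), comp("white spruce", 0.13),
            comp("other", 0.10))
}

#' Validate an allometry table
#'
#' @param table Data frame with `species`, `component`, `a`, `b`.
#' @return The table as a tibble, after checks (`a > 0`; a warning if
#'   component masses could exceed the total at 10 cm diameter).
#' @export
allometry_table <- function(table) {
  table <- as_tibble(table)
  if (!all(c("species", "component", "a", "b") %in% names(table))) {
    abort("Allometry table needs species, component, a, b.")
  }
  if (any(table$a <= 0)) abort("Allometry coefficient `a` must be > 0.")
  chk <- table %>%
    mutate(m10 = .data$a * 10^.data$b) %>%
    group_by(.data$species) %>%
    summarise(
      total = sum(.data$m10[.data$component == "total"]),
      parts = sum(.data$m10[.data$component != "total"]),
      .groups = "drop"
    )
  if (any(chk$parts > chk$total + 1e-9)) {
    warn("Component masses exceed total-tree mass for some species.")
  }
  table
}

#' Default combustion rule
#'
#' Fraction of each biomass component combusted per combustion class:
#' class 0 none; class 1 all foliage; class 2 all foliage and half the fine
#' branches; class 3 all foliage, fine branches, main branches and bark.
#' Fractions are monotone non-decreasing across classes.
#'
#' @return A tibble: `combustion_class`, `component`, `fraction`.
#' @export
default_combustion_rule <- function() {
  tidyr::expand_grid(combustion_class = 0:3,
                     component = setdiff(TREE_COMPONENTS, "total")) %>%
    mutate(fraction = dplyr::case_when(
      .data$combustion_class == 0 ~ 0,
      .data$component == "foliage" ~ 1,
      .data$component == "fine_branches" & .data$combustion_class == 2 ~ 0.5,
      .data$component == "fine_branches" & .data$combustion_class == 3 ~ 1,
      .data$combustion_class == 3 ~ 1,
      TRUE ~ 0
    ))
}

#' @noRd
check_combustion_rule <- function(rule) {
  rule <- as_tibble(rule)
  if (!all(c("combustion_class", "component", "fraction") %in% names(rule))) {
    abort("Combustion rule needs combustion_class, component, fraction.")
  }
  if (any(rule$fraction < 0 | rule$fraction > 1)) {
    abort("Combustion fractions must lie in [0, 1].")
  }
  mono <- rule %>%
    arrange(.data$component, .data$combustion_class) %>%
    group_by(.data$component) %>%
    summarise(ok = all(diff(.data$fraction) >= -1e-12), .groups = "drop")
  if (!all(mono$ok)) {
    abort("Combustion fractions must be non-decreasing across classes.")
  }
  rule
}

#' Per-component tree biomass
#'
#' Evaluates the power-law allometry for each tree and component.
#'
#' @param trees Data frame with `species` and `diameter` (cm, > 0); other
#'   columns are carried through.
#' @param table Allometry table (default [default_allometry()]).
#' @return A tibble: the tree columns plus `component` and `mass_kg`, one row
#'   per tree x component.
#' @export
#' @examples
#' tree_biomass(data.frame(species = "black spruce", diameter = 3))
tree_biomass <- function(trees, table = default_allometry()) {
  trees <- as_tibble(trees)
  table <- allometry_table(table)
  if (!all(c("species", "diameter") %in% names(trees))) {
    abort("`trees` needs species and diameter columns.")
  }
  if (any(trees$diameter <= 0)) abort("Diameters must be > 0.")
  missing <- setdiff(unique(trees$species), unique(table$species))
  if (length(missing)) {
    abort(sprintf("No allometry for species: %s.",
                  paste(missing, collapse = ", ")))
  }
  trees %>%
    mutate(.tree_row = row_number()) %>%
    left_join(table, by = "species", relationship = "many-to-many") %>%
    mutate(mass_kg = .data$a * .data$diameter^.data$b) %>%
    select(-"a", -"b")
}

#' Combusted carbon per tree from combustion class
#'
#' Applies the combustion rule: combusted carbon is the sum over non-total
#' components of `fraction(class) * mass * 0.5` (50% carbon content).
#'
#' @param biomass Output of [tree_biomass()], needing also a
#'   `combustion_class` column (0-3).
#' @param rule Combustion rule table (default [default_combustion_rule()]).
#' @return One row per tree: original columns plus `prefire_c_kg` (total-tree
#'   carbon) and `combusted_c_kg`.
#' @export
tree_combusted_carbon <- function(biomass, rule = default_combustion_rule()) {
  biomass <- as_tibble(biomass)
  rule <- check_combustion_rule(rule)
  if (!"combustion_class" %in% names(biomass)) {
    abort("`biomass` needs a combustion_class column.")
  }
  if (!all(biomass$combustion_class %in% unique(rule$combustion_class))) {
    abort("Combustion rule does not cover all classes present.")
  }
  if (!".tree_row" %in% names(biomass)) {
    biomass <- mutate(biomass, .tree_row = row_number())
  }
  comps <- setdiff(unique(biomass$component), "total")
  covered <- rule %>% count(.data$combustion_class) %>% pull(n)
  if (any(covered < length(comps))) {
    abort("Combustion rule is incomplete for some classes.")
  }
  combusted <- biomass %>%
    filter(.data$component != "total") %>%
    left_join(rule, by = c("combustion_class", "component")) %>%
    group_by(.data$.tree_row) %>%
    summarise(combusted_c_kg = sum(.data$fraction * .data$mass_kg) *
                C_FRACTION_BIOMASS, .groups = "drop")
  prefire <- biomass %>%
    filter(.data$component == "total") %>%
    mutate(prefire_c_kg = .data$mass_kg * C_FRACTION_BIOMASS) %>%
    select(-"component", -"mass_kg")
  out <- left_join(prefire, combusted, by = ".tree_row") %>%
    mutate(combusted_c_kg = dplyr::coalesce(.data$combusted_c_kg, 0),
           combusted_c_kg = pmin(.data$combusted_c_kg, .data$prefire_c_kg)) %>%
    select(-".tree_row")
  out
}

#' Area-based aboveground carbon pools per plot
#'
#' Sums per-tree pre-fire and combusted carbon over each plot and divides by
#' the plot area.
#'
#' @param trees Tree census: `plot_id`, `species`, `diameter`,
#'   `combustion_class`.
#' @param table Allometry table. @param rule Combustion rule.
#' @param plot_area Plot area in m2 (default 201).
#' @return A tibble: `plot_id`, `above_prefire`, `above_combusted`
#'   (kg C m-2).
#' @export
plot_aboveground_pools <- function(trees, table = default_allometry(),
                                   rule = default_combustion_rule(),
                                   plot_area = 201) {
  assert_number(plot_area, "plot_area", lower = 1e-9)
  trees <- as_tibble(trees)
  if (is.null(trees) || nrow(trees) == 0) {
    return(tibble(plot_id = character(0), above_prefire = numeric(0),
                  above_combusted = numeric(0)))
  }
  tree_biomass(trees, table) %>%
    tree_combusted_carbon(rule) %>%
    group_by(.data$plot_id) %>%
    summarise(above_prefire = sum(.data$prefire_c_kg) / plot_area,
              above_combusted = sum(.data$combusted_c_kg) / plot_area,
              .groups = "drop")
}
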