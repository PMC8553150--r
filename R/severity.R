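# Topo-edaphic metrics and burn-depth reconstruction from biometric proxies.

#' Equivalent latitude of a slope
#'
#' Latitude of a horizontal surface receiving the same solar insolation as the
#' measured slope/aspect, from the classical spherical rotation
#' `asin(sin(i) * cos(a) * cos(lat) + cos(i) * sin(lat))` with inclination `i`
#' and aspect `a` measured clockwise from north. Flat ground returns the
#' plot latitude unchanged; north-facing slopes steepen (higher equivalent
#' latitude, less insolation), south-facing slopes flatten.
#'
#' @param slope Slope inclination in degrees, `[0, 90)`.
#' @param aspect Aspect in degrees clockwise from north, `[0, 360)`.
#' @param latitude Geographic latitude in degrees.
#' @return Equivalent latitude in degrees (vectorized).
#' @export
#' @examples
#' equivalent_latitude(0, 120, 63.7)   # 63.7: flat ground identity
#' equivalent_latitude(10, 0, 63)      # ~73: north-facing
#' equivalent_latitude(10, 180, 63)    # ~53: south-facing
equivalent_latitude <- function(slope, aspect, latitude) {
  assert_number(slope, "slope", lower = 0, upper = 90 - 1e-9)
  assert_number(aspect, "aspect", lower = 0, upper = 360 - 1e-9)
  assert_number(latitude, "latitude", lower = -90, upper = 90)
  i <- deg2rad(slope)
  a <- deg2rad(aspect)
  l <- deg2rad(latitude)
  rad2deg(asin(pmin(pmax(sin(i) * cos(a) * cos(l) + cos(i) * sin(l), -1), 1)))
}

#' Classify pre-fire conifer density
#'
#' Three-way classification used throughout the analysis: low = 0 stems m-2,
#' medium = 0.0001 to 0.0249 stems m-2, high = more than 0.0249 stems m-2.
#'
#' @param density Stem density in stems m-2 (vectorized, >= 0).
#' @return A factor with levels `low`, `medium`, `high`.
#' @export
#' @examples
#' classify_density(c(0, 0.01, 0.05))
classify_density <- function(density) {
  assert_number(density, "density", lower = 0)
  factor(dplyr::case_when(
    density < 1e-4 ~ "low",
    density <= 0.0249 ~ "medium",
    TRUE ~ "high"
  ), levels = c("low", "medium", "high"))
}

#' Calibrate burn-depth offsets from unburned proxy measurements
#'
#' In unburned plots the depth of black-spruce adventitious roots below the
#' green moss surface and the tussock crown height above it are measured; their
#' arithmetic means are the offsets added to (ARH) or subtracted from (TCH)
#' burned-plot proxy heights to reconstruct burn depth.
#'
#' @param proxies A data frame of unburned proxy measurements with columns
#'   `context` (`"unburned"`), `proxy` (`"arh"` or `"tch"`), and `value_cm`.
#' @return A one-row tibble: `arh_offset`, `tch_offset` (cm), their standard
#'   errors (`NA` when fewer than two measurements), and counts.
#' @export
#' @examples
#' calibrate_offsets(data.frame(context = "unburned",
#'                              proxy = c("arh", "arh", "tch", "tch"),
#'                              value_cm = c(2.19, 2.19, 10, 13.02)))
calibrate_offsets <- function(proxies) {
  proxies <- as_tibble(proxies)
  need <- c("context", "proxy", "value_cm")
  if (!all(need %in% names(proxies))) {
    abort("`proxies` needs columns context, proxy, value_cm.")
  }
  unb <- proxies %>% filter(.data$context == "unburned")
  if (nrow(unb) == 0) abort("No unburned proxy measurements supplied.")
  if (any(unb$value_cm < 0) || anyNA(unb$value_cm)) {
    abort("Proxy measurements must be non-negative and non-missing.")
  }
  one <- function(p) {
    v <- unb$value_cm[unb$proxy == p]
    tibble(offset = if (length(v)) mean(v) else NA_real_,
           se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
           n = length(v))
  }
  a <- one("arh")
  t <- one("tch")
  if (a$n == 0 && t$n == 0) abort("Need at least one ARH or TCH measurement.")
  tibble(arh_offset = a$offset, arh_se = a$se, n_arh = a$n,
         tch_offset = t$offset, tch_se = t$se, n_tch = t$n)
}

#' Reconstruct burn depth from burned-plot proxies
#'
#' Per sampling point, individual proxy heights are averaged, then the ARH
#' calibration offset is added (roots sit below the pre-fire surface) and the
#' TCH offset subtracted (tussock crowns sit above it). When both proxies are
#' present the burn depth is the mean of the two estimates. TCH-derived depths
#' below zero are floored at 0 and flagged, since burn depth is physically
#' non-negative.
#'
#' @param proxies Data frame of burned-context measurements with columns
#'   `plot_id`, `point_id`, `context`, `proxy`, `value_cm`.
#' @param calibration A one-row tibble from [calibrate_offsets()].
#' @return A tibble with one row per sampling point: `plot_id`, `point_id`,
#'   `method` (`"ARH"`, `"TCH"` or `"mean"`), `bd_cm`, and `floored` flag.
#' @export
#' @examples
#' cal <- tibble::tibble(arh_offset = 2.19, tch_offset = 11.51)
#' estimate_burn_depth(data.frame(plot_id = "B01", point_id = "B01-01",
#'                                context = "burned", proxy = "arh",
#'                                value_cm = 8), cal)
estimate_burn_depth <- function(proxies, calibration) {
  proxies <- as_tibble(proxies)
  need <- c("plot_id", "point_id", "context", "proxy", "value_cm")
  if (!all(need %in% names(proxies))) {
    abort("`proxies` needs columns plot_id, point_id, context, proxy, value_cm.")
  }
  if (any(proxies$context != "burned")) {
    abort("Burn depth is only defined for burned-context measurements.")
  }
  if (nrow(proxies) == 0) abort("No proxy measurements supplied.")
  if (any(proxies$value_cm < 0)) abort("Proxy heights must be >= 0.")

  per_point <- proxies %>%
    group_by(.data$plot_id, .data$point_id, .data$proxy) %>%
    summarise(mean_cm = mean(.data$value_cm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "proxy", values_from = "mean_cm")
  if (!"arh" %in% names(per_point)) per_point$arh <- NA_real_
  if (!"tch" %in% names(per_point)) per_point$tch <- NA_real_

  o_a <- calibration$arh_offset[1]
  o_t <- calibration$tch_offset[1]
  if (any(!is.na(per_point$arh)) && is.na(o_a)) {
    abort("ARH measurements present but no ARH offset calibrated.")
  }
  if (any(!is.na(per_point$tch)) && is.na(o_t)) {
    abort("TCH measurements present but no TCH offset calibrated.")
  }

  per_point %>%
    mutate(
      bd_arh = .data$arh + o_a,
      bd_tch_raw = .data$tch - o_t,
      bd_tch = pmax(.data$bd_tch_raw, 0),
      floored = !is.na(.data$bd_tch_raw) & .data$bd_tch_raw < 0,
      method = dplyr::case_when(
        !is.na(.data$bd_arh) & !is.na(.data$bd_tch) ~ "mean",
        !is.na(.data$bd_arh) ~ "ARH",
        TRUE ~ "TCH"
      ),
      bd_cm = dplyr::case_when(
        method == "mean" ~ (.data$bd_arh + .data$bd_tch) / 2,
        method == "ARH" ~ .data$bd_arh,
        TRUE ~ .data$bd_tch
      )
    ) %>%
    select("plot_id", "point_id", "method", "bd_cm", "floored")
}

#' Partition the pre-fire soil organic layer
#'
#' Pre-fire SOL depth is the sum of burn depth and residual SOL depth; the
#' proportion combusted is burn depth over pre-fire depth.
#'
#' @param bd Burn depth (cm, >= 0). @param residual Residual SOL depth
#'   (cm, >= 0). Vectorized; `bd + residual` must be positive.
#' @return A tibble with `prefire_cm` and `prop_combusted`.
#' @export
#' @examples
#' sol_partition(10, 15)  # 25 cm pre-fire, 40% combusted
sol_partition <- function(bd, residual) {
  assert_number(bd, "bd", lower = 0)
  assert_number(residual, "residual", lower = 0)
  if (any(bd + residual <= 0)) {
    abort("Proportion combusted is undefined when bd + residual = 0.")
  }
  tibble(prefire_cm = bd + residual,
         prop_combusted = bd / (bd + residual))
}

#' Burn-depth table for a whole study
#'
#' Convenience wrapper: calibrates offsets from unburned measurements,
#' reconstructs burn depth at every burned point with proxies, and joins the
#' residual SOL depth to partition the pre-fire SOL.
#'
#' @param proxies Proxy measurement table (burned and unburned contexts).
#' @param points Point table with `point_id` and `residual_cm`.
#' @return A tibble: `plot_id`, `point_id`, `method`, `bd_cm`, `residual_cm`,
#'   `prefire_cm`, `prop_combusted`, `floored`.
#' @export
burn_depth_table <- function(proxies, points) {
  cal <- calibrate_offsets(proxies)
  est <- estimate_burn_depth(filter(as_tibble(proxies),
                                    .data$context == "burned"), cal)
  est %>%
    left_join(select(as_tibble(points), "point_id", "residual_cm"),
              by = "point_id") %>%
    mutate(sol_partition(.data$bd_cm, .data$residual_cm))
}
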