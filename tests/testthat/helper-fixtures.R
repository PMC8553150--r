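# Fixtures built in code, shared across test files.

# Increment table with prescribed bulk density and %C per 5-cm slice.
make_increments <- function(bd, pct, thickness = rep(5, length(bd)),
                            plot_id = "P1", monolith_id = "M1") {
  bottom <- cumsum(thickness)
  top <- bottom - thickness
  vol <- 50 * thickness
  tibble::tibble(
    plot_id = plot_id, monolith_id = monolith_id,
    top_depth = top, bottom_depth = bottom,
    dry_fine_mass = bd * vol, sample_volume = vol, rock_volume = 0,
    pct_carbon = pct
  )
}

# Long-format proxy rows for one sampling point.
make_proxy <- function(values, proxy, context = "burned",
                       plot_id = "B01", point_id = "B01-01") {
  tibble::tibble(plot_id = plot_id, point_id = point_id, context = context,
                 proxy = proxy, value_cm = values)
}

# Anderson pseudo-F computed independently from first principles, used as
# the brute-force oracle for permanova tests.
oracle_pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    sub <- d2[i, i, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
  }
  k <- length(unique(groups))
  list(F = ((sst - ssw) / (k - 1)) / (ssw / (n - k)),
       R2 = (sst - ssw) / sst)
}
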