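# Community-change statistics: line-point-intercept cover, rare-species
# augmentation, Bray-Curtis distance, presence-absence turnover, and a
# strata-respecting permutational MANOVA on a distance matrix.

LPI_BANDS <- c(">4m", "3-4m", "2-3m", "1-2m", "0.5-1m", "30-50cm", "20-30cm",
               "10-20cm", "0-10cm")

#' Species percent cover from line-point-intercept pin drops
#'
#' Cover of a species is 100 x (number of pins at which the species was hit in
#' at least one height band) / (total pins). A species hit in several bands at
#' the same pin counts once. The default plot design drops 56 pins (32 on the
#' west-east transect, 24 on the north-south transect).
#'
#' @param pins Data frame of pin hits: `pin_id` (unique per pin drop), `band`,
#'   `species`; pins with no hits may appear with `species = NA`.
#' @param n_pins Total pins dropped (default 56); must be >= the number of
#'   distinct pins in `pins`.
#' @return A tibble `species`, `cover` (percent).
#' @export
#' @examples
#' lpi_cover(data.frame(pin_id = 1:2, band = "0-10cm",
#'                      species = c("sp1", "sp1")), n_pins = 56)
lpi_cover <- function(pins, n_pins = 56) {
  pins <- as_tibble(pins)
  if (!all(c("pin_id", "band", "species") %in% names(pins))) {
    abort("`pins` needs pin_id, band, species.")
  }
  if (nrow(pins) == 0) abort("Empty pin-drop table.")
  bad <- setdiff(unique(stats::na.omit(pins$band)), LPI_BANDS)
  if (length(bad)) {
    abort(sprintf("Unknown height band(s): %s.", paste(bad, collapse = ", ")))
  }
  n_obs <- dplyr::n_distinct(pins$pin_id)
  if (n_pins < n_obs) abort("`n_pins` is smaller than the pins observed.")
  pins %>%
    filter(!is.na(.data$species)) %>%
    distinct(.data$pin_id, .data$species) %>%
    count(.data$species, name = "hits") %>%
    mutate(cover = 100 * .data$hits / n_pins) %>%
    select("species", "cover")
}

#' Add occurrence-only species at a small cover value
#'
#' Species recorded in the full occurrence list but never hit by a pin are
#' appended with 0.5% cover; species already present keep their cover.
#'
#' @param cover Tibble `species`, `cover`. @param occurrences Character vector
#'   of species observed in the plot.
#' @param rare_cover Cover assigned to occurrence-only species (default 0.5).
#' @return The augmented cover tibble.
#' @export
augment_rare_species <- function(cover, occurrences, rare_cover = 0.5) {
  cover <- as_tibble(cover)
  extra <- setdiff(occurrences, cover$species)
  if (length(extra) == 0) return(cover)
  bind_rows(cover, tibble(species = extra, cover = rare_cover))
}

#' Bray-Curtis dissimilarity between two cover vectors
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`: 0 for identical assemblages, 1
#' for disjoint ones.
#'
#' @param x,y Non-negative cover vectors of equal length (matched species).
#' @return The dissimilarity.
#' @export
#' @examples
#' bray_curtis(c(3, 0, 1), c(1, 2, 1))  # 0.5
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (any(x < 0) || any(y < 0) || anyNA(x) || anyNA(y)) {
    abort("Cover values must be non-negative and non-missing.")
  }
  tot <- sum(x + y)
  if (tot == 0) abort("Bray-Curtis is undefined for two all-zero vectors.")
  sum(abs(x - y)) / tot
}

#' Presence-absence species turnover between two samplings
#'
#' Converts cover to presence-absence and returns
#' (species gained + species lost) / richness of the union, in `[0, 1]`:
#' 0 = no change in composition, 1 = complete change.
#'
#' @param pre,post Named or positionally matched cover vectors for the same
#'   species universe.
#' @return The turnover index.
#' @export
#' @examples
#' turnover_index(c(A = 1, B = 2, C = 3, D = 0), c(A = 0, B = 9, C = 1, D = 2))
turnover_index <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort("`pre` and `post` must cover the same species universe.")
  }
  if (!is.null(names(pre)) && !is.null(names(post))) {
    if (!setequal(names(pre), names(post))) {
      abort("`pre` and `post` must share species names.")
    }
    post <- post[names(pre)]
  }
  p1 <- pre > 0
  p2 <- post > 0
  union_n <- sum(p1 | p2)
  if (union_n == 0) abort("Both assemblages are empty.")
  (sum(p2 & !p1) + sum(p1 & !p2)) / union_n
}

# All permutations of 1..n (small n only).
#' @noRd
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

# Every admissible within-strata permutation (index vectors), identity
# included. Only called when the total count is small.
#' @noRd
strata_permutations <- function(idx_by_stratum, n) {
  per <- lapply(idx_by_stratum, function(idx) {
    lapply(all_perms(length(idx)), function(p) idx[p])
  })
  combos <- expand.grid(lapply(per, seq_along))
  lapply(seq_len(nrow(combos)), function(r) {
    perm <- integer(n)
    for (s in seq_along(per)) {
      perm[idx_by_stratum[[s]]] <- per[[s]][[combos[r, s]]]
    }
    perm
  })
}

# Anderson pseudo-F partition of a squared distance matrix.
#' @noRd
permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  levs <- unique(groups)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in levs) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssa <- sst - ssw
  k <- length(levs)
  f <- (ssa / (k - 1)) / (ssw / (n - k))
  c(F = f, R2 = ssa / sst, SSA = ssa, SSW = ssw, SST = sst)
}

#' Permutational MANOVA with within-strata permutations
#'
#' Partitions the total sum of squared inter-site distances among and within
#' groups, forms the pseudo-F statistic, and obtains its permutation p-value
#' by shuffling group labels only within strata (e.g. pre/post labels within
#' each paired grid point). The p-value uses the add-one correction
#' `(1 + #(F* >= F)) / (1 + n_perm)`, so it is never zero; permuted statistics
#' tying the observed one count as exceedances. When the admissible
#' permutation group is no larger than `n_perm` it is enumerated exhaustively
#' and the p-value is exact (`#(F* >= F) / #permutations`, identity included).
#'
#' @param dist A `dist` object or symmetric distance matrix with zero
#'   diagonal.
#' @param groups Group labels (>= 2 groups).
#' @param strata Optional strata labels; permutations exchange labels only
#'   within a stratum. `NULL` for free permutation.
#' @param n_perm Number of permutations (default 999, >= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `permanova_result` tibble: `pseudo_F`, `R2`, `p_value`, `df_among`,
#'   `df_within`, `n_perm` (permutations actually used), `exhaustive`, `seed`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), nrow = 8)
#' permanova(dist(x), groups = rep(c("a", "b"), 4),
#'           strata = rep(1:4, each = 2), n_perm = 199, seed = 1)
permanova <- function(dist, groups, strata = NULL, n_perm = 999, seed = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || any(abs(diag(d)) > 1e-12) ||
      any(abs(d - t(d)) > 1e-8)) {
    abort("`dist` must be a symmetric distance matrix with zero diagonal.")
  }
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) abort("`groups` must match the distance matrix.")
  if (length(unique(groups)) < 2) abort("Need at least two groups.")
  if (n_perm < 99) abort("Use at least 99 permutations.")
  if (!is.null(strata)) {
    strata <- as.character(strata)
    if (length(strata) != n) abort("`strata` must match the distance matrix.")
    mixed <- any(vapply(split(groups, strata),
                        function(g) length(unique(g)) > 1, logical(1)))
    if (!mixed) {
      abort("Groups are constant within every stratum: no admissible permutation.")
    }
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  d2 <- d^2
  obs <- permanova_stat(d2, groups)
  idx_by_stratum <- if (is.null(strata)) list(seq_len(n)) else
    split(seq_len(n), strata)
  # exhaustive enumeration when the admissible permutation group is small:
  # the p-value is then exact (identity included, so p > 0)
  n_total <- prod(factorial(lengths(idx_by_stratum)))
  exhaustive <- is.finite(n_total) && n_total <= n_perm
  if (exhaustive) {
    perms <- strata_permutations(idx_by_stratum, n)
    fs <- vapply(perms,
                 function(p) permanova_stat(d2, groups[p])[["F"]],
                 numeric(1))
    exceed <- sum(fs >= obs[["F"]] - 1e-12)
    p_value <- exceed / length(perms)
    n_used <- length(perms)
  } else {
    exceed <- 0L
    perm <- integer(n)
    for (b in seq_len(n_perm)) {
      for (idx in idx_by_stratum) {
        perm[idx] <- if (length(idx) > 1) idx[sample.int(length(idx))] else idx
      }
      f_b <- permanova_stat(d2, groups[perm])[["F"]]
      if (f_b >= obs[["F"]] - 1e-12) exceed <- exceed + 1L
    }
    p_value <- (1 + exceed) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  k <- length(unique(groups))
  out <- tibble(
    pseudo_F = obs[["F"]], R2 = obs[["R2"]],
    p_value = p_value,
    df_among = k - 1, df_within = n - k,
    n_perm = n_used, exhaustive = exhaustive,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(out) <- c("permanova_result", class(out))
  out
}

#' @rdname permanova
#' @param x A `permanova_result`. @param ... Unused.
#' @exportS3Method generics::tidy
tidy.permanova_result <- function(x, ...) {
  tibble(term = "groups", statistic = x$pseudo_F, R2 = x$R2,
         p.value = x$p_value, df = x$df_among)
}

#' Community change per site
#'
#' Computes the Bray-Curtis pre/post distance and the presence-absence
#' turnover index for every site of a paired pair of wide community matrices.
#'
#' @param pre,post Wide community matrices: `plot_id` plus one column per
#'   species (shared universe).
#' @return A tibble: `plot_id`, `bray_curtis`, `turnover`.
#' @export
community_change <- function(pre, post) {
  pre <- as_tibble(pre)
  post <- as_tibble(post)
  sp <- setdiff(names(pre), "plot_id")
  if (!setequal(sp, setdiff(names(post), "plot_id"))) {
    abort("`pre` and `post` must share a species universe.")
  }
  post <- post[match(pre$plot_id, post$plot_id), ]
  purrr::map_dfr(seq_len(nrow(pre)), function(i) {
    x <- as.numeric(pre[i, sp])
    y <- as.numeric(post[i, sp])
    tibble(plot_id = pre$plot_id[i],
           bray_curtis = bray_curtis(x, y),
           turnover = turnover_index(x, y))
  })
}
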