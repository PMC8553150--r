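# Internal helpers shared across modules.

# Unit conversion: g C cm-2 -> kg C m-2. thickness(cm) * bulk density(g cm-3)
# * fraction C gives g C cm-2; multiplying by 1e4 cm2 m-2 / 1e3 g kg-1 = 10.
GCM2_TO_KGM2 <- 10

MOISTURE_LEVELS <- c("mesic", "mesic-subhygric", "subhygric")

#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) == 0) || anyNA(x)) {
    abort(sprintf("`%s` must be a non-missing numeric value.", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort(sprintf("`%s` must lie in [%s, %s].", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

#' @noRd
assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Normal left-truncated at zero; degenerate sd = 0 returns the mean
# (which must itself be >= 0 to respect the truncation).
#' @noRd
rtruncnorm0 <- function(n, mean, sd) {
  if (any(sd < 0)) abort("`sd` must be >= 0.")
  if (all(sd == 0)) return(rep_len(pmax(mean, 0), n))
  lo <- pnorm(0, mean = mean, sd = sd)
  u <- runif(n, min = lo, max = 1)
  qnorm(u, mean = mean, sd = sd)
}

# NB1 (variance = mu * (1 + alpha)): gamma-Poisson mixture with
# shape mu / alpha. NB2 (variance = mu + mu^2 / theta): size = theta.
#' @noRd
rnb1 <- function(n, mu, alpha) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  if (alpha <= 0) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- rnbinom(sum(pos), size = mu[pos] / alpha, mu = mu[pos])
  }
  out
}

#' @noRd
rnb2 <- function(n, mu, theta) {
  mu <- rep_len(mu, n)
  out <- integer(n)
  pos <- mu > 0
  out[pos] <- rnbinom(sum(pos), size = theta, mu = mu[pos])
  out
}

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
rad2deg <- function(x) x * 180 / pi
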