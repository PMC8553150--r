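test_that("LPI cover counts each pin once per species", {
  pins <- tibble::tibble(pin_id = 1:28, band = "0-10cm", species = "sp1")
  expect_equal(lpi_cover(pins, n_pins = 56)$cover, 50)

  # same pin, two bands: still one hit
  multi <- tibble::tibble(pin_id = c(1, 1), band = c("0-10cm", "30-50cm"),
                          species = "sp1")
  expect_equal(lpi_cover(multi, n_pins = 56)$cover, 100 / 56)

  # full synthetic table against a brute-force tally
  set.seed(17)
  tab <- tidyr::expand_grid(pin_id = 1:56, band = c("0-10cm", "10-20cm")) %>%
    dplyr::mutate(species = sample(c("a", "b", "c", NA), 112, replace = TRUE))
  got <- lpi_cover(tab, n_pins = 56)
  for (sp in c("a", "b", "c")) {
    hand <- length(unique(tab$pin_id[!is.na(tab$species) &
                                       tab$species == sp]))
    expect_equal(got$cover[got$species == sp], 100 * hand / 56)
  }
  expect_error(lpi_cover(tab[0, ]))
  expect_error(lpi_cover(tibble::tibble(pin_id = 1, band = "5m",
                                        species = "a")))
})

test_that("rare species are added at half a percent", {
  cov <- tibble::tibble(species = c("a", "b"), cover = c(10, 3))
  out <- augment_rare_species(cov, c("a", "c"))
  expect_equal(out$cover[out$species == "a"], 10)
  expect_equal(out$cover[out$species == "c"], 0.5)
  expect_identical(augment_rare_species(cov, character(0)), cov)
})

test_that("Bray-Curtis follows the formula and its axioms", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(3, 0, 1), c(1, 2, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)))
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)))
  expect_error(bray_curtis(c(-1, 2), c(1, 2)))

  set.seed(18)
  for (i in 1:200) {
    x <- runif(10, 0, 5) * rbinom(10, 1, 0.7)
    y <- runif(10, 0, 5) * rbinom(10, 1, 0.7)
    if (sum(x + y) == 0) next
    d <- bray_curtis(x, y)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    expect_equal(bray_curtis(x, x), 0)
  }
})

test_that("turnover uses presence-absence over the union richness", {
  expect_equal(turnover_index(c(1, 2, 3), c(4, 5, 6)), 0)
  expect_equal(turnover_index(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  # {A,B,C} -> {B,C,D}: one gain + one loss over union of 4
  expect_equal(turnover_index(c(A = 1, B = 1, C = 1, D = 0),
                              c(A = 0, B = 1, C = 1, D = 1)), 0.5)
  # invariant to cover magnitude
  expect_equal(turnover_index(c(9, 0.4, 0, 0), c(0, 88, 1, 0)),
               turnover_index(c(1, 1, 0, 0), c(0, 1, 1, 0)))
  expect_error(turnover_index(c(0, 0), c(0, 0)))
})

test_that("permanova pseudo-F and R2 match brute force and vegan", {
  set.seed(19)
  x <- matrix(abs(rnorm(60)), nrow = 10)
  g <- rep(c("a", "b"), 5)
  d <- dist(x)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  oracle <- oracle_pseudo_f(d, g)
  expect_equal(res$pseudo_F, oracle$F)
  expect_equal(res$R2, oracle$R2)
  expect_gte(res$R2, 0)
  expect_lte(res$R2, 1)

  skip_if_not_installed("vegan")
  va <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(res$pseudo_F, va$F[1], tolerance = 1e-10)
  expect_equal(res$R2, va$R2[1], tolerance = 1e-10)
})

test_that("within-strata p-value is exact against full enumeration", {
  set.seed(20)
  x <- matrix(rnorm(18), nrow = 6)
  d <- dist(x)
  g <- rep(c("pre", "post"), 3)
  s <- rep(1:3, each = 2)
  res <- permanova(d, g, strata = s, n_perm = 999)
  expect_true(res$exhaustive)

  # independent enumeration of the 2^3 within-pair swaps
  obs <- oracle_pseudo_f(d, g)$F
  fs <- c()
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    gg <- g
    if (b1) gg[1:2] <- gg[2:1]
    if (b2) gg[3:4] <- gg[4:3]
    if (b3) gg[5:6] <- gg[6:5]
    fs <- c(fs, oracle_pseudo_f(d, gg)$F)
  }
  expect_equal(res$p_value, mean(fs >= obs - 1e-12))
})

test_that("separated clusters attain the minimum p-value", {
  x <- rbind(matrix(rnorm(30, 0, 0.1), nrow = 6),
             matrix(rnorm(30, 50, 0.1), nrow = 6))
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(dist(x), g, n_perm = 199, seed = 2)
  expect_equal(res$p_value, 1 / 200)
})

test_that("degenerate permanova inputs are rejected", {
  d <- dist(matrix(rnorm(12), nrow = 4))
  expect_error(permanova(d, rep("a", 4), n_perm = 99))
  # strata confounded with groups: no admissible permutation
  expect_error(permanova(d, c("a", "a", "b", "b"), strata = c(1, 1, 2, 2),
                         n_perm = 99))
  expect_error(permanova(d, c("a", "b", "a", "b"), n_perm = 10))
})

test_that("permanova holds its size under a simulated null", {
  set.seed(23)
  rejections <- replicate(200, {
    x <- matrix(rnorm(60), nrow = 12)
    g <- sample(rep(c("a", "b"), 6))
    permanova(dist(x), g, n_perm = 199)$p_value <= 0.05
  })
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.12)
})

test_that("community change pairs sites across matrices", {
  pre <- tibble::tibble(plot_id = c("P1", "P2"), a = c(1, 0), b = c(2, 3),
                        c = c(0, 1))
  post <- tibble::tibble(plot_id = c("P2", "P1"), a = c(0, 0), b = c(3, 2),
                         c = c(2, 1))
  cc <- community_change(pre, post)
  expect_equal(cc$plot_id, c("P1", "P2"))
  expect_equal(cc$turnover[1], turnover_index(c(1, 2, 0), c(0, 2, 1)))
  expect_equal(cc$bray_curtis[2], bray_curtis(c(0, 3, 1), c(0, 3, 2)))
})
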