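toy_table <- function() {
  tidyr::expand_grid(species = "black spruce",
                     component = c("total", "bark", "main_branches",
                                   "fine_branches", "foliage")) %>%
    dplyr::mutate(a = c(0.1, 0.01, 0.02, 0.01, 0.02), b = 2)
}

test_that("tree biomass follows the power law", {
  bm <- tree_biomass(data.frame(species = "black spruce", diameter = 3),
                     toy_table())
  expect_equal(bm$mass_kg[bm$component == "total"], 0.9)
  tiny <- tree_biomass(data.frame(species = "black spruce", diameter = 1e-6),
                       toy_table())
  expect_lt(max(tiny$mass_kg), 1e-10)
  expect_error(tree_biomass(data.frame(species = "larch", diameter = 3),
                            toy_table()))
  expect_error(tree_biomass(data.frame(species = "black spruce",
                                       diameter = 0), toy_table()))
})

test_that("biomass matches independent recomputation over random trees", {
  set.seed(12)
  trees <- data.frame(species = "black spruce", diameter = runif(100, 0.5, 30))
  bm <- tree_biomass(trees, toy_table())
  tab <- toy_table()
  for (comp in unique(tab$component)) {
    a <- tab$a[tab$component == comp]
    b <- tab$b[tab$component == comp]
    expect_equal(bm$mass_kg[bm$component == comp], a * trees$diameter^b)
  }
})

test_that("combustion classes release the documented component fractions", {
  mk <- function(class, d = 10) {
    tree_biomass(data.frame(species = "black spruce", diameter = d,
                            combustion_class = class), toy_table())
  }
  expect_equal(tree_combusted_carbon(mk(0))$combusted_c_kg, 0)

  # class 1: only foliage, x 0.5 carbon
  t1 <- tree_combusted_carbon(mk(1))
  foliage <- 0.02 * 10^2
  expect_equal(t1$combusted_c_kg, foliage * 0.5)

  # class 2: foliage + half the fine branches
  t2 <- tree_combusted_carbon(mk(2))
  fine <- 0.01 * 10^2
  expect_equal(t2$combusted_c_kg, (foliage + 0.5 * fine) * 0.5)

  # class 3: foliage + fine + main + bark, x 0.5
  t3 <- tree_combusted_carbon(mk(3))
  expect_equal(t3$combusted_c_kg, (0.02 + 0.01 + 0.02 + 0.01) * 100 * 0.5)

  expect_error(tree_combusted_carbon(mk(1),
                                     rule = data.frame(combustion_class = 1,
                                                       component = "foliage",
                                                       fraction = 2)))
})

test_that("worked class-3 example sums the affected components", {
  # foliage 2 + fine 1 + main 3 + bark 1 kg combusted -> 3.5 kg C
  tab <- tibble::tibble(
    species = "black spruce",
    component = c("total", "foliage", "fine_branches", "main_branches",
                  "bark"),
    a = c(8, 2, 1, 3, 1), b = 0  # diameter-independent masses
  )
  bm <- tree_biomass(data.frame(species = "black spruce", diameter = 5,
                                combustion_class = 3), tab)
  expect_equal(tree_combusted_carbon(bm)$combusted_c_kg, 3.5)
})

test_that("plot pools are area-normalized tree sums", {
  empty <- plot_aboveground_pools(data.frame())
  expect_equal(nrow(empty), 0)

  tab <- tibble::tibble(species = "black spruce",
                        component = c("total", "foliage"),
                        a = c(201, 1), b = 0)
  one <- plot_aboveground_pools(
    data.frame(plot_id = "B01", species = "black spruce", diameter = 5,
               combustion_class = 0),
    table = tab, plot_area = 201)
  expect_equal(one$above_prefire, 0.5)   # 201 kg x 0.5 C / 201 m2
  expect_equal(one$above_combusted, 0)

  # randomized plots against a brute-force per-tree oracle
  set.seed(13)
  trees <- data.frame(
    plot_id = sample(c("A", "B", "C"), 60, replace = TRUE),
    species = "black spruce",
    diameter = runif(60, 1, 20),
    combustion_class = sample(0:3, 60, replace = TRUE)
  )
  got <- plot_aboveground_pools(trees, toy_table(), plot_area = 100)
  tab <- toy_table()
  frac <- function(cls, comp) {
    r <- default_combustion_rule()
    r$fraction[r$combustion_class == cls & r$component == comp]
  }
  for (p in unique(trees$plot_id)) {
    sub <- trees[trees$plot_id == p, ]
    pre <- sum(0.1 * sub$diameter^2) * 0.5 / 100
    comb <- sum(vapply(seq_len(nrow(sub)), function(i) {
      d <- sub$diameter[i]; cls <- sub$combustion_class[i]
      sum(vapply(c("bark", "main_branches", "fine_branches", "foliage"),
                 function(cp) {
                   a <- tab$a[tab$component == cp]
                   frac(cls, cp) * a * d^2
                 }, numeric(1))) * 0.5
    }, numeric(1))) / 100
    expect_equal(got$above_prefire[got$plot_id == p], pre)
    expect_equal(got$above_combusted[got$plot_id == p], comb)
  }
  expect_error(plot_aboveground_pools(trees, toy_table(), plot_area = 0))
})

test_that("combustion accounting is monotone and bounded", {
  set.seed(14)
  for (i in 1:20) {
    d <- runif(1, 1, 25)
    cc <- vapply(0:3, function(cls) {
      bm <- tree_biomass(data.frame(species = "black spruce", diameter = d,
                                    combustion_class = cls), toy_table())
      out <- tree_combusted_carbon(bm)
      expect_lte(out$combusted_c_kg, out$prefire_c_kg + 1e-12)
      out$combusted_c_kg
    }, numeric(1))
    expect_true(all(diff(cc) >= -1e-12))
  }
})

test_that("degenerate rule with all fractions 1 releases half the biomass", {
  tab <- tibble::tibble(species = "black spruce",
                        component = c("total", "foliage", "fine_branches",
                                      "main_branches", "bark"),
                        a = c(0.4, 0.1, 0.1, 0.1, 0.1), b = 2)
  rule <- tidyr::expand_grid(combustion_class = 0:3,
                             component = c("foliage", "fine_branches",
                                           "main_branches", "bark")) %>%
    dplyr::mutate(fraction = 1)
  bm <- tree_biomass(data.frame(species = "black spruce", diameter = 7,
                                combustion_class = 3), tab)
  out <- tree_combusted_carbon(bm, rule)
  expect_equal(out$combusted_c_kg, 0.5 * 0.4 * 7^2)
})
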