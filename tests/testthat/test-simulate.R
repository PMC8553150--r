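test_that("identical seeds give identical studies", {
  cfg <- sim_config(n_plots = 10, n_control = 5)
  s1 <- simulate_study(cfg, seed = 42)
  s2 <- simulate_study(cfg, seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_study(cfg, seed = 43)
  expect_false(identical(s1$points$residual_cm, s3$points$residual_cm))
})

test_that("generated tables satisfy the design arithmetic", {
  for (np in c(48L, 24L)) {
    cfg <- sim_config(n_plots = np)
    st <- simulate_study(cfg, seed = 2)
    exp <- design_expectations(cfg)
    expect_equal(nrow(st$points), exp$n_measurement_locations)
    expect_equal(sum(st$points$has_burn_depth), exp$n_burn_depth_points)
    expect_equal(sum(st$points$hit == "mineral"), exp$n_alt_usable)
    expect_equal(nrow(st$quadrats), exp$n_quadrats)
    expect_equal(sum(st$quadrats$seeds_sown), exp$seeds_sown)
  }
  # paper-shaped defaults
  exp <- design_expectations(sim_config())
  expect_equal(exp$n_measurement_locations, 576)
  expect_equal(exp$n_burn_depth_points, 170)
  expect_equal(exp$n_alt_usable, 470)
  expect_equal(exp$n_quadrats, 240)
  expect_equal(exp$seeds_sown, 30000)
})

test_that("every child row references an existing plot", {
  st <- simulate_study(sim_config(n_plots = 8, n_control = 4), seed = 3)
  ids <- st$plots$plot_id
  for (tab in c("points", "soil", "proxies", "trees", "seed_traps",
                "quadrats")) {
    expect_true(all(st[[tab]]$plot_id %in% ids), info = tab)
  }
  expect_true(all(st$community_pre$plot_id %in% ids))
})

test_that("degenerate burn-depth variance gives constant burn depths", {
  cfg <- sim_config(n_plots = 6, n_control = 3, burn_depth_mean = 10,
                    burn_depth_sd = 0)
  st <- simulate_study(cfg, seed = 1)
  expect_true(all(st$ground_truth$point_truth$burn_depth_true == 10))
})

test_that("soil profiles partition depth into 5-cm slices plus remainder", {
  cfg <- sim_config()
  set.seed(1)
  prof <- simulate_soil_profile("mesic", 27, cfg)
  expect_equal(prof$bottom_depth - prof$top_depth, c(5, 5, 5, 5, 5, 2))
  expect_equal(prof$top_depth[1], 0)
  expect_equal(max(prof$bottom_depth), 27)
  # exact multiple of 5 -> no remainder slice
  prof20 <- simulate_soil_profile("subhygric", 20, cfg)
  expect_equal(nrow(prof20), 4)
  expect_error(simulate_soil_profile("mesic", 0, cfg))
  expect_error(simulate_soil_profile("bog", 10, cfg))
})

test_that("surface bulk density draws average near the configured mean", {
  cfg <- sim_config()
  set.seed(10)
  surface_bd <- replicate(1000, {
    prof <- simulate_soil_profile("mesic", 12, cfg)
    bulk_density(prof)$bulk_density[1]
  })
  expect_lt(abs(mean(surface_bd) - 0.14), 0.015)
})

test_that("cumulative carbon is strictly increasing down a profile", {
  cfg <- sim_config()
  set.seed(4)
  for (i in 1:20) {
    prof <- simulate_soil_profile(sample(c("mesic", "subhygric"), 1),
                                  runif(1, 6, 40), cfg)
    cum <- cumulative_profile(prof)$cum_carbon
    expect_true(all(diff(cum) > 0))
  }
})

test_that("seeding experiment has the factorial design and NB1 counts", {
  cfg <- sim_config()
  set.seed(1)
  q <- simulate_seeding_experiment(cfg)
  expect_equal(nrow(q), 240)
  expect_equal(nrow(dplyr::count(q, seeded, scarified)), 4)
  expect_true(all(dplyr::count(q, seeded, scarified)$n == 60))
  expect_equal(sum(q$seeds_sown), 30000)
  expect_true(all(q$seedlings_2018 <= q$seedlings_2017))

  # all effects -> -Inf surrogate: mean 0, all counts 0
  cfg0 <- cfg
  cfg0$seeding_coefs[] <- -Inf
  q0 <- simulate_seeding_experiment(cfg0)
  expect_true(all(q0$seedlings_2017 == 0))
})

test_that("seeded quadrats out-count unseeded ones almost surely", {
  cfg <- sim_config()
  set.seed(99)
  wins <- replicate(1000, {
    q <- simulate_seeding_experiment(cfg)
    mean(q$seedlings_2017[q$seeded]) > mean(q$seedlings_2017[!q$seeded])
  })
  expect_gt(mean(wins), 0.99)
})

test_that("community pairs hit the turnover target in expectation", {
  cfg <- sim_config()
  set.seed(21)
  p0 <- simulate_community_pair(10, 0, cfg)
  expect_identical(p0$pre > 0, p0$post > 0)
  p1 <- simulate_community_pair(10, 1, cfg)
  expect_true(all(!(p1$pre > 0 & p1$post > 0)))  # disjoint sets
  expect_gt(sum(p1$pre), 0)
  expect_gt(sum(p1$post), 0)

  to <- replicate(1000, {
    p <- simulate_community_pair(50, 0.34, cfg)
    turnover_index(p$pre, p$post)
  })
  expect_gt(mean(to), 0.29)
  expect_lt(mean(to), 0.39)

  expect_error(simulate_community_pair(1, 0.5, cfg))
  expect_error(simulate_community_pair(10, 1.5, cfg))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(burn_depth_sd = -1))
  expect_error(sim_config(viability = 1.5))
  expect_error(sim_config(n_plots = 0))
  expect_error(sim_config(points_per_plot = 2.5))
  expect_error(sim_config(monolith_points = 20, points_per_plot = 12))
})

test_that("study tables round-trip through CSV", {
  st <- simulate_study(sim_config(n_plots = 4, n_control = 2), seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(file.path(dir, "points.csv"))
  expect_equal(nrow(back), nrow(st$points))
})
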