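test_that("noiseless linear truth is recovered in the exact-fit limit", {
  depths <- seq(5, 25, by = 5)
  dat <- tidyr::expand_grid(plot_id = c("P1", "P2"),
                            mono = c("M1", "M2"),
                            depth = depths) %>%
    dplyr::mutate(monolith_id = paste(plot_id, mono, sep = "-"),
                  moisture = "mesic",
                  cum_carbon = 0.3 * depth)
  fit <- fit_depth_carbon_model(dat)
  expect_equal(unname(fit$coefficients[["depth"]]), 0.3, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients[["depth2"]]), 0, tolerance = 1e-8)
  expect_lt(fit$varcomp[["sigma_plot"]] * fit$varcomp[["sigma"]], 1e-6)
  expect_true(fit$reduced_moisture)
})

test_that("REML matches closed-form variance components on a balanced design", {
  set.seed(5)
  M <- 8
  depths <- seq(5, 25, by = 5)
  n <- length(depths)
  dat <- purrr::map_dfr(seq_len(M), function(m) tibble::tibble(
    plot_id = "P1", monolith_id = paste0("M", m), moisture = "mesic",
    depth = depths,
    cum_carbon = 1 + 0.2 * depths + 0.004 * depths^2 +
      rnorm(1, 0, 0.6) + rnorm(n, 0, 0.3)
  ))
  fit <- fit_depth_carbon_model(dat, variance_function = FALSE)

  # closed form: one-way ANOVA on group means; within-group MSE from the
  # fixed model with monolith dummies (depth terms are orthogonal to groups
  # because every monolith sees the same depth grid)
  gm <- tapply(dat$cum_carbon, dat$monolith_id, mean)
  msb <- n * var(gm)
  l <- lm(cum_carbon ~ depth + I(depth^2) + factor(monolith_id), data = dat)
  mse <- sum(resid(l)^2) / (nrow(dat) - M - 2)

  expect_equal(fit$varcomp[["sigma"]], sqrt(mse), tolerance = 1e-6)
  expect_equal(fit$varcomp[["sigma_mono"]], sqrt((msb - mse) / n),
               tolerance = 1e-6)
})

test_that("moisture interactions are estimated when classes differ", {
  set.seed(6)
  dat <- simulate_depth_carbon_data(n_plots = 12, monoliths_per_plot = 3,
                                    sigma_plot = 0.3, sigma_mono = 0.2,
                                    sigma_resid = 0.2)
  dat$moisture <- rep(c("mesic", "mesic-subhygric", "subhygric"), length.out = 12)[
    as.integer(factor(dat$plot_id))]
  # steepen the wetter classes by a known interaction
  shift <- c(mesic = 0, `mesic-subhygric` = 0.05, subhygric = 0.1)
  dat$cum_carbon <- dat$cum_carbon + shift[dat$moisture] * dat$depth
  fit <- fit_depth_carbon_model(dat)
  expect_false(fit$reduced_moisture)
  expect_equal(unname(fit$coefficients[["depth:moisturesubhygric"]]), 0.1,
               tolerance = 0.35)
  expect_setequal(fit$moisture_levels,
                  c("mesic", "mesic-subhygric", "subhygric"))
})

test_that("variance function is inert on homoscedastic data", {
  set.seed(7)
  dat <- simulate_depth_carbon_data(n_plots = 15, monoliths_per_plot = 5,
                                    depths = seq(2.5, 25, by = 2.5),
                                    sigma_plot = 0.4, sigma_mono = 0.3,
                                    sigma_resid = 0.2)
  f1 <- fit_depth_carbon_model(dat, variance_function = TRUE)
  f0 <- fit_depth_carbon_model(dat, variance_function = FALSE)
  expect_lt(abs(f1$coefficients[["depth"]] - f0$coefficients[["depth"]]) /
              abs(f0$coefficients[["depth"]]), 0.01)
})

test_that("prediction uses the fixed surface, floored at zero", {
  depths <- seq(5, 25, by = 5)
  dat <- tidyr::expand_grid(plot_id = c("P1", "P2"), mono = c("M1", "M2"),
                            depth = depths) %>%
    dplyr::mutate(monolith_id = paste(plot_id, mono, sep = "-"),
                  moisture = "mesic", cum_carbon = 0.3 * depth)
  fit <- fit_depth_carbon_model(dat)
  pred <- predict_combusted_carbon(fit, 10, "mesic")
  expect_equal(pred$combusted_c, 3.0, tolerance = 1e-6)
  expect_equal(predict_combusted_carbon(fit, 0, "mesic")$combusted_c, 0,
               tolerance = 1e-6)

  # concave-up truth: prediction monotone over the fitted range
  grid <- predict_combusted_carbon(fit, seq(0, 25, by = 0.5), "mesic")
  expect_true(all(diff(grid$combusted_c) >= -1e-9))

  # negative intercept region floored and flagged
  dat2 <- dplyr::mutate(dat, cum_carbon = -1 + 0.3 * .data$depth)
  fit2 <- fit_depth_carbon_model(dat2)
  p0 <- predict_combusted_carbon(fit2, 0, "mesic")
  expect_equal(p0$combusted_c, 0)
  expect_true(p0$floored)

  expect_error(predict_combusted_carbon(fit, 10, "bog"), "moisture")
  expect_error(predict_combusted_carbon(fit, -5, "mesic"))
})

test_that("tidy and glance expose coefficients and metadata", {
  set.seed(8)
  dat <- simulate_depth_carbon_data(n_plots = 5, monoliths_per_plot = 3)
  fit <- fit_depth_carbon_model(dat)
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "depth", "depth2") %in% td$term))
  gl <- glance(fit)
  expect_equal(gl$n_plots, 5)
  expect_equal(gl$n_monoliths, 15)
})
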