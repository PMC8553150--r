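test_that("equivalent latitude behaves as the insolation rotation", {
  expect_equal(equivalent_latitude(0, 45, 63.7), 63.7)
  expect_equal(equivalent_latitude(10, 0, 63), 73.0, tolerance = 0.1 / 73)
  expect_equal(equivalent_latitude(10, 180, 63), 53.0, tolerance = 0.1 / 53)
  # east/west-facing slopes barely move the equivalent latitude
  expect_lt(abs(equivalent_latitude(10, 90, 63) - 63), 2)
  expect_error(equivalent_latitude(-1, 0, 63))
  expect_error(equivalent_latitude(95, 0, 63))
  expect_error(equivalent_latitude(10, 380, 63))
})

test_that("density classification follows the published cutpoints", {
  expect_equal(as.character(classify_density(c(0, 0.01, 0.05))),
               c("low", "medium", "high"))
  expect_equal(as.character(classify_density(c(1e-4, 0.0249, 0.025))),
               c("medium", "medium", "high"))
  expect_error(classify_density(-0.1))
})

test_that("offset calibration averages unburned proxies", {
  cal <- calibrate_offsets(make_proxy(c(2.19, 2.19), "arh", "unburned"))
  expect_equal(cal$arh_offset, 2.19)
  cal2 <- calibrate_offsets(make_proxy(c(10, 13.02), "tch", "unburned"))
  expect_equal(cal2$tch_offset, 11.51)
  # single measurement: offset defined, SE flagged NA
  cal3 <- calibrate_offsets(make_proxy(5, "arh", "unburned"))
  expect_equal(cal3$arh_offset, 5)
  expect_true(is.na(cal3$arh_se))
  expect_error(calibrate_offsets(make_proxy(numeric(0), "arh", "unburned")))
  expect_error(calibrate_offsets(make_proxy(3, "arh", "burned")))
})

test_that("offset calibration recovers truth on synthetic controls", {
  set.seed(31)
  n <- 200
  sdv <- 0.06 * sqrt(n)  # SE of the mean = 0.06
  prox <- dplyr::bind_rows(
    make_proxy(pmax(rnorm(n, 2.19, sdv), 0), "arh", "unburned"),
    make_proxy(pmax(rnorm(n, 11.51, sdv), 0), "tch", "unburned")
  )
  cal <- calibrate_offsets(prox)
  expect_lt(abs(cal$arh_offset - 2.19), 2 * cal$arh_se)
  expect_lt(abs(cal$tch_offset - 11.51), 2 * cal$tch_se)
})

test_that("burn depth reconstruction applies the offset rules", {
  cal <- tibble::tibble(arh_offset = 2.19, tch_offset = 11.51)
  est <- estimate_burn_depth(make_proxy(8, "arh"), cal)
  expect_equal(est$bd_cm, 10.19)
  expect_equal(est$method, "ARH")

  est2 <- estimate_burn_depth(make_proxy(11.51, "tch"), cal)
  expect_equal(est2$bd_cm, 0)
  expect_equal(est2$method, "TCH")

  both <- dplyr::bind_rows(make_proxy(7.81, "arh"), make_proxy(23.51, "tch"))
  est3 <- estimate_burn_depth(both, cal)
  expect_equal(est3$bd_cm, 11.0)   # mean(10, 12)
  expect_equal(est3$method, "mean")

  # shorter-than-offset tussock: floored at zero and flagged
  est4 <- estimate_burn_depth(make_proxy(5, "tch"), cal)
  expect_equal(est4$bd_cm, 0)
  expect_true(est4$floored)

  expect_error(estimate_burn_depth(make_proxy(5, "arh", "unburned"), cal))
  expect_error(estimate_burn_depth(make_proxy(numeric(0), "arh"), cal))
})

test_that("per-point proxies are averaged before offsetting", {
  cal <- tibble::tibble(arh_offset = 2, tch_offset = 10)
  est <- estimate_burn_depth(make_proxy(c(6, 8, 10), "arh"), cal)
  expect_equal(est$bd_cm, mean(c(6, 8, 10)) + 2)
})

test_that("SOL partition identities hold", {
  p <- sol_partition(10, 15)
  expect_equal(p$prefire_cm, 25)
  expect_equal(p$prop_combusted, 0.4)
  expect_equal(sol_partition(0, 20)$prop_combusted, 0)
  expect_equal(sol_partition(12, 0)$prop_combusted, 1)
  expect_error(sol_partition(0, 0))
  expect_error(sol_partition(-1, 5))

  # proportion is monotone in burn depth at fixed residual
  bd <- seq(0, 30, by = 0.5)
  expect_true(all(diff(sol_partition(bd, 10)$prop_combusted) > 0))
})

test_that("reconstructed burn depth is never negative", {
  cal <- tibble::tibble(arh_offset = 2.19, tch_offset = 11.51)
  set.seed(8)
  for (i in 1:50) {
    prox <- dplyr::bind_rows(
      make_proxy(runif(5, 0, 4), "arh"),
      make_proxy(runif(5, 0, 25), "tch")
    )
    expect_gte(estimate_burn_depth(prox, cal)$bd_cm, 0)
  }
})
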