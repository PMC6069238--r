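# Replicate Monte Carlo protocol: draws, percentile extraction, replicate
# confidence intervals, route totals, determinism.

small_settings <- function(iterations = 1e4, replicates = 5, seed = 11,
                           ...) {
  simulation_settings(iterations = iterations, replicates = replicates,
                      seed = seed, ...)
}

test_that("degenerate point-mass scenarios give a flat percentile profile", {
  r <- simulate_intake(point_mass_scenario(), small_settings(2000, 3))
  expect_true(all(r$point == 0.01))
  expect_true(all(r$lower == 0.01))
  expect_true(all(r$upper == 0.01))
})

test_that("identical seeds reproduce reports bit-exactly, different seeds agree within CI", {
  sc <- load_scenario("chlorpyrifos_dust")
  r1 <- simulate_intake(sc, small_settings())
  r2 <- simulate_intake(sc, small_settings())
  expect_identical(r1$replicate_estimates, r2$replicate_estimates)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  r3 <- simulate_intake(sc, small_settings(seed = 12))
  expect_false(identical(r3$point, r1$point))
  # overlapping confidence intervals at every percentile
  expect_true(all(r1$lower <= r3$upper & r3$lower <= r1$upper))
})

test_that("percentile estimates are non-decreasing within every replicate", {
  sc <- load_scenario("cypermethrin_dust")
  r <- simulate_intake(sc, small_settings())
  expect_true(all(apply(r$replicate_estimates, 1, function(v)
    all(diff(v) >= 0))))
  expect_true(all(diff(r$point) >= 0))
  expect_true(all(r$lower <= r$point & r$point <= r$upper))
})

test_that("Monte Carlo quantiles converge to the closed-form product oracle", {
  sc <- load_scenario("chlorpyrifos_dust")
  r <- simulate_intake(sc, small_settings(iterations = 1e5, replicates = 3))
  oracle <- lognormal_quantile(scenario_oracle(sc),
                               c(0.5, 0.75, 0.9, 0.95))
  got <- r$point[1:4]
  expect_true(all(abs(got - oracle) / oracle < 0.03))
})

test_that("route totals share one body weight and reduce to the single-route run", {
  sc_dust <- load_scenario("chlorpyrifos_dust")
  sc_soil <- load_scenario("chlorpyrifos_soil")
  s <- small_settings()

  single <- simulate_intake(sc_dust, s)
  total1 <- simulate_total(list(sc_dust), s)
  expect_identical(single$replicate_estimates, total1$replicate_estimates)

  pm <- point_mass_scenario()
  doubled <- simulate_total(list(pm, pm), small_settings(2000, 3))
  expect_true(all(doubled$point == 0.02))

  total <- simulate_total(list(sc_dust, sc_soil),
                          small_settings(iterations = 1e5, replicates = 3))
  both <- lapply(list(sc_dust, sc_soil), simulate_intake,
                 settings = small_settings(iterations = 1e5, replicates = 3))
  elementwise_max <- pmax(both[[1]]$point, both[[2]]$point)
  expect_true(all(total$point >= elementwise_max))

  expect_error(simulate_total(list(sc_dust, load_scenario("cypermethrin_dust")),
                              s),
               "invalid aggregation")
})

test_that("replicate t-intervals match the textbook construction", {
  expect_equal(percentile_ci(c(5, 5, 5)),
               c(lower = 5, point = 5, upper = 5))
  ci <- percentile_ci(c(1, 2, 3), level = 0.95)
  expect_equal(ci[["point"]], 2)
  expect_equal(ci[["upper"]] - ci[["point"]], 2.48413771175,
               tolerance = 1e-10)
  wide <- percentile_ci(c(1, 2, 3), level = 0.99)
  expect_lt(wide[["lower"]], ci[["lower"]])
  expect_gt(wide[["upper"]], ci[["upper"]])
  expect_error(percentile_ci(5), "insufficient replicates")
})

test_that("percentiles finer than the draw resolution raise a warning", {
  sc <- point_mass_scenario()
  expect_warning(
    simulate_intake(sc, simulation_settings(iterations = 100, replicates = 2,
                                            percentiles = c(0.5, 0.9999))),
    "resolution")
})

test_that("report CSVs and sidecars are byte-identical across reruns", {
  sc <- load_scenario("cypermethrin_soil")
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(simulate_intake(sc, small_settings(5e3, 3)), p1)
  write_report_csv(simulate_intake(sc, small_settings(5e3, 3)), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(paste0(p1, ".meta.json")),
                   readLines(paste0(p2, ".meta.json")))
  back <- read_report_csv(p1)
  expect_equal(back$point,
               simulate_intake(sc, small_settings(5e3, 3))$point,
               tolerance = 1e-12)
})
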