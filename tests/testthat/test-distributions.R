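# Lognormal fitting from the three kinds of published evidence, and the
# closed-form lognormal algebra used as the simulator's oracle.

test_that("moment matching reproduces the published mean/SD pairs exactly", {
  cases <- list(
    list(mean = 2.32, sd = 15.41, mu = -1.06308864248, sigma = 1.95174579705),
    list(mean = 26.65, sd = 36.54, mu = 2.75390541930, sigma = 1.02847822662))
  for (cs in cases) {
    spec <- fit_lognormal(summary_moments(cs$mean, cs$sd))
    expect_equal(spec$mu, cs$mu, tolerance = 1e-10)
    expect_equal(spec$sigma, cs$sigma, tolerance = 1e-10)
    expect_equal(lnorm_mean(spec), cs$mean, tolerance = 1e-12)
    expect_equal(lnorm_sd(spec), cs$sd, tolerance = 1e-12)
  }
})

test_that("moment fit round-trips over a wide randomized (mean, sd) grid", {
  set.seed(101)
  for (i in 1:200) {
    m <- exp(stats::runif(1, log(0.01), log(1000)))
    s <- exp(stats::runif(1, log(0.01), log(1000)))
    spec <- fit_lognormal(summary_moments(m, s))
    expect_equal(lnorm_mean(spec), m, tolerance = 1e-12)
    expect_equal(lnorm_sd(spec), s, tolerance = 1e-12)
  }
})

test_that("moment fit handles the point-mass limit and rejects bad summaries", {
  expect_true(dustintake:::is_point_mass(fit_lognormal(summary_moments(5, 0))))
  tiny <- fit_lognormal(summary_moments(5, 1e-8))
  expect_lt(tiny$sigma, 1e-7)
  expect_equal(tiny$mu, log(5), tolerance = 1e-9)
  expect_error(summary_moments(-1, 2), "mean")
  expect_error(summary_moments(1, -2), "sd")
  expect_error(summary_moments(0, 1), "mean")
})

test_that("percentile fitting solves two points exactly and probit-fits more", {
  two <- fit_lognormal(percentile_table(c(0.25, 0.75), exp(c(-1, 1))))
  expect_equal(two$mu, 0, tolerance = 1e-12)
  expect_equal(two$sigma, 1.48260221851, tolerance = 1e-10)

  bw <- fit_lognormal(percentile_table(
    c(0.03, 0.15, 0.25, 0.50, 0.75, 0.85, 0.97),
    c(13.5, 15.1, 15.8, 17.3, 19.0, 20.1, 22.9)))
  expect_equal(bw$mu, 2.857770939371, tolerance = 1e-9)
  expect_equal(bw$sigma, 0.139616831359, tolerance = 1e-9)
  # residuals of the probit fit stay small in log space
  z <- qnorm(c(0.03, 0.15, 0.25, 0.50, 0.75, 0.85, 0.97))
  resid <- log(c(13.5, 15.1, 15.8, 17.3, 19.0, 20.1, 22.9)) -
    (bw$mu + bw$sigma * z)
  expect_lt(max(abs(resid)), 0.02)
})

test_that("percentile fitting recovers known parameters from exact tables", {
  set.seed(7)
  for (i in 1:25) {
    mu <- stats::runif(1, -3, 3)
    sigma <- stats::runif(1, 0.05, 2.5)
    truth <- lognormal_spec(mu, sigma)
    grid <- sort(stats::runif(sample(3:9, 1), 0.01, 0.99))
    tab <- percentile_table(grid, lognormal_quantile(truth, grid))
    fit <- fit_lognormal(tab)
    expect_equal(fit$mu, mu, tolerance = 1e-9)
    expect_equal(fit$sigma, sigma, tolerance = 1e-9)
  }
})

test_that("percentile tables reject degenerate or malformed input", {
  expect_error(percentile_table(0.5, 17.3), "at least 2")
  expect_error(percentile_table(c(0.5, 0.5), c(1, 2)), "increasing")
  expect_error(percentile_table(c(0.25, 0.75), c(-1, 2)), "> 0")
  expect_error(percentile_table(c(0.25, 0.75), c(3, 2)), "non-decreasing")
})

test_that("half-LOD substitution replaces only censored entries", {
  s <- censored_sample(c(0.01, 0.08), c(TRUE, FALSE), lod = 0.025)
  expect_equal(substitute_half_lod(s), c(0.0125, 0.08))

  none <- censored_sample(c(1, 2, 3), c(FALSE, FALSE, FALSE), lod = 0.5)
  expect_identical(substitute_half_lod(none), c(1, 2, 3))

  empty <- censored_sample(numeric(0), logical(0), lod = 1)
  expect_length(substitute_half_lod(empty), 0)

  expect_error(censored_sample(1, TRUE, lod = 0), "LOD")
  expect_error(censored_sample(1, TRUE, lod = -1), "LOD")

  set.seed(33)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    v <- stats::rlnorm(n)
    cens <- stats::runif(n) < 0.3
    lod <- stats::runif(1, 0.1, 2)
    out <- substitute_half_lod(censored_sample(v, cens, lod))
    expect_length(out, n)
    expect_identical(out[!cens], v[!cens])
    expect_true(all(out[cens] == lod / 2))
  }
})

test_that("censored fitting composes substitution with moment matching", {
  all_cens <- censored_sample(c(0.01, 0.02, 0.005), rep(TRUE, 3), lod = 0.05)
  spec <- fit_lognormal(all_cens)
  expect_true(dustintake:::is_point_mass(spec))
  expect_equal(exp(spec$mu), 0.025)

  const <- censored_sample(rep(2, 3), rep(FALSE, 3), lod = 0.1)
  spec2 <- fit_lognormal(const)
  expect_equal(spec2$mu, log(2))
  expect_equal(spec2$sigma, 0)

  expect_error(fit_lognormal(censored_sample(c(1, 2), c(FALSE, FALSE), 0.1)),
               "insufficient")
})

test_that("lognormal quantiles match the normal-quantile closed form", {
  std <- lognormal_spec(0, 1)
  expect_equal(lognormal_quantile(std, 0.5), 1)
  expect_equal(lognormal_quantile(std, 0.975), 7.09907138423,
               tolerance = 1e-10)
  spec <- lognormal_spec(1.7, 0.4)
  expect_equal(lognormal_quantile(spec, 0.5), exp(1.7))
  # strictly increasing in p
  p <- seq(0.001, 0.999, length.out = 200)
  expect_true(all(diff(lognormal_quantile(spec, p)) > 0))
  expect_error(lognormal_quantile(std, 0), "0, 1")
  expect_error(lognormal_quantile(std, 1), "0, 1")
})

test_that("product/quotient composition is exact lognormal algebra", {
  a <- lognormal_spec(0, 1)
  expect_equal(combine_product_quotient(a)[c("mu", "sigma")],
               a[c("mu", "sigma")])
  b <- lognormal_spec(0, 0.7)
  ab <- combine_product_quotient(list(a, b))
  expect_equal(ab$mu, 0)
  expect_equal(ab$sigma, sqrt(1 + 0.49))
  expect_error(combine_product_quotient(list(), list(a)), "numerator")

  # brute-force Monte Carlo cross-check of product/quotient quantiles
  num <- list(lognormal_spec(0.3, 0.9), lognormal_spec(-0.5, 1.4))
  den <- list(lognormal_spec(1.1, 0.2))
  comb <- combine_product_quotient(num, den, scale = 2.5)
  set.seed(99)
  draws <- 2.5 * stats::rlnorm(1e6, 0.3, 0.9) * stats::rlnorm(1e6, -0.5, 1.4) /
    stats::rlnorm(1e6, 1.1, 0.2)
  for (p in c(0.5, 0.9, 0.99)) {
    mc <- unname(stats::quantile(draws, p, type = 1))
    expect_equal(mc, lognormal_quantile(comb, p), tolerance = 0.02)
  }
})

test_that("relative standard deviation matches the published diagnostics", {
  expect_equal(round(rsd(summary_moments(26.65, 36.54)), 2), 1.37)
  expect_equal(round(rsd(summary_moments(2.32, 15.41)), 2), 6.64)
  expect_equal(rsd(summary_moments(5, 0)), 0)
  # analytic RSD of a fitted lognormal reproduces the summary RSD
  expect_equal(rsd(fit_lognormal(summary_moments(26.65, 36.54))),
               36.54 / 26.65, tolerance = 1e-12)
})
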