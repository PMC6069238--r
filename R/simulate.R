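# Monte Carlo engine: independent draws of (IR, C, BW), the intake equation
# per draw, empirical percentiles of %ADI per replicate, and t-based 95%
# confidence intervals across replicates.

#' Simulation settings
#'
#' Defaults follow the study protocol: 1,000,000 iterations per replicate,
#' 30 replicates, percentile grid P50/P75/P90/P95/P97.5/P99/P99.9.
#'
#' @param iterations Draws per replicate (>= 1).
#' @param replicates Independent repeats (>= 1).
#' @param seed Base RNG seed; per-replicate streams are derived from it
#'   deterministically, so results are reproducible and replicate-order
#'   insensitive.
#' @param percentiles Strictly increasing probabilities in (0, 1).
#' @param ci_level Confidence level for replicate-based intervals.
#' @return An object of class `simulation_settings`.
#' @export
simulation_settings <- function(iterations = 1e6, replicates = 30,
                                seed = 1L,
                                percentiles = c(0.50, 0.75, 0.90, 0.95,
                                                0.975, 0.99, 0.999),
                                ci_level = 0.95) {
  if (iterations < 1 || replicates < 1)
    stop("iterations and replicates must be >= 1", call. = FALSE)
  if (any(percentiles <= 0) || any(percentiles >= 1) ||
      any(diff(percentiles) <= 0))
    stop("percentiles must be strictly increasing in (0, 1)", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0, 1)", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 percentiles = percentiles,
                 ci_level = ci_level),
            class = "simulation_settings")
}

# Deterministic, order-insensitive per-replicate seed in [1, 2^31-2].
replicate_seed <- function(base_seed, r) {
  as.integer((abs(as.double(base_seed)) + 1103515245 * as.double(r)) %%
               2147483646) + 1L
}

# One vector of draws from a lognormal spec, honouring an optional upper
# truncation bound via inverse-CDF sampling (keeps the draw count per
# variable constant, so seeding stays aligned across settings).
draw_spec <- function(spec, n, upper = NULL) {
  if (is_point_mass(spec)) {
    v <- exp(spec$mu)
    if (!is.null(upper) && v > upper)
      stop("point mass lies above its truncation bound", call. = FALSE)
    return(rep(v, n))
  }
  if (is.null(upper)) {
    stats::rlnorm(n, spec$mu, spec$sigma)
  } else {
    u <- stats::runif(n, 0, stats::plnorm(upper, spec$mu, spec$sigma))
    stats::qlnorm(u, spec$mu, spec$sigma)
  }
}

# Lower nearest-rank empirical quantile (inverse empirical CDF), type 1.
empirical_percentiles <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 1, names = FALSE))
}

#' Replicate-based confidence interval for a percentile estimate
#'
#' Point estimate is the mean of the per-replicate percentile estimates;
#' bounds are `point +/- t((1+level)/2, n-1) * sd / sqrt(n)`.
#'
#' @param replicate_estimates Numeric vector of per-replicate estimates
#'   (length >= 2).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, point, upper)`.
#' @export
percentile_ci <- function(replicate_estimates, level = 0.95) {
  n <- length(replicate_estimates)
  if (n < 2L)
    stop("insufficient replicates: need at least 2 for a confidence interval",
         call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  point <- mean(replicate_estimates)
  hw <- stats::qt((1 + level) / 2, n - 1) *
    stats::sd(replicate_estimates) / sqrt(n)
  c(lower = point - hw, point = point, upper = point + hw)
}

new_percentile_report <- function(probs, reps, settings, meta) {
  point <- colMeans(reps)
  if (nrow(reps) >= 2L) {
    cis <- apply(reps, 2L, percentile_ci, level = settings$ci_level)
    lower <- cis["lower", ]
    upper <- cis["upper", ]
  } else {
    lower <- upper <- rep(NA_real_, length(probs))
  }
  structure(list(percentiles = probs,
                 point = unname(point),
                 lower = unname(lower),
                 upper = unname(upper),
                 replicate_estimates = unname(reps),
                 ci_level = settings$ci_level,
                 meta = meta),
            class = "percentile_report")
}

check_resolution <- function(settings) {
  p <- settings$percentiles
  if (min(c(p, 1 - p)) < 1 / settings$iterations)
    warning("requested percentile finer than the 1/iterations resolution; ",
            "tail estimates will be coarse", call. = FALSE)
}

sim_meta <- function(scenarios, settings, shared_bw = NA) {
  one <- scenarios[[1L]]
  list(compound = one$compound,
       route = paste(vapply(scenarios, `[[`, character(1), "route"),
                     collapse = "+"),
       adi = one$adi,
       seed = settings$seed,
       iterations = settings$iterations,
       replicates = settings$replicates,
       parameterization = one$parameterization,
       shared_bw = shared_bw,
       ci_method = "t interval across replicate percentile estimates",
       package_version = as.character(utils::packageVersion("dustintake")))
}

# draws for one replicate of a set of routes sharing compound/ADI;
# draw order: (ir_i, conc_i[, bw_i if not shared]) per route, then shared bw.
replicate_pct_adi <- function(scenarios, n, shared_bw) {
  total <- 0
  for (sc in scenarios) {
    ir <- draw_spec(sc$ir, n, sc$truncation$ir)
    conc <- draw_spec(sc$conc, n, sc$truncation$conc)
    if (!shared_bw) {
      bw <- draw_spec(sc$bw, n, sc$truncation$bw)
      total <- total + intake_from_draw(ir, conc, bw, sc$cf)
    } else {
      total <- total + ir * conc * sc$cf
    }
  }
  if (shared_bw) {
    sc1 <- scenarios[[1L]]
    bw <- draw_spec(sc1$bw, n, sc1$truncation$bw)
    total <- total / bw
  }
  percent_of_adi(total, scenarios[[1L]]$adi)
}

simulate_engine <- function(scenarios, settings, shared_bw) {
  check_resolution(settings)
  probs <- settings$percentiles
  reps <- matrix(NA_real_, settings$replicates, length(probs))
  for (r in seq_len(settings$replicates)) {
    set.seed(replicate_seed(settings$seed, r))
    pct <- replicate_pct_adi(scenarios, settings$iterations, shared_bw)
    reps[r, ] <- empirical_percentiles(pct, probs)
  }
  reps
}

#' Simulate the %ADI distribution for one exposure route
#'
#' Runs the replicate Monte Carlo protocol: per replicate, `iterations`
#' independent (IR, C, BW) triples are drawn, the intake equation is applied
#' to each, and the empirical percentiles of intake as percent of ADI are
#' extracted (lower nearest-rank definition). Estimates are aggregated across
#' replicates into a point estimate (mean) with a t-based confidence
#' interval. Identical `(scenario, settings)` give bit-identical reports.
#'
#' @param scenario An [exposure_scenario()].
#' @param settings A [simulation_settings()].
#' @return A `percentile_report` object; see [as.data.frame.percentile_report()].
#' @examples
#' sc <- load_scenario("chlorpyrifos_dust")
#' simulate_intake(sc, simulation_settings(iterations = 1e4, replicates = 3))
#' @export
simulate_intake <- function(scenario, settings = simulation_settings()) {
  stopifnot(inherits(scenario, "exposure_scenario"),
            inherits(settings, "simulation_settings"))
  reps <- simulate_engine(list(scenario), settings, shared_bw = TRUE)
  new_percentile_report(settings$percentiles, reps, settings,
                        sim_meta(list(scenario), settings))
}

#' Simulate the total %ADI across routes of one compound
#'
#' Per iteration one shared body weight is drawn (one child, one body weight)
#' and independent (IR, C) pairs per route; route intakes are summed before
#' ADI normalization. Set `shared_bw = FALSE` to draw body weight
#' independently per route instead.
#'
#' @param scenarios List of [exposure_scenario()]s sharing compound and ADI.
#' @param settings A [simulation_settings()].
#' @param shared_bw Share one body-weight draw across routes (default `TRUE`).
#' @return A `percentile_report`.
#' @export
simulate_total <- function(scenarios, settings = simulation_settings(),
                           shared_bw = TRUE) {
  if (inherits(scenarios, "exposure_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, logical(1), "exposure_scenario")))
  compounds <- vapply(scenarios, `[[`, character(1), "compound")
  adis <- vapply(scenarios, `[[`, numeric(1), "adi")
  if (length(unique(compounds)) != 1L || length(unique(adis)) != 1L)
    stop("invalid aggregation: all scenarios must share compound and ADI",
         call. = FALSE)
  reps <- simulate_engine(scenarios, settings, shared_bw = shared_bw)
  new_percentile_report(settings$percentiles, reps, settings,
                        sim_meta(scenarios, settings, shared_bw = shared_bw))
}

#' Raw Monte Carlo draws for a scenario
#'
#' Returns the per-draw inputs and outputs (used by the sensitivity analysis
#' and the density plot); one stream, no replication.
#'
#' @param scenario An [exposure_scenario()].
#' @param n Number of draws.
#' @param seed RNG seed.
#' @return Data frame with columns `ir`, `conc`, `bw`, `intake`, `pct_adi`.
#' @export
simulate_draws <- function(scenario, n = 1e5, seed = 1L) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  set.seed(replicate_seed(seed, 1L))
  ir <- draw_spec(scenario$ir, n, scenario$truncation$ir)
  conc <- draw_spec(scenario$conc, n, scenario$truncation$conc)
  bw <- draw_spec(scenario$bw, n, scenario$truncation$bw)
  intake <- intake_from_draw(ir, conc, bw, scenario$cf)
  data.frame(ir = ir, conc = conc, bw = bw, intake = intake,
             pct_adi = percent_of_adi(intake, scenario$adi))
}

# ---- report methods ---------------------------------------------------------

#' @export
as.data.frame.percentile_report <- function(x, ...) {
  data.frame(percentile = x$percentiles,
             point = x$point,
             ci_lower = x$lower,
             ci_upper = x$upper)
}

#' Coerce a percentile report to a data frame
#'
#' @param x A `percentile_report`.
#' @param ... Unused.
#' @return Data frame with columns `percentile`, `point`, `ci_lower`,
#'   `ci_upper` (one row per requested percentile, %ADI scale).
#' @name as.data.frame.percentile_report
NULL

#' @export
print.percentile_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Simulated %%ADI percentiles: %s via %s\n", m$compound, m$route))
  cat(sprintf("  %d iterations x %d replicates, seed %d, %s parameterization\n",
              m$iterations, m$replicates, m$seed, m$parameterization))
  cat(render_percentile_table(x), sep = "\n")
  invisible(x)
}

#' @export
summary.percentile_report <- function(object, ...) {
  df <- as.data.frame(object)
  df$ci_width <- df$ci_upper - df$ci_lower
  df
}

#' @export
plot.percentile_report <- function(x, ...) {
  df <- as.data.frame(x)
  ok <- df$point > 0
  graphics::plot(stats::qnorm(df$percentile[ok]), log10(df$point[ok]),
                 type = "b", pch = 19,
                 xlab = "standard-normal quantile of percentile",
                 ylab = "log10(% of ADI)",
                 main = sprintf("%s via %s", x$meta$compound, x$meta$route),
                 ...)
  if (!all(is.na(df$ci_lower))) {
    lo <- pmax(df$ci_lower[ok], .Machine$double.xmin)
    graphics::segments(stats::qnorm(df$percentile[ok]), log10(lo),
                       stats::qnorm(df$percentile[ok]), log10(df$ci_upper[ok]),
                       col = "grey40")
  }
  invisible(x)
}

#' Write a percentile report to CSV with a metadata sidecar
#'
#' One row per percentile with columns `percentile`, `point`, `ci_lower`,
#' `ci_upper`, plus `<path>.meta.json` recording seed, iterations,
#' replicates, parameterization, CI method and package version. Reruns with
#' identical inputs produce byte-identical files.
#'
#' @param report A `percentile_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "percentile_report"))
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a percentile report CSV
#'
#' Reads the CSV shape written by [write_report_csv()] (also the shape of the
#' packaged dietary/reference percentile tables). Missing cells are `NA`.
#'
#' @param path CSV path.
#' @return Data frame with columns `percentile`, `point`, `ci_lower`,
#'   `ci_upper`.
#' @export
read_report_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("percentile", "point")
  if (!all(need %in% names(df)))
    stop("report CSV needs at least columns 'percentile' and 'point'",
         call. = FALSE)
  if (is.null(df$ci_lower)) df$ci_lower <- NA_real_
  if (is.null(df$ci_upper)) df$ci_upper <- NA_real_
  df[c("percentile", "point", "ci_lower", "ci_upper")]
}
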