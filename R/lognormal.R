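# Lognormal distribution specifications and fitting from published evidence.
#
# Every input variable of the intake model (ingestion rate, concentration,
# body weight) is carried as a fitted lognormal on the log scale; exact
# lognormal algebra on these objects doubles as the closed-form oracle for
# the Monte Carlo engine.

new_lognormal_spec <- function(mu, sigma, unit_label = "") {
  structure(list(mu = mu, sigma = sigma, unit_label = unit_label),
            class = "lognormal_spec")
}

#' Lognormal distribution specification
#'
#' The package's universal distribution currency: a lognormal described by its
#' log-space location `mu` and scale `sigma`, i.e. `log(X) ~ N(mu, sigma^2)`.
#' A degenerate (point-mass) distribution is only constructed explicitly via
#' [point_mass()].
#'
#' @param mu Log-space location (natural log of the variable's unit).
#' @param sigma Log-space scale, strictly positive.
#' @param unit_label Free-text unit, e.g. `"ug/g"`, `"mg/day"`, `"kg"`.
#' @return An object of class `lognormal_spec`.
#' @seealso [fit_lognormal()], [point_mass()], [lognormal_quantile()]
#' @examples
#' lognormal_spec(0, 1)
#' @export
lognormal_spec <- function(mu, sigma, unit_label = "") {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("`mu` must be a single finite number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("`sigma` must be a single finite number > 0; ",
         "use point_mass() for a degenerate distribution", call. = FALSE)
  new_lognormal_spec(mu, sigma, unit_label)
}

#' @describeIn lognormal_spec Degenerate distribution concentrated at `value`
#'   (> 0), represented as `sigma = 0`.
#' @param value Point-mass location, > 0.
#' @export
point_mass <- function(value, unit_label = "") {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop("`value` must be a single finite number > 0", call. = FALSE)
  new_lognormal_spec(log(value), 0, unit_label)
}

is_lognormal_spec <- function(x) inherits(x, "lognormal_spec")

is_point_mass <- function(spec) spec$sigma == 0

#' Analytic moments of a lognormal specification
#'
#' Closed-form arithmetic mean `exp(mu + sigma^2/2)` and standard deviation
#' `mean * sqrt(exp(sigma^2) - 1)`.
#'
#' @param spec A [lognormal_spec()].
#' @return A single number.
#' @export
lnorm_mean <- function(spec) {
  stopifnot(is_lognormal_spec(spec))
  exp(spec$mu + spec$sigma^2 / 2)
}

#' @rdname lnorm_mean
#' @export
lnorm_sd <- function(spec) {
  stopifnot(is_lognormal_spec(spec))
  lnorm_mean(spec) * sqrt(expm1(spec$sigma^2))
}

#' @export
print.lognormal_spec <- function(x, ...) {
  cat("Lognormal specification",
      if (nzchar(x$unit_label)) paste0("[", x$unit_label, "]"), "\n")
  cat(sprintf("  mu = %.6g, sigma = %.6g%s\n", x$mu, x$sigma,
              if (is_point_mass(x)) "  (point mass)" else ""))
  cat(sprintf("  arithmetic mean = %.6g, sd = %.6g, RSD = %.4g\n",
              lnorm_mean(x), lnorm_sd(x), rsd(x)))
  invisible(x)
}

# ---- evidence containers ----------------------------------------------------

#' Published summary moments of a positive variable
#'
#' Arithmetic mean/SD pair as printed in study tables.
#'
#' @param mean Arithmetic mean, > 0.
#' @param sd Arithmetic standard deviation, >= 0.
#' @param n Optional sample count.
#' @return An object of class `summary_moments`.
#' @export
summary_moments <- function(mean, sd, n = NA_integer_) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("invalid summary: `mean` must be a single number > 0", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("invalid summary: `sd` must be a single number >= 0", call. = FALSE)
  if (!is.na(n) && (n < 1 || n != round(n)))
    stop("invalid summary: `n` must be a positive integer", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = n), class = "summary_moments")
}

#' Published percentile table of a positive variable
#'
#' Ordered (probability, value) pairs, e.g. a growth-chart row.
#'
#' @param probabilities Strictly increasing probabilities in (0, 1).
#' @param values Non-decreasing positive values, same length.
#' @return An object of class `percentile_table`.
#' @export
percentile_table <- function(probabilities, values) {
  if (length(probabilities) != length(values))
    stop("probabilities and values must have equal length", call. = FALSE)
  if (length(probabilities) < 2L)
    stop("insufficient data: a percentile table needs at least 2 entries",
         call. = FALSE)
  if (any(!is.finite(probabilities)) || any(probabilities <= 0) ||
      any(probabilities >= 1))
    stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
  if (any(diff(probabilities) <= 0))
    stop("invalid table: probabilities must be strictly increasing ",
         "(no duplicates)", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("percentile values must all be > 0", call. = FALSE)
  if (any(diff(values) < 0))
    stop("invalid table: values must be non-decreasing", call. = FALSE)
  structure(list(probabilities = as.numeric(probabilities),
                 values = as.numeric(values)),
            class = "percentile_table")
}

#' Left-censored concentration sample
#'
#' Raw concentrations with a detection limit: entries flagged `censored` are
#' below the LOD and are replaced by LOD/2 in downstream estimation
#' ([substitute_half_lod()]).
#'
#' @param values Concentrations (observed entries > 0).
#' @param censored Logical vector, parallel to `values`; `TRUE` = below LOD.
#' @param lod Limit of detection, > 0, in the same unit.
#' @return An object of class `censored_sample`.
#' @export
censored_sample <- function(values, censored, lod) {
  if (!is.numeric(lod) || length(lod) != 1L || !is.finite(lod) || lod <= 0)
    stop("invalid LOD: must be a single number > 0", call. = FALSE)
  if (length(values) != length(censored))
    stop("`values` and `censored` must have equal length", call. = FALSE)
  censored <- as.logical(censored)
  if (anyNA(censored))
    stop("`censored` must be TRUE/FALSE with no missing values", call. = FALSE)
  obs <- values[!censored]
  if (any(!is.finite(obs)) || any(obs < 0))
    stop("uncensored values must be finite and >= 0", call. = FALSE)
  structure(list(values = as.numeric(values), censored = censored, lod = lod),
            class = "censored_sample")
}

#' @export
length.censored_sample <- function(x) length(x$values)

# ---- fitting ----------------------------------------------------------------

#' Fit a lognormal specification from published evidence
#'
#' A single generic covering the three kinds of evidence studies publish:
#'
#' * `summary_moments`: exact moment matching,
#'   `sigma = sqrt(log(1 + (sd/mean)^2))`, `mu = log(mean) - sigma^2/2`.
#'   The analytic mean/SD of the result reproduce the inputs exactly.
#' * `percentile_table`: least-squares fit of `log(value)` against the
#'   standard-normal quantile of probability (a probit plot); the slope is
#'   `sigma`, the intercept `mu`. With exactly two entries the fit
#'   interpolates them exactly.
#' * `censored_sample`: half-LOD substitution ([substitute_half_lod()])
#'   followed by moment matching on the substituted sample (at least 3
#'   entries required).
#'
#' @param x Evidence object ([summary_moments()], [percentile_table()], or
#'   [censored_sample()]).
#' @param unit_label Unit carried into the result.
#' @param ... Passed to methods.
#' @return A [lognormal_spec()].
#' @examples
#' fit_lognormal(summary_moments(mean = 26.65, sd = 36.54))
#' fit_lognormal(percentile_table(c(0.25, 0.75), exp(c(-1, 1))))
#' @export
fit_lognormal <- function(x, ...) UseMethod("fit_lognormal")

#' @rdname fit_lognormal
#' @export
fit_lognormal.summary_moments <- function(x, unit_label = "", ...) {
  if (x$sd == 0) return(point_mass(x$mean, unit_label))
  cv2 <- (x$sd / x$mean)^2
  sigma <- sqrt(log1p(cv2))
  mu <- log(x$mean) - sigma^2 / 2
  new_lognormal_spec(mu, sigma, unit_label)
}

#' @rdname fit_lognormal
#' @export
fit_lognormal.percentile_table <- function(x, unit_label = "", ...) {
  z <- stats::qnorm(x$probabilities)
  ly <- log(x$values)
  fit <- stats::lm.fit(cbind(1, z), ly)
  mu <- unname(fit$coefficients[1L])
  sigma <- unname(fit$coefficients[2L])
  if (sigma < 0)
    stop("percentile table implies a negative scale; not lognormal",
         call. = FALSE)
  if (sigma == 0) return(point_mass(exp(mu), unit_label))
  new_lognormal_spec(mu, sigma, unit_label)
}

#' @rdname fit_lognormal
#' @export
fit_lognormal.censored_sample <- function(x, unit_label = "", ...) {
  if (length(x) < 3L)
    stop("insufficient data: censored fitting needs at least 3 observations",
         call. = FALSE)
  v <- substitute_half_lod(x)
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) return(point_mass(m, unit_label))
  fit_lognormal(summary_moments(m, s, length(v)), unit_label = unit_label)
}

#' Half-LOD substitution for left-censored samples
#'
#' Replaces every below-detection entry by half the limit of detection and
#' leaves observed entries untouched; the conventional pre-processing applied
#' to censored residue concentrations before distribution fitting.
#'
#' @param sample A [censored_sample()].
#' @return Numeric vector, same length as the input.
#' @export
substitute_half_lod <- function(sample) {
  stopifnot(inherits(sample, "censored_sample"))
  out <- sample$values
  out[sample$censored] <- sample$lod / 2
  out
}

# ---- lognormal algebra ------------------------------------------------------

#' Quantiles of a lognormal specification
#'
#' `exp(mu + sigma * qnorm(p))`; for a point mass every quantile is the mass
#' location.
#'
#' @param spec A [lognormal_spec()].
#' @param p Probabilities in (0, 1); vectorised.
#' @return Numeric vector of quantiles.
#' @export
lognormal_quantile <- function(spec, p) {
  stopifnot(is_lognormal_spec(spec))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  exp(spec$mu + spec$sigma * stats::qnorm(p))
}

#' Exact distribution of a product/quotient of independent lognormals
#'
#' For independent lognormal factors the product (numerators) over a product
#' (denominators), times a positive constant, is again lognormal with
#' `mu = sum(mu_num) - sum(mu_den) + log(scale)` and
#' `sigma = sqrt(sum(sigma_num^2) + sum(sigma_den^2))`. This closed form is
#' the oracle against which the Monte Carlo engine is validated.
#'
#' @param numerators A [lognormal_spec()] or list of them; must be non-empty.
#' @param denominators A [lognormal_spec()] or list of them; may be empty.
#' @param scale Positive multiplicative constant.
#' @param unit_label Unit carried into the result.
#' @return A [lognormal_spec()].
#' @export
combine_product_quotient <- function(numerators, denominators = list(),
                                     scale = 1, unit_label = "") {
  as_spec_list <- function(x) {
    if (is_lognormal_spec(x)) list(x) else as.list(x)
  }
  num <- as_spec_list(numerators)
  den <- as_spec_list(denominators)
  if (length(num) == 0L)
    stop("invalid composition: at least one numerator is required",
         call. = FALSE)
  all_specs <- c(num, den)
  if (!all(vapply(all_specs, is_lognormal_spec, logical(1))))
    stop("all factors must be lognormal_spec objects", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("`scale` must be a single number > 0", call. = FALSE)
  mu <- sum(vapply(num, `[[`, numeric(1), "mu")) -
    sum(vapply(den, `[[`, numeric(1), "mu")) + log(scale)
  sigma <- sqrt(sum(vapply(all_specs, function(s) s$sigma^2, numeric(1))))
  new_lognormal_spec(mu, sigma, unit_label)
}

#' Relative standard deviation (SD/mean)
#'
#' Unitless dispersion diagnostic used to rank input variability. For a
#' fitted lognormal the analytic form `sqrt(exp(sigma^2) - 1)` is used.
#'
#' @param x A [summary_moments()] or [lognormal_spec()].
#' @param ... Unused.
#' @return A single non-negative number.
#' @examples
#' rsd(summary_moments(26.65, 36.54)) # 1.37
#' @export
rsd <- function(x, ...) UseMethod("rsd")

#' @rdname rsd
#' @export
rsd.summary_moments <- function(x, ...) x$sd / x$mean

#' @rdname rsd
#' @export
rsd.lognormal_spec <- function(x, ...) sqrt(expm1(x$sigma^2))
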