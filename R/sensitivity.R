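# Contribution-to-variance sensitivity analysis.
#
# Two estimators, reported side by side:
#  * rank correlation: normalized squared Spearman correlations between each
#    input's draws and the simulated output (the convention of commercial
#    Monte Carlo tools);
#  * log-variance: for a pure product/quotient of independent lognormals the
#    variance of log intake decomposes exactly into the inputs' sigma^2, so
#    shares are 100 * sigma_i^2 / sum(sigma_j^2), no simulation needed.

new_sensitivity_report <- function(df, method) {
  structure(list(shares = df, method = method), class = "sensitivity_report")
}

#' Contribution to variance by rank correlation
#'
#' Computes the Spearman rank correlation `rho_i` between each input variable
#' and the output, and reports `100 * rho_i^2 / sum_j rho_j^2` per variable.
#' Ties are handled by midranks. A constant (degenerate) input gets share 0
#' and is flagged. Shares are invariant to monotone rescaling of the output
#' (e.g. intake vs %ADI).
#'
#' @param inputs Data frame or matrix of input draws (one column per
#'   variable, >= 100 rows).
#' @param output Numeric vector of output draws, same length.
#' @return A `sensitivity_report`; `$shares` has columns `variable`, `rho`,
#'   `share`, `degenerate`.
#' @examples
#' d <- simulate_draws(load_scenario("chlorpyrifos_dust"), n = 5000, seed = 7)
#' contribution_rank_correlation(d[c("ir", "conc", "bw")], d$pct_adi)
#' @export
contribution_rank_correlation <- function(inputs, output) {
  inputs <- as.data.frame(inputs)
  n <- nrow(inputs)
  if (n < 100L)
    stop("need at least 100 draws for the rank-correlation estimator",
         call. = FALSE)
  if (length(output) != n)
    stop("`output` must have one value per input row", call. = FALSE)
  degenerate <- vapply(inputs, function(v) length(unique(v)) == 1L, logical(1))
  rho <- vapply(seq_along(inputs), function(j) {
    if (degenerate[j]) return(0)
    stats::cor(inputs[[j]], output, method = "spearman")
  }, numeric(1))
  denom <- sum(rho^2)
  share <- if (denom == 0) rep(0, length(rho)) else 100 * rho^2 / denom
  new_sensitivity_report(
    data.frame(variable = names(inputs), rho = rho, share = share,
               degenerate = degenerate),
    method = "rank_correlation")
}

#' Contribution to variance by exact log-variance decomposition
#'
#' For the intake equation with independent lognormal inputs,
#' `Var(log intake) = sigma_ir^2 + sigma_conc^2 + sigma_bw^2` exactly, so
#' each variable's share is `100 * sigma_i^2 / sum(sigma_j^2)`.
#'
#' @param scenario An [exposure_scenario()].
#' @return A `sensitivity_report` with columns `variable`, `sigma`, `share`,
#'   `degenerate`.
#' @export
contribution_log_variance <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  sig <- c(ir = scenario$ir$sigma, conc = scenario$conc$sigma,
           bw = scenario$bw$sigma)
  denom <- sum(sig^2)
  if (denom == 0)
    stop("undefined decomposition: all inputs are point masses", call. = FALSE)
  new_sensitivity_report(
    data.frame(variable = names(sig), sigma = unname(sig),
               share = unname(100 * sig^2 / denom),
               degenerate = unname(sig == 0)),
    method = "log_variance")
}

#' Scenario-level sensitivity analysis
#'
#' Convenience wrapper running either estimator on a scenario: the analytic
#' log-variance decomposition directly, or the rank-correlation estimator on
#' `n` fresh draws.
#'
#' @param scenario An [exposure_scenario()].
#' @param method `"rank_correlation"` or `"log_variance"`.
#' @param n Draws for the rank-correlation estimator.
#' @param seed RNG seed for the rank-correlation estimator.
#' @return A `sensitivity_report`.
#' @export
sensitivity_analysis <- function(scenario,
                                 method = c("rank_correlation",
                                            "log_variance"),
                                 n = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (method == "log_variance") return(contribution_log_variance(scenario))
  d <- simulate_draws(scenario, n = n, seed = seed)
  contribution_rank_correlation(d[c("ir", "conc", "bw")], d$pct_adi)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Contribution to variance (", x$method, ")\n", sep = "")
  df <- x$shares
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-5s %6.2f%%%s\n", df$variable[i], df$share[i],
                if (df$degenerate[i]) "  (degenerate input)" else ""))
  invisible(x)
}

#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(variable = x$shares$variable, method = x$method,
             share_percent = x$shares$share)
}

#' Write a sensitivity report to CSV
#'
#' Columns `variable`, `method`, `share_percent`.
#'
#' @param report A `sensitivity_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(report, path) {
  stopifnot(inherits(report, "sensitivity_report"))
  df <- as.data.frame(report)
  df$share_percent <- sprintf("%.15g", df$share_percent)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
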