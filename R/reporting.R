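# Result rendering and route comparison.
#
# Percent-of-ADI values are rendered with the survey-table conventions:
# values below 0.001% print as "<0.001%", values below 10% with three
# decimals, values at or above 10% with two. Ratios are computed from
# unrounded values and rounded exactly once, at render time.

#' Format percent-of-ADI values for display
#'
#' @param x Numeric vector of percentages.
#' @return Character vector: `"<0.001%"` below the display floor, `"%.3f%%"`
#'   below 10, `"%.2f%%"` at or above 10.
#' @examples
#' format_pct(c(0.0004, 8.3127, 16.894))
#' @export
format_pct <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  lo <- !is.na(x) & x < 0.001
  mid <- !is.na(x) & x >= 0.001 & x < 10
  hi <- !is.na(x) & x >= 10
  out[lo] <- "<0.001%"
  out[mid] <- sprintf("%.3f%%", x[mid])
  out[hi] <- sprintf("%.2f%%", x[hi])
  out
}

# inverse of format_pct, used to check renders are lossless above the floor
parse_pct <- function(s) {
  out <- rep(NA_real_, length(s))
  floor_mask <- s == "<0.001%"
  num <- !floor_mask & s != "NA"
  out[num] <- as.numeric(sub("%$", "", s[num]))
  out[floor_mask] <- 0
  out
}

percentile_label <- function(p) {
  paste0("P", sub("\\.?0+$", "", sprintf("%.2f", 100 * p)))
}

#' Render a percentile report as a plain-text table
#'
#' One line per percentile: `P99  0.884% (0.880%, 0.887%)`, using the
#' [format_pct()] precision and floor conventions.
#'
#' @param report A `percentile_report` or a data frame with columns
#'   `percentile`, `point`, `ci_lower`, `ci_upper`.
#' @return Character vector of table lines.
#' @export
render_percentile_table <- function(report) {
  df <- as.data.frame(report)
  has_ci <- !all(is.na(df$ci_lower))
  lines <- vapply(seq_len(nrow(df)), function(i) {
    lab <- percentile_label(df$percentile[i])
    if (has_ci)
      sprintf("%-6s %s (%s, %s)", lab, format_pct(df$point[i]),
              format_pct(df$ci_lower[i]), format_pct(df$ci_upper[i]))
    else
      sprintf("%-6s %s", lab, format_pct(df$point[i]))
  }, character(1))
  lines
}

#' Compare non-dietary against dietary exposure percentiles
#'
#' Aligns a simulated (or published) non-dietary percentile report with an
#' external dietary percentile table on their shared percentiles and computes
#' the dietary/non-dietary ratio wherever both sides are present and the
#' non-dietary value is positive. Ratios are kept unrounded internally and
#' rendered to 2 decimal places by `print()`.
#'
#' @param nondietary A `percentile_report` or data frame (columns
#'   `percentile`, `point`, `ci_lower`, `ci_upper`) of non-dietary %ADI.
#' @param dietary Data frame of the same shape with the external dietary %ADI
#'   percentiles (missing entries `NA`).
#' @return An object of class `route_comparison`: a data frame with columns
#'   `percentile`, `nondietary`, `nondietary_lower`, `nondietary_upper`,
#'   `dietary`, `dietary_lower`, `dietary_upper`, `ratio`.
#' @examples
#' nd <- read_report_csv(system.file("extdata", "reference",
#'   "nondietary_total_chlorpyrifos.csv", package = "dustintake"))
#' di <- read_report_csv(system.file("extdata", "reference",
#'   "dietary_chlorpyrifos.csv", package = "dustintake"))
#' build_comparison(nd, di)
#' @export
build_comparison <- function(nondietary, dietary) {
  nd <- as.data.frame(nondietary)
  di <- as.data.frame(dietary)
  shared <- intersect(nd$percentile, di$percentile)
  if (length(shared) == 0L)
    stop("empty comparison: no overlapping percentiles", call. = FALSE)
  shared <- sort(shared)
  ndi <- match(shared, nd$percentile)
  dii <- match(shared, di$percentile)
  out <- data.frame(percentile = shared,
                    nondietary = nd$point[ndi],
                    nondietary_lower = nd$ci_lower[ndi],
                    nondietary_upper = nd$ci_upper[ndi],
                    dietary = di$point[dii],
                    dietary_lower = di$ci_lower[dii],
                    dietary_upper = di$ci_upper[dii])
  out$ratio <- ifelse(!is.na(out$dietary) & !is.na(out$nondietary) &
                        out$nondietary > 0,
                      out$dietary / out$nondietary, NA_real_)
  structure(out, class = c("route_comparison", "data.frame"))
}

#' @export
print.route_comparison <- function(x, ...) {
  cat("Non-dietary vs dietary ingestion exposure (% of ADI)\n")
  cat(sprintf("%-7s %-24s %-24s %s\n", "", "non-dietary", "dietary",
              "dietary/non-dietary"))
  for (i in seq_len(nrow(x))) {
    fmt_side <- function(p, l, u) {
      if (is.na(p)) return("NA")
      if (is.na(l) || is.na(u)) return(format_pct(p))
      sprintf("%s (%s, %s)", format_pct(p), format_pct(l), format_pct(u))
    }
    cat(sprintf("%-7s %-24s %-24s %s\n",
                percentile_label(x$percentile[i]),
                fmt_side(x$nondietary[i], x$nondietary_lower[i],
                         x$nondietary_upper[i]),
                fmt_side(x$dietary[i], x$dietary_lower[i], x$dietary_upper[i]),
                if (is.na(x$ratio[i])) "NA" else sprintf("%.2f", x$ratio[i])))
  }
  invisible(x)
}

#' Write a route comparison to CSV
#'
#' @param comparison A `route_comparison`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  stopifnot(inherits(comparison, "route_comparison"))
  df <- as.data.frame(comparison)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.15g", v)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-scale density plot of simulated %ADI
#'
#' Kernel density of log10(% of ADI) from fresh scenario draws; the simulated
#' intake of a lognormal-only scenario is itself lognormal, so the curve
#' should look Gaussian on this axis.
#'
#' @param scenario An [exposure_scenario()].
#' @param n Number of draws.
#' @param seed RNG seed.
#' @param ... Passed to [graphics::plot()].
#' @return The draws, invisibly.
#' @export
plot_intake_density <- function(scenario, n = 1e5, seed = 1L, ...) {
  d <- simulate_draws(scenario, n = n, seed = seed)
  dens <- stats::density(log10(d$pct_adi))
  graphics::plot(dens, xlab = "log10(% of ADI)",
                 main = sprintf("%s via %s", scenario$compound,
                                scenario$route), ...)
  invisible(d)
}
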