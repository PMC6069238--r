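# Scenario configuration: YAML scenario files and censored-sample CSVs.
#
# A scenario file declares compound, route, ADI, conversion factor, and one
# block per variable (ir, conc, bw). Each block may carry `moments`
# (mean/sd/n), `percentiles` (probabilities/values), or `censored_values`
# (values/censored/lod); `kind` names the default evidence used for fitting,
# and the loader's `parameterization` switch can override it for variables
# that publish both moments and percentiles.

#' List the scenario files shipped with the package
#'
#' Four scenarios covering the two compounds by the two ingestion routes,
#' with the published summary distributions of ingestion rate, residue
#' concentration, and child body weight.
#'
#' @return Character vector of scenario names usable with [load_scenario()].
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "dustintake")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

scenario_file <- function(name) {
  if (file.exists(name)) return(name)
  f <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                   package = "dustintake")
  if (!nzchar(f))
    stop("unknown scenario '", name, "'; available: ",
         paste(list_scenarios(), collapse = ", "), call. = FALSE)
  f
}

fit_variable_block <- function(block, name, parameterization) {
  unit <- if (is.null(block$unit)) "" else block$unit
  has_m <- !is.null(block$moments)
  has_p <- !is.null(block$percentiles)
  has_c <- !is.null(block$censored_values)
  kind <- parameterization
  # fall back to whatever evidence the block actually carries
  if (kind == "moments" && !has_m) kind <- if (has_p) "percentiles" else "censored_values"
  if (kind == "percentiles" && !has_p) kind <- if (has_m) "moments" else "censored_values"
  spec <- switch(kind,
    moments = fit_lognormal(
      summary_moments(block$moments$mean, block$moments$sd,
                      if (is.null(block$moments$n)) NA else block$moments$n),
      unit_label = unit),
    percentiles = fit_lognormal(
      percentile_table(unlist(block$percentiles$probabilities),
                       unlist(block$percentiles$values)),
      unit_label = unit),
    censored_values = fit_lognormal(
      censored_sample(unlist(block$censored_values$values),
                      unlist(block$censored_values$censored),
                      block$censored_values$lod),
      unit_label = unit),
    stop("variable '", name, "' carries no usable evidence", call. = FALSE))
  spec
}

#' Load an exposure scenario from a YAML file
#'
#' @param name A packaged scenario name (see [list_scenarios()]) or a path to
#'   a scenario YAML file.
#' @param parameterization Which published evidence to fit the lognormals
#'   from where a variable carries both: `"moments"` (mean/SD moment
#'   matching, the default) or `"percentiles"` (probit least squares).
#'   Variables that publish only one kind (e.g. body weight, percentiles
#'   only) always use what they have.
#' @param truncate_at_maximum If `TRUE`, each variable that declares a
#'   `maximum` in the file is sampled truncated at that bound. Default
#'   `FALSE` (untruncated).
#' @return An [exposure_scenario()].
#' @examples
#' load_scenario("chlorpyrifos_dust")
#' @export
load_scenario <- function(name,
                          parameterization = c("moments", "percentiles"),
                          truncate_at_maximum = FALSE) {
  parameterization <- match.arg(parameterization)
  cfg <- yaml::read_yaml(scenario_file(name))
  for (field in c("compound", "route", "variables"))
    if (is.null(cfg[[field]]))
      stop("scenario file missing required field '", field, "'", call. = FALSE)
  vars <- cfg$variables
  for (v in c("ir", "conc", "bw"))
    if (is.null(vars[[v]]))
      stop("scenario file missing variable block '", v, "'", call. = FALSE)
  specs <- lapply(c(ir = "ir", conc = "conc", bw = "bw"), function(v)
    fit_variable_block(vars[[v]], v, parameterization))
  truncation <- NULL
  if (isTRUE(truncate_at_maximum)) {
    truncation <- Filter(Negate(is.null),
                         lapply(vars, function(b) b$maximum))
    if (length(truncation) == 0L) truncation <- NULL
  }
  exposure_scenario(compound = cfg$compound, route = cfg$route,
                    ir = specs$ir, conc = specs$conc, bw = specs$bw,
                    adi = cfg$adi,
                    cf = if (is.null(cfg$cf)) 1e-3 else cfg$cf,
                    truncation = truncation,
                    parameterization = parameterization)
}

#' Consistency diagnostics between published moments and percentiles
#'
#' Published summary rows are sometimes internally inconsistent with a single
#' lognormal: the moment-matched fit can imply upper percentiles far from the
#' printed ones (heavily skewed residue data are the usual culprit). This
#' function compares, for every variable carrying both kinds of evidence, the
#' moment-fit quantiles against the printed percentile values. Discrepancies
#' are reported, never silently corrected.
#'
#' @param name Scenario name or path, as in [load_scenario()].
#' @param flag_ratio Flag entries whose fitted/printed ratio falls outside
#'   `[1/flag_ratio, flag_ratio]`.
#' @return A data frame with columns `variable`, `probability`, `printed`,
#'   `fitted_from_moments`, `ratio`, `flagged`.
#' @export
scenario_diagnostics <- function(name, flag_ratio = 3) {
  cfg <- yaml::read_yaml(scenario_file(name))
  out <- list()
  for (v in names(cfg$variables)) {
    b <- cfg$variables[[v]]
    if (is.null(b$moments) || is.null(b$percentiles)) next
    spec <- fit_lognormal(summary_moments(b$moments$mean, b$moments$sd))
    p <- unlist(b$percentiles$probabilities)
    printed <- unlist(b$percentiles$values)
    fitted <- lognormal_quantile(spec, p)
    ratio <- fitted / printed
    out[[v]] <- data.frame(variable = v, probability = p, printed = printed,
                           fitted_from_moments = fitted, ratio = ratio,
                           flagged = ratio > flag_ratio | ratio < 1 / flag_ratio)
  }
  if (length(out) == 0L)
    return(data.frame(variable = character(), probability = numeric(),
                      printed = numeric(), fitted_from_moments = numeric(),
                      ratio = numeric(), flagged = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read and write left-censored concentration CSVs
#'
#' The on-disk form is a two-column CSV (`value`, `censored`) preceded by a
#' header comment line `# lod=<value>` recording the detection limit.
#'
#' @param path File path.
#' @return For the reader, a [censored_sample()].
#' @export
read_censored_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*lod\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L)
    stop("censored CSV must start with a '# lod=<value>' header line",
         call. = FALSE)
  lod <- as.numeric(m[2])
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("value", "censored") %in% names(df)))
    stop("censored CSV needs columns 'value' and 'censored'", call. = FALSE)
  censored_sample(df$value, as.logical(df$censored), lod)
}

#' @rdname read_censored_csv
#' @param sample A [censored_sample()] to write.
#' @export
write_censored_csv <- function(sample, path) {
  stopifnot(inherits(sample, "censored_sample"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lod=%.15g", sample$lod), con)
  utils::write.csv(data.frame(value = sample$values,
                              censored = sample$censored),
                   con, row.names = FALSE)
  invisible(path)
}
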