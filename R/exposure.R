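# Intake equation and risk normalization.
#
# Daily intake (ug/kg/day) = IR (mg/day) x C (ug/g) x CF (g/mg) / BW (kg),
# reported as percent of the compound's Acceptable Daily Intake (mg/kg/day).
# Units are fixed package-wide; anything else must be converted at the config
# boundary.

.adi_registry <- c(chlorpyrifos = 0.01, cypermethrin = 0.02)

#' Acceptable Daily Intake registry
#'
#' WHO ADI values shipped with the package: chlorpyrifos 0.01 and cypermethrin
#' 0.02 mg/kg body weight/day. Custom compounds must supply an explicit ADI.
#'
#' @param compound Compound name.
#' @return ADI in mg/kg/day.
#' @export
default_adi <- function(compound) {
  if (!compound %in% names(.adi_registry))
    stop("no registered ADI for '", compound,
         "'; supply `adi` explicitly", call. = FALSE)
  unname(.adi_registry[[compound]])
}

#' Exposure scenario: one route of one compound
#'
#' Bundles the three input distributions of the intake equation with the unit
#' conversion factor and the compound's ADI. Optional upper truncation bounds
#' per variable restrict sampling to (0, bound]; by default distributions are
#' untruncated.
#'
#' @param compound Compound label (`"chlorpyrifos"`, `"cypermethrin"`, or a
#'   custom name with explicit `adi`).
#' @param route Route label, e.g. `"indoor_dust"` or `"outdoor_soil"`.
#' @param ir [lognormal_spec()] for the dust/soil ingestion rate (mg/day).
#' @param conc [lognormal_spec()] for the residue concentration (ug/g).
#' @param bw [lognormal_spec()] for child body weight (kg).
#' @param adi Acceptable daily intake (mg/kg/day); defaults to the registry
#'   value for known compounds.
#' @param cf Conversion factor (g/mg); fixed at `1e-3` unless overridden.
#' @param truncation Optional named list of upper bounds (`ir`, `conc`, `bw`).
#' @param parameterization Label recording how the distributions were fitted
#'   (`"moments"` or `"percentiles"`); carried into report metadata.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(compound, route, ir, conc, bw,
                              adi = NULL, cf = 1e-3, truncation = NULL,
                              parameterization = "moments") {
  stopifnot(is_lognormal_spec(ir), is_lognormal_spec(conc),
            is_lognormal_spec(bw))
  if (is.null(adi)) adi <- default_adi(compound)
  if (!is.numeric(adi) || length(adi) != 1L || !is.finite(adi) || adi <= 0)
    stop("`adi` must be a single number > 0 (mg/kg/day)", call. = FALSE)
  if (!is.numeric(cf) || length(cf) != 1L || !is.finite(cf) || cf <= 0)
    stop("`cf` must be a single number > 0 (g/mg)", call. = FALSE)
  if (!is.null(truncation)) {
    bad <- setdiff(names(truncation), c("ir", "conc", "bw"))
    if (length(bad))
      stop("unknown truncation variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(unlist(truncation) <= 0))
      stop("truncation bounds must be > 0", call. = FALSE)
  }
  structure(list(compound = compound, route = route,
                 ir = ir, conc = conc, bw = bw,
                 adi = adi, cf = cf, truncation = truncation,
                 parameterization = parameterization),
            class = "exposure_scenario")
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("Exposure scenario: %s via %s (ADI %.3g mg/kg/day, CF %g g/mg)\n",
              x$compound, x$route, x$adi, x$cf))
  for (v in c("ir", "conc", "bw")) {
    s <- x[[v]]
    cat(sprintf("  %-4s LN(mu = %.4g, sigma = %.4g) [%s]%s\n",
                v, s$mu, s$sigma, s$unit_label,
                if (!is.null(x$truncation[[v]]))
                  sprintf("  truncated at %.4g", x$truncation[[v]]) else ""))
  }
  cat("  parameterization:", x$parameterization, "\n")
  invisible(x)
}

#' Daily intake from one Monte Carlo draw
#'
#' `ir * conc * cf / bw` in ug/kg/day (mg/day x ug/g x g/mg / kg). Vectorised;
#' all vectors are recycled by ordinary R rules.
#'
#' @param ir Ingestion rate draw(s), mg/day, >= 0.
#' @param conc Concentration draw(s), ug/g, >= 0.
#' @param bw Body-weight draw(s), kg, > 0.
#' @param cf Conversion factor, g/mg.
#' @return Intake in ug/kg/day.
#' @examples
#' intake_from_draw(26.65, 2.32, 17.3) # Table-mean plug-in
#' @export
intake_from_draw <- function(ir, conc, bw, cf = 1e-3) {
  if (any(bw <= 0)) stop("`bw` must be > 0", call. = FALSE)
  if (any(ir < 0) || any(conc < 0) || cf <= 0)
    stop("`ir` and `conc` must be >= 0 and `cf` > 0", call. = FALSE)
  ir * conc * cf / bw
}

#' Intake as percent of the Acceptable Daily Intake
#'
#' `100 * intake / (1000 * adi)`: the intake is in ug/kg/day while the ADI is
#' registered in mg/kg/day, hence the factor 1000.
#'
#' @param intake Daily intake, ug/kg/day. Vectorised.
#' @param adi Acceptable daily intake, mg/kg/day, > 0.
#' @return Percent of ADI.
#' @export
percent_of_adi <- function(intake, adi) {
  if (!is.numeric(adi) || length(adi) != 1L || !is.finite(adi) || adi <= 0)
    stop("`adi` must be a single number > 0", call. = FALSE)
  100 * intake / (1000 * adi)
}
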