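# Shared fixtures: packaged scenarios and a tiny all-point-mass scenario.

table1_scenarios <- function(parameterization = "moments") {
  lapply(stats::setNames(nm = list_scenarios()), load_scenario,
         parameterization = parameterization)
}

point_mass_scenario <- function(ir = 10, conc = 1, bw = 10, adi = 0.01) {
  exposure_scenario("custom", "test", ir = point_mass(ir),
                    conc = point_mass(conc), bw = point_mass(bw), adi = adi)
}

# closed-form %ADI distribution of a lognormal-only scenario
scenario_oracle <- function(sc) {
  combine_product_quotient(list(sc$ir, sc$conc), list(sc$bw),
                           scale = sc$cf * 100 / (1000 * sc$adi))
}

reference_csv <- function(name) {
  read_report_csv(system.file("extdata", "reference", name,
                              package = "dustintake"))
}
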