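# Shared instrument fixtures: the trapezoidal channel, constant-flow method
# and aqueous carrier used across the suite. Calibration maps the albumin
# monomer reference (Rh 3.2 nm at 4.5 min) onto the nominal geometry once.
nominal_geometry <- channel_geometry()
std_flows <- flow_conditions()
std_solvent <- solvent_conditions()
cal_geometry <- calibrate_thickness(3.2, 4.5, nominal_geometry,
                                    std_flows, std_solvent)

# 93:7 albumin monomer/dimer mix at 2 mg/mL total
hsa_mix <- function(total_mg_ml = 2, monomer_fraction = 0.93) {
  mix <- dplyr::bind_rows(hsa_monomer(), hsa_dimer())
  mix$conc_mg_ml <- c(monomer_fraction, 1 - monomer_fraction) * total_mg_ml
  mix
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
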