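test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_fractogram(hsa_mix(), cal_geometry, std_flows, std_solvent,
                           noise_rel = 0.005, seed = 5)
  b <- simulate_fractogram(hsa_mix(), cal_geometry, std_flows, std_solvent,
                           noise_rel = 0.005, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_fractogram(hsa_mix(), cal_geometry, std_flows, std_solvent,
                            noise_rel = 0.005, seed = 6)
  expect_false(identical(a$uv_au, c2$uv_au))
  s1 <- simulate_saxs_curve("sphere", seed = 9)
  s2 <- simulate_saxs_curve("sphere", seed = 9)
  expect_identical(s1, s2)
})

test_that("injected mass is conserved in the dRI trace at zero noise", {
  fr <- simulate_fractogram(hsa_mix(2), cal_geometry, std_flows, std_solvent,
                            noise_rel = 0, inject_ml = 0.075)
  # mass (mg) = detector flow x integral of concentration; c = dRI / (dn/dc)
  mass <- std_flows$detector_ml_min *
    pracma::trapz(fr$time_min, fr$dri_riu / 0.185) * 1e3
  expect_rel(mass, 2 * 0.075, 0.001)
})

test_that("zero concentrations give flat baselines", {
  mix <- hsa_mix(0)
  fr <- simulate_fractogram(mix, cal_geometry, std_flows, std_solvent,
                            noise_rel = 0.005, seed = 2)
  expect_lt(max(abs(fr$uv_au)), 1e-9)
  expect_equal(nrow(fr), length(seq(0, 30, by = 0.01)))
})

test_that("species eluting beyond the run are flagged", {
  big <- species("huge", 5000, 120)
  big$conc_mg_ml <- 1
  expect_warning(
    simulate_fractogram(big, cal_geometry, std_flows, std_solvent,
                        noise_rel = 0),
    class = "af4saxs_truncation_warning")
})

test_that("the sphere form factor has its first zero at qR = 4.493", {
  cv <- simulate_saxs_curve("sphere", radius_nm = 3,
                            q = seq(0.5, 3, by = 0.001), noise_rel = 0,
                            noise_floor_frac = 0)
  i <- cv$intensity
  mins <- which(diff(sign(diff(i))) > 0) + 1
  q_first_min <- cv$q[mins[1]]
  expect_rel(q_first_min * 3, 4.4934, 0.005)
  expect_equal(simulate_saxs_curve("sphere", radius_nm = 3, q = 1e-4,
                                   noise_rel = 0,
                                   noise_floor_frac = 0)$intensity,
               1, tolerance = 1e-6)
})

test_that("the ellipsoid average reproduces the closed-form Rg", {
  cv <- simulate_saxs_curve("ellipsoid", semi_axes_nm = c(4, 4, 1.5),
                            q = seq(0.02, 3, by = 0.005), noise_rel = 0,
                            noise_floor_frac = 1e-5)
  gf <- guinier_fit(cv, q_rg_limit = 0.6)
  expect_rel(gf$rg_nm, sqrt((16 + 16 + 2.25) / 5), 0.01)
  # triaxial path agrees with the spheroid path when nearly degenerate
  tri <- simulate_saxs_curve("ellipsoid", semi_axes_nm = c(4, 3.999, 1.5),
                             q = seq(0.02, 3, by = 0.005), noise_rel = 0,
                             noise_floor_frac = 0)
  sph <- simulate_saxs_curve("ellipsoid", semi_axes_nm = c(4, 4, 1.5),
                             q = seq(0.02, 3, by = 0.005), noise_rel = 0,
                             noise_floor_frac = 0)
  expect_equal(tri$intensity, sph$intensity, tolerance = 1e-3)
})

test_that("a zero-separation dumbbell scatters as one coherent particle", {
  q <- seq(0.05, 5, by = 0.01)
  db <- simulate_saxs_curve("dumbbell", radii_nm = c(3, 3), separation_nm = 0,
                            q = q, noise_rel = 0, noise_floor_frac = 0)
  sp <- simulate_saxs_curve("sphere", radius_nm = 3, q = q, noise_rel = 0,
                            noise_floor_frac = 0)
  # normalised curves coincide; the unnormalised forward intensity is
  # (V1+V2)^2 = 4 V^2, i.e. coherent addition quadruples I(0)
  expect_equal(db$intensity, sp$intensity, tolerance = 1e-12)
})

test_that("mixtures are weighted sums of their components", {
  q <- seq(0.05, 5, by = 0.01)
  mx <- simulate_saxs_curve("mixture",
                            components = list(list(model = "sphere", radius_nm = 2),
                                              list(model = "sphere", radius_nm = 4)),
                            weights = c(0.3, 0.7), q = q, noise_rel = 0,
                            noise_floor_frac = 0)
  a <- simulate_saxs_curve("sphere", radius_nm = 2, q = q, noise_rel = 0,
                           noise_floor_frac = 0)
  b <- simulate_saxs_curve("sphere", radius_nm = 4, q = q, noise_rel = 0,
                           noise_floor_frac = 0)
  expect_equal(mx$intensity, 0.3 * a$intensity + 0.7 * b$intensity,
               tolerance = 1e-12)
  expect_error(simulate_saxs_curve("mixture",
                                   components = list(list(model = "sphere")),
                                   weights = 2),
               class = "af4saxs_domain_error")
})

test_that("fast-exchange peaks reduce to pure bands at the endpoints", {
  f0 <- simulate_fast_exchange_peak(gaz_monomer(), gaz_dimer(), 0, 2,
                                    cal_geometry, std_flows, std_solvent,
                                    noise_rel = 0)
  mono <- gaz_monomer(); mono$conc_mg_ml <- 2
  ref <- simulate_fractogram(mono, cal_geometry, std_flows, std_solvent,
                             noise_rel = 0)
  expect_equal(f0$uv_au, ref$uv_au, tolerance = 1e-9)
  f1 <- simulate_fast_exchange_peak(gaz_monomer(), gaz_dimer(), 1, 2,
                                    cal_geometry, std_flows, std_solvent,
                                    noise_rel = 0)
  dimr <- gaz_dimer(); dimr$conc_mg_ml <- 2
  ref1 <- simulate_fractogram(dimr, cal_geometry, std_flows, std_solvent,
                              noise_rel = 0)
  expect_equal(f1$uv_au, ref1$uv_au, tolerance = 1e-9)
})

test_that("co-eluting exchange shows a flat weight-average mass across the peak", {
  fe <- simulate_fast_exchange_peak(gaz_monomer(), gaz_dimer(), 0.5, 2,
                                    cal_geometry, std_flows, std_solvent,
                                    noise_rel = 0)
  prof <- peak_mass_profile(fe, c(3, 4.5), 0.196, std_solvent)
  expect_rel(prof$mw_wavg_kda, 0.5 * 11.5 + 0.5 * 23, 0.001)
  # apparent MW must not climb with retention time: the co-elution fingerprint
  expect_lt(diff(range(prof$slices$mw_kda)), 0.01)
})

test_that("titration truth follows the single-site equilibrium limits", {
  # vanishing affinity: no complex, everything stays free
  weak <- simulate_titration_series(gaz_stocks_mg_ml = c(1), kd = 10,
                                    geometry = cal_geometry, flows = std_flows,
                                    solvent = std_solvent, noise_rel = 0)
  expect_lt(weak$points$occupancy, 1e-5)
  expect_rel(weak$points$true_free_mol_l, weak$points$gaz_added_mol_l, 1e-4)
  # tight binding below saturation: free ligand is (essentially) absent
  tight <- simulate_titration_series(gaz_stocks_mg_ml = c(0.3), kd = 1e-9,
                                     geometry = cal_geometry, flows = std_flows,
                                     solvent = std_solvent, noise_rel = 0)
  expect_lt(tight$points$true_free_mol_l / tight$points$gaz_added_mol_l, 1e-3)
  expect_error(simulate_titration_series(kd = 0, geometry = cal_geometry,
                                         flows = std_flows,
                                         solvent = std_solvent),
               class = "af4saxs_domain_error")
})
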