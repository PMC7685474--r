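gauss_signal <- function(t, center, sigma, area, base = 0, slope = 0) {
  base + slope * t + area / (sigma * sqrt(2 * pi)) *
    exp(-(t - center)^2 / (2 * sigma^2))
}

test_that("a single noiseless Gaussian is recovered to numerical precision", {
  t <- seq(0, 10, by = 0.01)
  d <- data.frame(time_min = t, signal = gauss_signal(t, 4.5, 0.3, 1.0))
  fit <- fit_baseline_and_deconvolve(d, list(peak = c(3.5, 5.5)))
  expect_equal(fit$peaks$center, 4.5, tolerance = 1e-6)
  expect_equal(fit$peaks$sigma, 0.3, tolerance = 1e-6)
  expect_equal(fit$peaks$area, 1.0, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
  # the area invariant of the Gaussian peak type
  expect_equal(fit$peaks$area,
               fit$peaks$amplitude * fit$peaks$sigma * sqrt(2 * pi),
               tolerance = 1e-9)
})

test_that("overlapping Gaussians with noise are separated within 2%", {
  t <- seq(0, 12, by = 0.01)
  truth <- c(a1 = 1.0, a2 = 0.8)
  clean <- gauss_signal(t, 4.5, 0.4, truth[1]) +
    gauss_signal(t, 5.4, 0.4, truth[2])   # ~50% height overlap at the midpoint
  d <- data.frame(time_min = t,
                  signal = withr::with_seed(
                    13, clean + rnorm(length(t), sd = 0.01 * max(clean))))
  fit <- fit_baseline_and_deconvolve(d, list(first = c(3.5, 4.9),
                                             second = c(4.9, 6.5)))
  expect_rel(fit$peaks$area[1], truth[1], 0.02)
  expect_rel(fit$peaks$area[2], truth[2], 0.02)
})

test_that("flat signals yield zero-area peaks and window rules are enforced", {
  t <- seq(0, 10, by = 0.01)
  d <- data.frame(time_min = t, signal = rep(0, length(t)))
  fit <- fit_baseline_and_deconvolve(d, list(a = c(2, 4), b = c(5, 7)))
  expect_true(fit$empty)
  expect_equal(fit$peaks$area, c(0, 0))
  expect_error(
    fit_baseline_and_deconvolve(d, list(a = c(2, 5), b = c(4, 7))),
    class = "af4saxs_domain_error")  # overlapping windows
})

test_that("area integration matches closed forms", {
  t <- seq(0, 10, by = 0.01)
  rect <- data.frame(time_min = t, signal = as.numeric(t >= 4 & t <= 6))
  expect_equal(area_under_peak(rect, c(3, 7)), 2.0, tolerance = 0.01)
  g <- data.frame(time_min = t, signal = gauss_signal(t, 5, 0.4, 2.5))
  expect_rel(area_under_peak(g, c(5 - 2, 5 + 2)), 2.5, 1e-4)
  expect_lt(abs(area_under_peak(g, c(0, 1))), 1e-6)
  expect_warning(out <- area_under_peak(g, c(20, 21)),
                 class = "af4saxs_empty_window_warning")
  expect_equal(out, 0)
})

test_that("monomer/dimer content sums to one and matches generated ratios", {
  t <- seq(0, 10, by = 0.01)
  d <- data.frame(time_min = t,
                  signal = gauss_signal(t, 4.5, 0.2, 0.93) +
                    gauss_signal(t, 6.5, 0.25, 0.07))
  ct <- monomer_dimer_content(d, c(3.5, 5.5), c(5.6, 7.6))
  expect_equal(ct$monomer_fraction + ct$dimer_fraction, 1, tolerance = 1e-12)
  expect_equal(ct$monomer_fraction, 0.93, tolerance = 0.01)
  eq <- data.frame(time_min = t,
                   signal = gauss_signal(t, 4.5, 0.2, 1) +
                     gauss_signal(t, 6.5, 0.2, 1))
  expect_equal(monomer_dimer_content(eq, c(3.5, 5.5), c(5.6, 7.6))$monomer_fraction,
               0.5, tolerance = 1e-5)
  solo <- data.frame(time_min = t, signal = gauss_signal(t, 4.5, 0.2, 1))
  ct0 <- monomer_dimer_content(solo, c(3.5, 5.5), c(5.6, 7.6))
  expect_lt(ct0$dimer_fraction, 1e-6)
  zero <- data.frame(time_min = t, signal = rep(0, length(t)))
  expect_error(monomer_dimer_content(zero, c(3.5, 5.5), c(5.6, 7.6)),
               class = "af4saxs_domain_error")
})

test_that("Konv is the injected molarity per unit area and self-consistent", {
  k <- konv_from_pure_injection(10, 2, 11.5)
  expect_equal(k, (2 / 11500) / 10, tolerance = 1e-12)
  expect_equal(konv_from_pure_injection(20, 2, 11.5), k / 2, tolerance = 1e-12)
  # round trip: applying Konv to the same injection returns its molarity
  expect_equal(10 * k, 2 / 11500, tolerance = 1e-12)
  expect_error(konv_from_pure_injection(0, 2, 11.5),
               class = "af4saxs_domain_error")
})

make_deconv <- function(areas, labels) {
  peaks <- purrr::list_rbind(purrr::map2(
    as.list(areas), as.list(labels),
    function(a, l) gaussian_peak(5, 0.3, a / (0.3 * sqrt(2 * pi)), label = l)))
  structure(list(peaks = peaks, baseline = c(intercept = 0, slope = 0),
                 residual_rms = 0, fitted = NULL, empty = FALSE,
                 converged = TRUE),
            class = "deconvolution")
}

test_that("binding ratio bookkeeping obeys its mass balance and edge cases", {
  konv <- 1e-6
  pure <- make_deconv(c(9, 1), c("monomer", "dimer"))
  # no ligand added, mixture identical to pure albumin
  same <- make_deconv(c(0, 9, 1), c("free", "monomer", "dimer"))
  br0 <- binding_ratios(same, pure, konv, 1.5e-5, 0.93, 0)
  expect_equal(br0$gaz_per_hsa_dimer, 0)
  expect_equal(br0$free_gaz_per_hsa_tot, 0)
  expect_equal(br0$gaz_per_hsa_monomer, 0)
  expect_equal(br0$overall_gaz_per_hsa, 0)
  # arbitrary point: the balance added = free + in_dimer + monomer-bound is exact
  mix <- make_deconv(c(2, 10, 1.8), c("free", "monomer", "dimer"))
  br <- binding_ratios(mix, pure, konv, 1.5e-5, 0.93, 2e-5)
  lhs <- br$c_gaz_added
  rhs <- br$c_gaz_free + br$c_gaz_in_dimer +
    br$gaz_per_hsa_monomer * br$c_hsa_monomer
  expect_equal(lhs, rhs, tolerance = 1e-15)
  # dimer pool counted as particles: C(dimer) = (1-f) C / 2
  expect_equal(br$c_hsa_dimer, 0.07 * 1.5e-5 / 2, tolerance = 1e-15)
})

test_that("binding ratios are invariant to a uniform UV gain", {
  pure <- make_deconv(c(9, 1), c("monomer", "dimer"))
  mix <- make_deconv(c(2, 10, 1.8), c("free", "monomer", "dimer"))
  g <- 37
  pure_g <- make_deconv(c(9, 1) * g, c("monomer", "dimer"))
  mix_g <- make_deconv(c(2, 10, 1.8) * g, c("free", "monomer", "dimer"))
  br1 <- binding_ratios(mix, pure, 1e-6, 1.5e-5, 0.93, 2e-5)
  br2 <- binding_ratios(mix_g, pure_g, 1e-6 / g, 1.5e-5, 0.93, 2e-5)
  expect_equal(br1$overall_gaz_per_hsa, br2$overall_gaz_per_hsa,
               tolerance = 1e-12)
  expect_equal(br1$gaz_per_hsa_dimer, br2$gaz_per_hsa_dimer,
               tolerance = 1e-12)
})

test_that("mixing molar ratios reproduce the titration design arithmetic", {
  expect_equal(mixing_molar_ratio(0.01, 2), (0.01 / 11.5) / (2 / 66.5),
               tolerance = 1e-12)
  expect_equal(mixing_molar_ratio(0.01, 2), 0.029, tolerance = 0.005)
  expect_equal(mixing_molar_ratio(1, 1, 50, 50), 1.0)
  # equal stocks: the molar-mass ratio itself (5.78 from the nominal masses)
  expect_equal(mixing_molar_ratio(2, 2), 66.5 / 11.5, tolerance = 1e-12)
  expect_error(mixing_molar_ratio(1, 0), class = "af4saxs_domain_error")
})

test_that("the recovered isotherm is non-decreasing in added ligand", {
  ser <- simulate_titration_series(
    gaz_stocks_mg_ml = c(0.05, 0.2, 0.5, 1, 2), kd = 1e-8,
    geometry = cal_geometry, flows = std_flows, solvent = std_solvent,
    noise_rel = 0)
  iso <- suppressWarnings(analyze_binding_titration(ser))
  expect_true(all(diff(iso$overall) > -1e-6))
  # noiseless recovery of the generating ratios
  expect_equal(iso$overall, iso$true_overall, tolerance = 0.02)
})
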