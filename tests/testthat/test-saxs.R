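test_that("reduced chi2 matches its definition and scale behaviour", {
  cv <- scattering_curve(seq(0.1, 2, by = 0.1), exp(-seq(0.1, 2, by = 0.1)),
                         sigma = rep(0.01, 20))
  self <- saxs_chi2(cv, cv$intensity)
  expect_equal(self$chi2, 0)
  expect_equal(self$scale_c, 1)
  # residuals exactly +/- sigma -> chi2 = N/(N-1)
  alt <- cv$intensity + 0.01 * rep(c(1, -1), 10)
  forced <- saxs_chi2(scattering_curve(cv$q, alt, cv$sigma), cv$intensity,
                      optimize_scale = FALSE)
  expect_equal(forced$chi2, 20 / 19, tolerance = 1e-9)
  # scale invariance: any multiple is a perfect fit with optimised c
  for (k in c(0.5, 2, 117)) {
    sc <- saxs_chi2(cv, k * cv$intensity)
    expect_equal(sc$scale_c, 1 / k, tolerance = 1e-12)
    expect_lt(sc$chi2, 1e-20)
  }
  expect_error(saxs_chi2(cv[1, ], cv$intensity[1]),
               class = "af4saxs_domain_error")
})

test_that("frame selection keeps replicates and rejects a larger particle", {
  q <- seq(0.05, 5, by = 0.02)
  clean <- simulate_saxs_curve("sphere", radius_nm = 3, q = q, noise_rel = 0,
                               noise_floor_frac = 0)
  same <- replicate(4, clean, simplify = FALSE)
  out <- select_and_average_frames(same)
  expect_equal(sort(out$kept), 1:4)
  expect_equal(out$curve$intensity, clean$intensity, tolerance = 1e-12)
  # 10 frames of one particle + 2 of a particle twice the size
  frames <- lapply(1:12, function(i) {
    simulate_saxs_curve("sphere", radius_nm = if (i <= 10) 3 else 6, q = q,
                        noise_rel = 0.02, seed = 700 + i)
  })
  sel <- select_and_average_frames(frames)
  expect_equal(sort(sel$kept), 1:10)
})

test_that("pairwise chi2 of pure-noise frames is centred on one", {
  q <- seq(0.05, 2, length.out = 200)
  base <- exp(-q^2)
  sig <- 0.05 * base
  stats <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      a <- scattering_curve(q, base + rnorm(200, sd = sig), sig)
      b <- scattering_curve(q, base + rnorm(200, sd = sig), sig)
      sum(((a$intensity - b$intensity) / sqrt(a$sigma^2 + b$sigma^2))^2) / 199
    })
  }, numeric(1))
  expect_lt(abs(mean(stats) - 1), 0.2)
})

test_that("Guinier fit matches the solid-sphere closed form", {
  cv <- simulate_saxs_curve("sphere", radius_nm = 3,
                            q = seq(0.02, 10, by = 0.005),
                            noise_rel = 0, noise_floor_frac = 0)
  # the strict Guinier regime of a sphere; at the 1.3 default the form
  # factor's 4th-order term biases Rg ~1.7% high
  gf <- guinier_fit(cv, q_rg_limit = 0.6)
  expect_rel(gf$rg_nm, sqrt(3 / 5) * 3, 0.005)
  expect_rel(gf$i_zero, 1, 0.005)
  expect_lte(gf$q_max_rg, 0.6 + 1e-6)
})

test_that("Guinier fit recovers a noisy 2.81 nm particle within 3%", {
  # oblate particle scaled to the albumin-like radius of gyration
  s <- 2.81 / sqrt((16 + 16 + 1.5^2) / 5)
  cv <- simulate_saxs_curve("ellipsoid", semi_axes_nm = s * c(4, 4, 1.5),
                            q = seq(0.05, 4, by = 0.01),
                            noise_rel = 0.01, seed = 21)
  gf <- guinier_fit(cv)
  expect_rel(gf$rg_nm, 2.81, 0.03)
})

test_that("a low-q upturn clears the linearity flag", {
  good <- simulate_saxs_curve("sphere", radius_nm = 3,
                              q = seq(0.05, 3, by = 0.01),
                              noise_rel = 0.005, seed = 3)
  agg <- simulate_saxs_curve("sphere", radius_nm = 3,
                             q = seq(0.05, 3, by = 0.01),
                             noise_rel = 0.005, aggregate_fraction = 0.5,
                             seed = 3)
  expect_true(guinier_fit(good)$linear)
  expect_false(guinier_fit(agg)$linear)
})

test_that("p(r) inversion matches the sphere distance distribution", {
  cv <- simulate_saxs_curve("sphere", radius_nm = 3, q = seq(0.05, 5, by = 0.01),
                            noise_rel = 0, noise_floor_frac = 0)
  pd <- pddf_ift(cv, d_max = 6)
  # endpoint and nonnegativity constraints hold exactly
  expect_equal(pd$pr$p[1], 0)
  expect_equal(pd$pr$p[nrow(pd$pr)], 0)
  expect_true(all(pd$pr$p >= 0))
  # sphere correlation function gamma(r) = 1 - 3r/(4R) + r^3/(16 R^3)
  r <- pd$pr$r; R <- 3
  pth <- r^2 * (1 - 3 * r / (4 * R) + r^3 / (16 * R^3))
  pth[r > 2 * R] <- 0
  rms <- sqrt(mean((pd$pr$p / max(pd$pr$p) - pth / max(pth))^2))
  expect_lt(rms, 0.02)
  expect_rel(pd$rg_real_nm, sqrt(3 / 5) * 3, 0.01)
  expect_rel(pd$i_zero_real, 1, 0.01)
})

test_that("Guinier and p(r) agree on noiseless compact particles", {
  cv <- simulate_saxs_curve("ellipsoid", semi_axes_nm = c(4, 4, 1.5),
                            q = seq(0.03, 5, by = 0.01),
                            noise_rel = 0, noise_floor_frac = 0)
  gf <- guinier_fit(cv, q_rg_limit = 0.8)
  pd <- pddf_ift(cv, d_max = 8.5)
  expect_rel(pd$rg_real_nm, gf$rg_nm, 0.03)
  expect_rel(pd$i_zero_real, gf$i_zero, 0.03)
})

test_that("p(r) support tracks a dumbbell's maximum dimension", {
  db <- simulate_saxs_curve("dumbbell", radii_nm = c(1.6, 1.6),
                            separation_nm = 5, q = seq(0.05, 6, by = 0.01),
                            noise_rel = 0, noise_floor_frac = 0)
  pd <- pddf_ift(db, d_max = 10)
  supp <- max(pd$pr$r[pd$pr$p > 0.01 * max(pd$pr$p)])
  # the smoothness penalty tapers the outermost, sparsely populated distances
  expect_gt(supp, 2 * 1.6 + 5 - 0.6)
  expect_lt(supp, 10 - 0.5)
})

test_that("IFT reconstructions stay statistically consistent with their noise", {
  chis <- vapply(1:20, function(s) {
    cv <- simulate_saxs_curve("sphere", radius_nm = 3,
                              q = seq(0.05, 5, by = 0.02),
                              noise_rel = 0.01, seed = 300 + s)
    pddf_ift(cv, d_max = 6)$chi2
  }, numeric(1))
  expect_lte(median(chis), 1.5)
})

test_that("Porod volume approximates the sphere volume across sizes", {
  for (R in c(2, 3, 4, 6)) {
    cv <- simulate_saxs_curve("sphere", radius_nm = R,
                              q = seq(0.02, 10, by = 0.005),
                              noise_rel = 0, noise_floor_frac = 0)
    po <- porod_volume(cv, i_zero = 1, rg_nm = sqrt(3 / 5) * R)
    expect_rel(po$porod_volume_nm3, 4 / 3 * pi * R^3, 0.1)
  }
})

test_that("molecular-weight estimators follow their defining rules", {
  # rounding is half away from zero (needed for 62.5 -> 63)
  expect_equal(mw_from_porod(100), 63)
  expect_equal(mw_from_porod(99.2), 62)
  expect_equal(mw_from_excluded_volume(0), 0)
  expect_equal(mw_from_excluded_volume(c(10, 20)), c(5, 10))
  expect_error(mw_from_excluded_volume(-1), class = "af4saxs_domain_error")
  # standard-based MW: identity, joint-scaling invariance, ratio recovery
  expect_equal(mw_from_standard(5, 2, 5, 2, 66), 66)
  expect_equal(mw_from_standard(10, 4, 5, 2, 66), 66)
  i0_ref <- 66 * 3; i0_s <- 25 * 3   # I(0)/c proportional to MW
  expect_rel(mw_from_standard(i0_s, 1, i0_ref, 1, 66), 25, 0.01)
  expect_error(mw_from_standard(1, 1, 0, 1, 66), class = "af4saxs_domain_error")
})

test_that("shape factors divide Rg by Rh and report two significant figures", {
  expect_equal(shape_factor(3, 3)$rho, 1.0)
  sph <- shape_factor(sqrt(3 / 5) * 5, 5)
  expect_equal(sph$rho, sqrt(3 / 5), tolerance = 1e-12)
  expect_equal(sph$rho_reported, 0.77)
  expect_error(shape_factor(-1, 3), class = "af4saxs_domain_error")
})
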