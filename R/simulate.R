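#' Molecular species description
#'
#' A species row bundles the physical parameters both the generator and the
#' analysis need: molar mass, hydrodynamic radius, refractive-index increment
#' and extinction coefficient. `rg_nm` (radius of gyration, used only for the
#' weak angular dependence of the light-scattering signal) defaults to a
#' compact-sphere ratio of the hydrodynamic radius.
#'
#' @param name Label.
#' @param mw_kda Molar mass (kDa), > 0.
#' @param rh_nm Hydrodynamic radius (nm), > 0.
#' @param dn_dc Refractive-index increment (mL/g).
#' @param ext_280 Extinction coefficient at 280 nm (AU mL / (mg cm)).
#' @param rg_nm Radius of gyration (nm); default `sqrt(3/5) * rh_nm`.
#'
#' @return A one-row tibble.
#' @export
species <- function(name, mw_kda, rh_nm, dn_dc = 0.185, ext_280 = 0.53,
                    rg_nm = sqrt(3 / 5) * rh_nm) {
  if (mw_kda <= 0 || rh_nm <= 0) {
    abort("Molar mass and hydrodynamic radius must be positive.",
          class = "af4saxs_domain_error")
  }
  tibble(name = name, mw_kda = mw_kda, rh_nm = rh_nm,
         dn_dc = dn_dc, ext_280 = ext_280, rg_nm = rg_nm)
}

#' Reference species used throughout the examples and tests
#'
#' Human serum albumin monomer (66.5 kDa, Rh 3.3 nm) and dimer (133 kDa,
#' 4.8 nm), and the albumin-binding fusion protein monomer (11.5 kDa) and
#' Z-Z-interface dimer (23 kDa, Rh ~2.8 nm, the value an AF4 peak of the
#' fast-exchanging population reports).
#'
#' @return A one-row tibble as from [species()].
#' @name reference_species
NULL

#' @rdname reference_species
#' @export
hsa_monomer <- function() species("HSA_monomer", 66.5, 3.3, 0.185, 0.531)

#' @rdname reference_species
#' @export
hsa_dimer <- function() species("HSA_dimer", 133.0, 4.8, 0.185, 0.531)

#' @rdname reference_species
#' @export
gaz_monomer <- function() species("GAZ_monomer", 11.5, 2.5, 0.196, 0.30)

#' @rdname reference_species
#' @export
gaz_dimer <- function() species("GAZ_dimer", 23.0, 2.8, 0.196, 0.30)

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# shared band -> detector-matrix assembly.
# bands: tibble with conc_profile (list of mg/mL traces), mw_kda, dn_dc,
# ext_280, rg_nm per band.
.assemble_detectors <- function(time_min, bands, solvent, angles,
                                noise_rel, seed) {
  nt <- length(time_min)
  uv <- dri <- rep(0, nt)
  ls <- matrix(0, nt, length(angles))
  q <- .q_from_angle(angles, solvent)
  for (k in seq_len(nrow(bands))) {
    c_mg <- bands$conc_profile[[k]]
    c_g <- c_mg * 1e-3
    uv <- uv + c_mg * bands$ext_280[k]
    dri <- dri + c_g * bands$dn_dc[k]
    kst <- k_star(solvent, bands$dn_dc[k])
    p_theta <- exp(-q^2 * bands$rg_nm[k]^2 / 3)
    ls <- ls + outer(c_g * bands$mw_kda[k] * 1000, rep(kst, length(q))) *
      matrix(p_theta, nt, length(q), byrow = TRUE)
  }
  out <- tibble(time_min = time_min, uv_au = uv, dri_riu = dri)
  ls_cols <- sprintf("ls_%03d", round(angles))
  for (j in seq_along(angles)) out[[ls_cols[j]]] <- ls[, j]
  if (noise_rel > 0) {
    out <- .with_seed(seed, {
      for (col in c("uv_au", "dri_riu", ls_cols)) {
        s <- noise_rel * max(out[[col]])
        if (s > 0) out[[col]] <- out[[col]] + rnorm(nt, sd = s)
      }
      out
    })
  }
  class(out) <- c("fractogram", class(out))
  out
}

#' Simulate a multi-detector AF4 fractogram
#'
#' Forward model of an AF4-UV-dRI-MALS run: each species elutes as a Gaussian
#' band centred at the retention time predicted by [time_from_radius()], with
#' width `tr / sqrt(plate_number)`. Detector responses follow the standard
#' linear models (UV from mass extinction, dRI from dn/dc, excess Rayleigh
#' ratio `K* c M P(theta)` with the nearly flat form factor of sub-5-nm
#' particles). Additive Gaussian noise per detector is a fixed fraction of
#' that detector's peak signal; output is deterministic for a given seed.
#'
#' @param species_mix A tibble of [species()] rows with an added
#'   `conc_mg_ml` column (injected sample concentration per species).
#' @param geometry,flows,solvent Channel model, see [channel_geometry()].
#' @param plate_number Band-broadening plate count (default 2500).
#' @param dt_min Sampling interval (min).
#' @param noise_rel Noise SD as a fraction of each detector's peak signal
#'   (default 0.005); 0 for noiseless data.
#' @param inject_ml Injected volume (mL).
#' @param angles MALS detector angles (degrees).
#' @param seed Optional integer seed (reproducible output; global RNG state is
#'   untouched).
#'
#' @return A fractogram tibble: `time_min`, `uv_au`, `dri_riu`, `ls_*`.
#' @export
simulate_fractogram <- function(species_mix, geometry, flows, solvent,
                                plate_number = 2500, dt_min = 0.01,
                                noise_rel = 0.005, inject_ml = 0.15,
                                angles = default_mals_angles(), seed = NULL) {
  stopifnot(is.data.frame(species_mix), "conc_mg_ml" %in% names(species_mix))
  if (any(species_mix$conc_mg_ml < 0) || plate_number <= 0) {
    abort("Concentrations must be >= 0 and plate number positive.",
          class = "af4saxs_domain_error")
  }
  time_min <- seq(0, flows$duration_min, by = dt_min)
  active <- species_mix[species_mix$conc_mg_ml > 0, ]
  bands <- tibble(conc_profile = list(), mw_kda = numeric(),
                  dn_dc = numeric(), ext_280 = numeric(), rg_nm = numeric())
  if (nrow(active) > 0) {
    tr <- as.numeric(time_from_radius(active$rh_nm, geometry, flows, solvent))
    if (any(tr > flows$duration_min)) {
      warn("Some species elute beyond the run duration; their bands are truncated.",
           class = "af4saxs_truncation_warning")
    }
    sig <- tr / sqrt(plate_number)
    mass_mg <- active$conc_mg_ml * inject_ml
    profiles <- map(seq_len(nrow(active)), function(k) {
      mass_mg[k] * dnorm(time_min, tr[k], sig[k]) / flows$detector_ml_min
    })
    rg <- if ("rg_nm" %in% names(active)) active$rg_nm else sqrt(3 / 5) * active$rh_nm
    bands <- tibble(conc_profile = profiles, mw_kda = active$mw_kda,
                    dn_dc = active$dn_dc, ext_280 = active$ext_280, rg_nm = rg)
  }
  out <- .assemble_detectors(time_min, bands, solvent, angles, noise_rel, seed)
  attr(out, "inject_ml") <- inject_ml
  out
}

#' Simulate a fast-exchange monomer-dimer peak
#'
#' Species interconverting faster than the separation elute as a single
#' asymmetric band at the population-weighted retention position rather than
#' as two resolved peaks. The band is skew-normal, the skew controlled by the
#' composition gradient (maximal at a 50:50 population, vanishing for a pure
#' form), and the light-scattering signal carries the weight-average molar
#' mass across the entire band -- so the apparent MW does not climb with
#' retention time, the diagnostic fingerprint of co-elution.
#'
#' @param monomer,dimer [species()] rows of the two exchanging forms.
#' @param fraction_dimer Mass fraction of the dimer form in [0, 1].
#' @param conc_mg_ml Total injected concentration (mg/mL).
#' @inheritParams simulate_fractogram
#' @param skew_scale Maximum skew-normal shape parameter (default 3).
#'
#' @return A fractogram tibble.
#' @export
simulate_fast_exchange_peak <- function(monomer, dimer, fraction_dimer,
                                        conc_mg_ml, geometry, flows, solvent,
                                        plate_number = 2500, dt_min = 0.01,
                                        noise_rel = 0.005, inject_ml = 0.15,
                                        angles = default_mals_angles(),
                                        skew_scale = 3, seed = NULL) {
  if (fraction_dimer < 0 || fraction_dimer > 1) {
    abort("fraction_dimer must lie in [0, 1].", class = "af4saxs_domain_error")
  }
  f <- fraction_dimer
  rh_w <- (1 - f) * monomer$rh_nm + f * dimer$rh_nm
  mw_w <- (1 - f) * monomer$mw_kda + f * dimer$mw_kda
  tr <- as.numeric(time_from_radius(rh_w, geometry, flows, solvent))
  sig <- tr / sqrt(plate_number)
  alpha <- skew_scale * 4 * f * (1 - f)
  time_min <- seq(0, flows$duration_min, by = dt_min)
  # skew-normal density with the mean re-centred on the weighted position
  delta <- alpha / sqrt(1 + alpha^2)
  xi <- tr - sig * delta * sqrt(2 / pi)
  z <- (time_min - xi) / sig
  dens <- 2 / sig * dnorm(z) * pnorm(alpha * z)
  mass_mg <- conc_mg_ml * inject_ml
  profile <- mass_mg * dens / flows$detector_ml_min
  bands <- tibble(conc_profile = list(profile),
                  mw_kda = mw_w,
                  dn_dc = (1 - f) * monomer$dn_dc + f * dimer$dn_dc,
                  ext_280 = (1 - f) * monomer$ext_280 + f * dimer$ext_280,
                  rg_nm = sqrt(3 / 5) * rh_w)
  out <- .assemble_detectors(time_min, bands, solvent, angles, noise_rel, seed)
  attr(out, "inject_ml") <- inject_ml
  out
}

# single-site binding equilibrium: bound entities from totals and Kd
.bound_entities <- function(e_tot, s_tot, kd) {
  if (e_tot <= 0 || s_tot <= 0) return(0)
  b <- (e_tot + s_tot + kd - sqrt((e_tot + s_tot + kd)^2 - 4 * e_tot * s_tot)) / 2
  min(max(b, 0), min(e_tot, s_tot))
}

#' Simulate a ligand-albumin titration series
#'
#' Generates the full input bundle of a binding experiment: mixture
#' fractograms at a series of ligand stock concentrations (mixed 1:1 v/v with
#' the albumin stock), plus matching pure-albumin and pure-ligand reference
#' runs recorded at the same injection volume. Per titration point a
#' single-site equilibrium is solved in which the binding entities are ligand
#' monomers and Z-Z-interface ligand dimers (a dimer occupies one albumin site
#' through one of its two free albumin-binding domains, contributing two
#' ligand masses); bound entities distribute over albumin monomer and dimer
#' pools in proportion to binding sites (one per monomer, two per dimer
#' particle). Complex hydrodynamic radii follow volume additivity over
#' constituents, `Rh^3 = sum(Rh_i^3)`.
#'
#' The default ligand dimer fraction 6/13 makes the saturation plateau of the
#' overall bound-ligand-per-albumin ratio exactly 1.3.
#'
#' @param gaz_stocks_mg_ml Ligand stock concentrations before 1:1 mixing.
#' @param hsa_stock_mg_ml Albumin stock before mixing (default 2).
#' @param kd Dissociation constant (mol/L), > 0.
#' @param gaz_dimer_fraction Mass fraction of ligand present as dimer.
#' @param monomer_fraction Albumin monomer mass fraction (default 0.93).
#' @inheritParams simulate_fractogram
#'
#' @return A list of class `titration_series`: `points` (tibble with the
#'   per-point fractogram in a list column plus ground-truth concentrations),
#'   `pure_hsa`, `pure_gaz` (reference fractograms), `hsa_total_mol_l`,
#'   `monomer_fraction`, `pure_gaz_conc_mg_ml`, `params`.
#' @export
simulate_titration_series <- function(gaz_stocks_mg_ml = c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 2),
                                      hsa_stock_mg_ml = 2,
                                      kd = 1e-9,
                                      gaz_dimer_fraction = 6 / 13,
                                      monomer_fraction = 0.93,
                                      geometry, flows, solvent,
                                      plate_number = 2500, dt_min = 0.01,
                                      noise_rel = 0.005, inject_ml = 0.15,
                                      seed = NULL) {
  if (kd <= 0) abort("Kd must be positive.", class = "af4saxs_domain_error")
  if (gaz_dimer_fraction < 0 || gaz_dimer_fraction > 1) {
    abort("Ligand dimer fraction must lie in [0, 1].",
          class = "af4saxs_domain_error")
  }
  hm <- hsa_monomer(); hd <- hsa_dimer()
  gm <- gaz_monomer(); gd <- gaz_dimer()
  f <- monomer_fraction
  delta <- gaz_dimer_fraction
  mu <- 1 / (1 - delta / 2)            # ligand molecules per bound entity
  dprime <- (delta / 2) / (1 - delta / 2)  # dimer fraction among entities
  v_g <- gm$rh_nm^3                     # ligand monomer hydrodynamic volume
  v_bound <- v_g * (1 + dprime)         # average bound volume per occupied site

  c_hsa <- hsa_stock_mg_ml / 2                     # mg/mL in the mixture
  c_hsa_m <- c_hsa / (hm$mw_kda * 1000)            # mol/L monomer equivalents
  s_tot <- c_hsa_m                                  # one site per equivalent

  time_args <- list(geometry = geometry, flows = flows, solvent = solvent,
                    plate_number = plate_number, dt_min = dt_min,
                    inject_ml = inject_ml)

  gaz_mix_rh <- (1 - delta) * gm$rh_nm + delta * gd$rh_nm
  gaz_mix_mw <- (1 - delta) * gm$mw_kda + delta * gd$mw_kda

  make_point <- function(i, gaz_stock) {
    c_gaz <- gaz_stock / 2
    g_tot <- c_gaz / (gm$mw_kda * 1000)            # mol/L ligand molecules
    e_tot <- g_tot * (1 - delta / 2)
    b <- .bound_entities(e_tot, s_tot, kd)
    theta <- b / s_tot
    g_bound <- b * mu
    g_free <- g_tot - g_bound

    bands <- list()
    # free ligand (fast-exchanging monomer/dimer population, one band)
    if (g_free > 0) {
      bands$free <- species("free_gaz", gaz_mix_mw, gaz_mix_rh,
                            gm$dn_dc, gm$ext_280)
      bands$free$conc_mg_ml <- g_free * gm$mw_kda * 1000
    }
    # monomer pool: HSA monomer + its bound ligand, one co-eluting band
    m_hsa_mono <- f * c_hsa
    m_gaz_mono <- theta * f * c_hsa_m * mu * gm$mw_kda * 1000
    rh_mono <- (hm$rh_nm^3 + theta * v_bound)^(1 / 3)
    bands$mono <- .pool_band("monomer_pool", m_hsa_mono, m_gaz_mono,
                             f * c_hsa_m, rh_mono, hm, gm)
    # dimer pool: two sites per particle
    m_hsa_dim <- (1 - f) * c_hsa
    n_dimer <- (1 - f) * c_hsa_m / 2
    m_gaz_dim <- theta * (1 - f) * c_hsa_m * mu * gm$mw_kda * 1000
    rh_dim <- (hd$rh_nm^3 + 2 * theta * v_bound)^(1 / 3)
    bands$dim <- .pool_band("dimer_pool", m_hsa_dim, m_gaz_dim,
                            n_dimer, rh_dim, hd, gm)
    mix <- bind_rows(bands)
    frac <- do.call(simulate_fractogram,
                    c(list(species_mix = mix, noise_rel = noise_rel,
                           seed = if (is.null(seed)) NULL else seed + i),
                      time_args))
    tibble(gaz_stock_mg_ml = gaz_stock,
           molar_ratio = mixing_molar_ratio(gaz_stock, hsa_stock_mg_ml,
                                            gm$mw_kda, hm$mw_kda),
           gaz_added_mol_l = g_tot,
           occupancy = theta,
           true_free_mol_l = g_free,
           true_in_dimer_mol_l = theta * (1 - f) * c_hsa_m * mu,
           true_per_monomer = theta * mu,
           true_per_dimer = 2 * theta * mu,
           true_overall = theta * mu,
           fractogram = list(frac))
  }

  points <- list_rbind(imap(as.list(gaz_stocks_mg_ml),
                            function(g, i) make_point(i, g)))

  hsa_mix <- bind_rows(hm, hd)
  hsa_mix$conc_mg_ml <- c(f, 1 - f) * c_hsa
  pure_hsa <- do.call(simulate_fractogram,
                      c(list(species_mix = hsa_mix, noise_rel = noise_rel,
                             seed = if (is.null(seed)) NULL else seed + 1000L),
                        time_args))
  c_gaz_ref <- max(gaz_stocks_mg_ml) / 2
  gaz_ref <- species("pure_gaz", gaz_mix_mw, gaz_mix_rh, gm$dn_dc, gm$ext_280)
  gaz_ref$conc_mg_ml <- c_gaz_ref
  pure_gaz <- do.call(simulate_fractogram,
                      c(list(species_mix = gaz_ref, noise_rel = noise_rel,
                             seed = if (is.null(seed)) NULL else seed + 2000L),
                        time_args))

  structure(
    list(points = points,
         pure_hsa = pure_hsa,
         pure_gaz = pure_gaz,
         hsa_total_mol_l = c_hsa_m,
         monomer_fraction = f,
         pure_gaz_conc_mg_ml = c_gaz_ref,
         gaz_mw_kda = gm$mw_kda,
         params = list(kd = kd, gaz_dimer_fraction = delta,
                       plate_number = plate_number, noise_rel = noise_rel,
                       inject_ml = inject_ml, dt_min = dt_min)),
    class = "titration_series"
  )
}

# a co-eluting albumin + bound-ligand band as one scattering particle
.pool_band <- function(name, m_hsa, m_gaz, n_particles_mol_l, rh, hsa_sp, gaz_sp) {
  m_tot <- m_hsa + m_gaz
  w_h <- m_hsa / m_tot; w_g <- m_gaz / m_tot
  band <- species(
    name,
    mw_kda = m_tot / n_particles_mol_l / 1000,  # (g/L)/(mol/L) = g/mol -> kDa
    rh_nm = rh,
    dn_dc = w_h * hsa_sp$dn_dc + w_g * gaz_sp$dn_dc,
    ext_280 = w_h * hsa_sp$ext_280 + w_g * gaz_sp$ext_280
  )
  band$conc_mg_ml <- m_tot
  band
}

# stable sphere amplitude 3 (sin x - x cos x) / x^3; preserves dim attributes
.sphere_amp <- function(x) {
  out <- x
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

.ellipsoid_intensity <- function(q, semi_axes) {
  ax <- sort(semi_axes, decreasing = TRUE)
  eq <- function(u, v) abs(u - v) < 1e-12
  if (eq(ax[1], ax[2]) || eq(ax[2], ax[3])) {
    # spheroid: orientation average reduces to one quadrature over cos(angle
    # between q and the symmetry axis)
    if (eq(ax[1], ax[2])) { axis <- ax[3]; eqt <- ax[1] }  # oblate
    else { axis <- ax[1]; eqt <- ax[3] }                   # prolate
    gl <- pracma::gaussLegendre(64, 0, 1)
    r_eff <- sqrt(axis^2 * gl$x^2 + eqt^2 * (1 - gl$x^2))
    amp2 <- .sphere_amp(outer(q, r_eff))^2
    drop(amp2 %*% gl$w)
  } else {
    glu <- pracma::gaussLegendre(48, 0, 1)
    glp <- pracma::gaussLegendre(48, 0, pi / 2)
    u <- glu$x; phi <- glp$x
    r2 <- outer(1 - u^2, cos(phi)^2) * ax[1]^2 +
      outer(1 - u^2, sin(phi)^2) * ax[2]^2 +
      matrix(u^2 * ax[3]^2, length(u), length(phi))
    r_eff <- sqrt(as.vector(r2))
    w2 <- as.vector(outer(glu$w, glp$w)) / (pi / 2)
    amp2 <- .sphere_amp(outer(q, r_eff))^2
    drop(amp2 %*% w2)
  }
}

#' Simulate a 1-D SAXS curve with known ground truth
#'
#' Analytic form factors for a solid sphere, a (possibly triaxial) ellipsoid
#' averaged over orientations by Gauss-Legendre quadrature, a two-sphere
#' dumbbell (coherent Debye cross term `sinc(q d)`), or a weighted mixture of
#' such models. Intensities are normalised so that `I(0) = i_zero`; Gaussian
#' noise with `sigma(q) = noise_rel * I(q) + noise_floor_frac * i_zero` is
#' added when requested, deterministically for a given seed. An optional
#' aggregate term adds a `q^-3` power-law upturn at low q for testing
#' linearity diagnostics.
#'
#' @param model `"sphere"`, `"ellipsoid"`, `"dumbbell"` or `"mixture"`.
#' @param q Momentum-transfer grid (1/nm).
#' @param radius_nm Sphere radius (nm).
#' @param semi_axes_nm Ellipsoid semi-axes (nm), length 3.
#' @param radii_nm Dumbbell sphere radii (nm), length 2.
#' @param separation_nm Dumbbell centre-centre separation (nm).
#' @param components For `model = "mixture"`: a list of argument lists, each
#'   accepted by this function (minus `q`, noise and seed).
#' @param weights Mixture weights, >= 0, summing to 1.
#' @param i_zero Forward scattering.
#' @param noise_rel Relative noise SD (default 0.01; 0 for noiseless).
#' @param noise_floor_frac Noise floor as a fraction of `i_zero`
#'   (default 1e-4).
#' @param aggregate_fraction Amplitude of the low-q power-law contaminant
#'   relative to `i_zero` at the first grid point (default 0).
#' @param seed Optional integer seed.
#'
#' @return A [scattering_curve()] tibble.
#' @export
simulate_saxs_curve <- function(model = c("sphere", "ellipsoid", "dumbbell", "mixture"),
                                q = seq(0.05, 7, by = 0.01),
                                radius_nm = 3,
                                semi_axes_nm = c(4, 4, 1.5),
                                radii_nm = c(1.6, 1.6),
                                separation_nm = 5,
                                components = NULL, weights = NULL,
                                i_zero = 1,
                                noise_rel = 0.01, noise_floor_frac = 1e-4,
                                aggregate_fraction = 0,
                                seed = NULL) {
  model <- match.arg(model)
  ideal <- switch(
    model,
    sphere = .sphere_amp(q * radius_nm)^2,
    ellipsoid = .ellipsoid_intensity(q, semi_axes_nm),
    dumbbell = {
      v1 <- radii_nm[1]^3; v2 <- radii_nm[2]^3
      f1 <- v1 * .sphere_amp(q * radii_nm[1])
      f2 <- v2 * .sphere_amp(q * radii_nm[2])
      qd <- q * separation_nm
      sinc <- ifelse(qd < 1e-8, 1, sin(qd) / qd)
      (f1^2 + f2^2 + 2 * f1 * f2 * sinc) / (v1 + v2)^2
    },
    mixture = {
      stopifnot(!is.null(components), !is.null(weights),
                length(components) == length(weights))
      if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
        abort("Mixture weights must be non-negative and sum to 1.",
              class = "af4saxs_domain_error")
      }
      parts <- map(components, function(cmp) {
        args <- c(cmp, list(q = q, i_zero = 1, noise_rel = 0,
                            noise_floor_frac = 0))
        do.call(simulate_saxs_curve, args)$intensity
      })
      Reduce(`+`, map2(parts, as.list(weights), ~ .x * .y))
    }
  )
  intensity <- i_zero * ideal
  if (aggregate_fraction > 0) {
    intensity <- intensity + aggregate_fraction * i_zero * (q / q[1])^(-3)
  }
  sig <- noise_rel * abs(intensity) + noise_floor_frac * i_zero
  noisy <- if (any(sig > 0)) {
    .with_seed(seed, intensity + rnorm(length(q), sd = sig))
  } else intensity
  scattering_curve(q, noisy, pmax(sig, 1e-12))
}
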