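#' MALS optical constant
#'
#' `K* = 4 pi^2 n0^2 (dn/dc)^2 / (NA lambda0^4)` in mol cm^2 / g^2, using the
#' vacuum laser wavelength, so that `R_theta / (K* c)` has units g/mol for
#' `R_theta` in 1/cm and `c` in g/mL.
#'
#' @param solvent A [solvent_conditions()] (supplies `refractive_index` and
#'   `laser_nm`).
#' @param dn_dc Specific refractive-index increment (mL/g), > 0.
#'
#' @return K* in mol cm^2 / g^2.
#' @export
k_star <- function(solvent, dn_dc) {
  stopifnot(inherits(solvent, "solvent_conditions"))
  if (!is.finite(dn_dc) || dn_dc <= 0) {
    abort("dn/dc must be positive.", class = "af4saxs_domain_error")
  }
  lambda_cm <- solvent$laser_nm * 1e-7
  4 * pi^2 * solvent$refractive_index^2 * dn_dc^2 / (.NAvo * lambda_cm^4)
}

# scattering vector magnitude (1/nm) at angle theta (degrees)
.q_from_angle <- function(theta_deg, solvent) {
  4 * pi * solvent$refractive_index / solvent$laser_nm *
    sin(theta_deg * pi / 360)
}

#' Default MALS detector angle set
#'
#' A 14-angle HELEOS-like set spanning 32-147 degrees, split six low angles
#' (<= 81) and eight high angles (>= 90) for co-elution diagnostics. The exact
#' angles of any given instrument differ; pass your own set where known.
#'
#' @return Numeric vector of 14 detector angles (degrees).
#' @export
default_mals_angles <- function() {
  c(32, 44, 51, 60, 69, 80, 90, 100, 110, 120, 130, 139, 144, 147)
}

#' Berry (square-root) fit of one fractogram slice
#'
#' Fits `sqrt(K* c / R_theta)` against `sin^2(theta/2)` by weighted polynomial
#' least squares of degree `order` (1 or 2). The intercept gives the molar mass
#' (`MW = 1/intercept^2`), the slope the z-average radius of gyration through
#' `sqrt(K*c/R) ~ (1/sqrt(M)) (1 + q^2 Rg^2 / 6)`. Angle subsets (`low`:
#' <= 81 degrees, `high`: >= 90 degrees) fit only part of the detector bank; a
#' divergence between the two is a co-elution diagnostic for species in fast
#' exchange.
#'
#' @param slice A data frame with columns `angle_deg` and `rayleigh` (excess
#'   Rayleigh ratio, 1/cm), optionally `noise_sd` (per-detector signal standard
#'   deviation used for inverse-variance weighting).
#' @param concentration_g_ml Slice concentration from the dRI detector (g/mL).
#' @param kstar Optical constant from [k_star()].
#' @param solvent A [solvent_conditions()].
#' @param order Polynomial degree of the fit, 1 or 2.
#' @param angle_subset `"all"`, `"low"` or `"high"`.
#' @param low_max,high_min Subset boundaries in degrees.
#'
#' @return An object of class `berry_fit` with elements `molar_mass_kda`,
#'   `rg_nm`, `mass_uncertainty_kda`, `intercept`, `slope`, `fit_order`,
#'   `angle_subset`, `angles_used`, `n_angles`.
#' @export
berry_fit <- function(slice, concentration_g_ml, kstar, solvent,
                      order = 1, angle_subset = c("all", "low", "high"),
                      low_max = 81, high_min = 90) {
  angle_subset <- match.arg(angle_subset)
  stopifnot(is.data.frame(slice), all(c("angle_deg", "rayleigh") %in% names(slice)))
  if (!is.finite(concentration_g_ml) || concentration_g_ml <= 0) {
    abort("Slice concentration must be positive for a Berry fit.",
          class = "af4saxs_low_signal_error")
  }
  if (is.unsorted(slice$angle_deg, strictly = TRUE)) {
    abort("Detector angles must be strictly increasing.",
          class = "af4saxs_domain_error")
  }
  keep <- switch(angle_subset,
                 all  = rep(TRUE, nrow(slice)),
                 low  = slice$angle_deg <= low_max,
                 high = slice$angle_deg >= high_min)
  sl <- slice[keep & is.finite(slice$rayleigh) & slice$rayleigh > 0, ]
  if (nrow(sl) < order + 2) {
    abort("Not enough usable angles in the subset for the requested fit order.",
          class = "af4saxs_fit_failure")
  }
  y <- sqrt(kstar * concentration_g_ml / sl$rayleigh)
  x <- sin(sl$angle_deg * pi / 360)^2
  # propagate detector noise into Berry coordinates: dy = y/(2 R) dR
  wts <- if ("noise_sd" %in% names(sl) && all(is.finite(sl$noise_sd)) &&
             all(sl$noise_sd > 0)) {
    sd_y <- y * sl$noise_sd / (2 * sl$rayleigh)
    1 / sd_y^2
  } else {
    rep(1, nrow(sl))
  }
  X <- outer(x, 0:order, `^`)
  fit <- lm.wfit(X, y, wts)
  b <- fit$coefficients
  intercept <- b[[1]]
  if (!is.finite(intercept) || intercept <= 0) {
    abort("Berry fit produced a non-positive intercept; cannot form a molar mass.",
          class = "af4saxs_fit_failure")
  }
  mw_g_mol <- 1 / intercept^2
  # standard error of the intercept from the weighted residuals
  dof <- max(nrow(sl) - (order + 1), 1)
  s2 <- sum(wts * fit$residuals^2) / dof
  xtx_inv <- tryCatch(solve(crossprod(X * sqrt(wts))), error = function(e) NULL)
  se_int <- if (is.null(xtx_inv)) NA_real_ else sqrt(s2 * xtx_inv[1, 1])
  mass_unc <- if (is.na(se_int)) NA_real_ else 2 * mw_g_mol * se_int / intercept
  # Rg^2 = 6 * slope / (intercept * (4 pi n0 / lambda0_nm)^2), in nm^2
  slope <- b[[2]]
  qfac <- (4 * pi * solvent$refractive_index / solvent$laser_nm)^2
  rg2 <- 6 * slope / (intercept * qfac)
  rg_nm <- if (is.finite(rg2) && rg2 > 0) sqrt(rg2) else NA_real_
  structure(
    list(molar_mass_kda = mw_g_mol / 1000,
         rg_nm = rg_nm,
         mass_uncertainty_kda = mass_unc / 1000,
         intercept = intercept,
         slope = slope,
         fit_order = order,
         angle_subset = angle_subset,
         angles_used = sl$angle_deg,
         n_angles = nrow(sl)),
    class = "berry_fit"
  )
}

#' @export
print.berry_fit <- function(x, ...) {
  cat(sprintf("Berry fit (order %d, %s angles, n = %d)\n",
              x$fit_order, x$angle_subset, x$n_angles))
  cat(sprintf("  MW = %.2f kDa (+/- %.2g)\n",
              x$molar_mass_kda, x$mass_uncertainty_kda))
  cat(sprintf("  Rg = %s nm\n",
              if (is.na(x$rg_nm)) "n.d. (below angular resolution)"
              else sprintf("%.2f", x$rg_nm)))
  invisible(x)
}

#' @method tidy berry_fit
#' @export
tidy.berry_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope")[seq_len(2)],
         estimate = c(x$intercept, x$slope))
}

#' @method glance berry_fit
#' @export
glance.berry_fit <- function(x, ...) {
  tibble(molar_mass_kda = x$molar_mass_kda,
         rg_nm = x$rg_nm,
         mass_uncertainty_kda = x$mass_uncertainty_kda,
         fit_order = x$fit_order,
         angle_subset = x$angle_subset,
         n_angles = x$n_angles)
}

# ls_### columns of a fractogram -> angles in degrees
.ls_columns <- function(fractogram) {
  cols <- grep("^ls_\\d+$", names(fractogram), value = TRUE)
  angles <- as.numeric(sub("^ls_", "", cols))
  ord <- order(angles)
  list(cols = cols[ord], angles = angles[ord])
}

# baseline statistics per detector column from the first/last 10% of points;
# the quieter end supplies both the baseline level and the noise SD
.baseline_stats <- function(fractogram, columns, frac = 0.1) {
  n <- nrow(fractogram)
  k <- max(ceiling(frac * n), 5)
  head_idx <- seq_len(min(k, n))
  tail_idx <- seq.int(max(n - k + 1, 1), n)
  map(setNames(columns, columns), function(col) {
    v <- fractogram[[col]]
    ends <- list(head = v[head_idx], tail = v[tail_idx])
    sds <- map_dbl(ends, sd)
    pick <- ends[[which.min(sds)]]
    list(level = median(pick), sd = min(sds))
  })
}

#' Per-slice molar mass across an elution window
#'
#' Runs a Berry fit on every fractogram slice inside `window` whose
#' dRI-derived concentration exceeds `conc_threshold_sd` times the baseline
#' noise, and reports the weight-average molar mass `sum(c M) / sum(c)` over
#' the window. Baseline level and noise per detector are estimated from the
#' quieter of the first and last 10% of the run.
#'
#' @param fractogram A fractogram tibble (`time_min`, `dri_riu`, `ls_*`
#'   columns; see [read_fractogram()]).
#' @param window Numeric length-2: elution window in minutes.
#' @param dn_dc Refractive-index increment of the eluting species (mL/g).
#' @param solvent A [solvent_conditions()].
#' @param order,angle_subset Passed to [berry_fit()].
#' @param conc_threshold_sd Low-signal cut: slices below this multiple of the
#'   baseline concentration noise are skipped (default 5).
#'
#' @return An object of class `mass_profile`: a list with `slices` (tibble of
#'   per-slice results), `mw_wavg_kda`, `mw_sd_kda`, `n_slices`, and
#'   `determined` (`FALSE` when every slice fell below the signal threshold,
#'   the "n.d." case).
#' @export
peak_mass_profile <- function(fractogram, window, dn_dc, solvent,
                              order = 1, angle_subset = "all",
                              conc_threshold_sd = 5) {
  stopifnot(length(window) == 2, window[1] < window[2])
  ls <- .ls_columns(fractogram)
  if (length(ls$cols) == 0) {
    abort("Fractogram has no light-scattering (ls_*) columns.",
          class = "af4saxs_format_error")
  }
  in_win <- fractogram$time_min >= window[1] & fractogram$time_min <= window[2]
  if (!any(in_win)) {
    abort("Elution window contains no fractogram slices.",
          class = "af4saxs_domain_error")
  }
  base <- .baseline_stats(fractogram, c("dri_riu", ls$cols))
  conc <- (fractogram$dri_riu - base$dri_riu$level) / dn_dc  # g/mL
  conc_sd <- base$dri_riu$sd / dn_dc
  ls_noise <- map_dbl(ls$cols, ~ base[[.x]]$sd)
  kst <- k_star(solvent, dn_dc)

  idx <- which(in_win & conc > conc_threshold_sd * conc_sd)
  if (length(idx) == 0) {
    return(structure(list(slices = tibble(), mw_wavg_kda = NA_real_,
                          mw_sd_kda = NA_real_, n_slices = 0L,
                          determined = FALSE, window = window),
                     class = "mass_profile"))
  }
  ls_mat <- as.matrix(fractogram[, ls$cols])
  ls_base <- map_dbl(ls$cols, ~ base[[.x]]$level)
  rows <- map(idx, function(i) {
    slice <- tibble(angle_deg = ls$angles,
                    rayleigh = ls_mat[i, ] - ls_base,
                    noise_sd = ls_noise)
    fit <- tryCatch(
      berry_fit(slice, conc[i], kst, solvent,
                order = order, angle_subset = angle_subset),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    tibble(time_min = fractogram$time_min[i],
           conc_g_ml = conc[i],
           mw_kda = fit$molar_mass_kda,
           rg_nm = fit$rg_nm,
           mw_sd_kda = fit$mass_uncertainty_kda)
  })
  slices <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(slices) == 0) {
    return(structure(list(slices = slices, mw_wavg_kda = NA_real_,
                          mw_sd_kda = NA_real_, n_slices = 0L,
                          determined = FALSE, window = window),
                     class = "mass_profile"))
  }
  wavg <- sum(slices$conc_g_ml * slices$mw_kda) / sum(slices$conc_g_ml)
  structure(
    list(slices = slices,
         mw_wavg_kda = wavg,
         mw_sd_kda = stats::sd(slices$mw_kda),
         n_slices = nrow(slices),
         determined = TRUE,
         window = window),
    class = "mass_profile"
  )
}

#' @export
print.mass_profile <- function(x, ...) {
  if (!x$determined) {
    cat(sprintf("Mass profile over %.2f-%.2f min: n.d. (low signal)\n",
                x$window[1], x$window[2]))
  } else {
    cat(sprintf("Mass profile over %.2f-%.2f min: MW(w) = %.2f kDa (SD %.2f, %d slices)\n",
                x$window[1], x$window[2], x$mw_wavg_kda, x$mw_sd_kda, x$n_slices))
  }
  invisible(x)
}

#' @method glance mass_profile
#' @export
glance.mass_profile <- function(x, ...) {
  tibble(mw_wavg_kda = x$mw_wavg_kda, mw_sd_kda = x$mw_sd_kda,
         n_slices = x$n_slices, determined = x$determined)
}

#' @method tidy mass_profile
#' @export
tidy.mass_profile <- function(x, ...) x$slices

#' Batch-mode dn/dc determination
#'
#' Ordinary least-squares slope of the differential refractive-index signal
#' against mass concentration across a dilution series (replicates allowed).
#' The intercept is reported and should be close to zero for a clean baseline.
#'
#' @param data A data frame with columns `concentration_mg_ml` and `dri_riu`.
#'
#' @return A tibble with `dn_dc_ml_g`, `dn_dc_se`, `intercept_riu`,
#'   `r_squared`, `n`.
#' @export
dn_dc_from_batch <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("concentration_mg_ml", "dri_riu") %in% names(data)))
  if (length(unique(data$concentration_mg_ml)) < 3) {
    abort("At least three concentration levels are required.",
          class = "af4saxs_domain_error")
  }
  c_g_ml <- data$concentration_mg_ml * 1e-3
  fit <- lm(dri_riu ~ c_g_ml, data = tibble(dri_riu = data$dri_riu, c_g_ml))
  sm <- summary(fit)
  slope <- coef(fit)[["c_g_ml"]]
  if (all(data$dri_riu == 0)) {
    warn("All dRI signals are zero: dn/dc of 0 mL/g is non-physical.",
         class = "af4saxs_nonphysical_warning")
  }
  tibble(dn_dc_ml_g = slope,
         dn_dc_se = sm$coefficients["c_g_ml", "Std. Error"],
         intercept_riu = coef(fit)[["(Intercept)"]],
         r_squared = sm$r.squared,
         n = nrow(data))
}
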