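#' Gaussian elution peak
#'
#' @param center Peak centre (min).
#' @param sigma Peak width (min), > 0.
#' @param amplitude Peak height in signal units.
#' @param label Optional component label.
#'
#' @return A one-row tibble with `label`, `center`, `sigma`, `amplitude`,
#'   `area` (`amplitude * sigma * sqrt(2*pi)`).
#' @export
gaussian_peak <- function(center, sigma, amplitude, label = NA_character_) {
  if (sigma <= 0) abort("Peak sigma must be positive.", class = "af4saxs_domain_error")
  tibble(label = label, center = center, sigma = sigma,
         amplitude = amplitude, area = amplitude * sigma * sqrt(2 * pi))
}

.gauss_sum <- function(t, pars, n) {
  # pars: b0, b1, then (amp, center, sigma) per component
  y <- pars[1] + pars[2] * t
  for (k in seq_len(n)) {
    a <- pars[3 * k]; ce <- pars[3 * k + 1]; s <- pars[3 * k + 2]
    y <- y + a * exp(-(t - ce)^2 / (2 * s^2))
  }
  y
}

#' Deconvolute a fractogram signal into Gaussian peaks
#'
#' Least-squares fit of a linear baseline plus a sum of 1-3 Gaussians, the
#' model class used to separate free ligand, monomer-complex and dimer-complex
#' contributions that are not baseline-resolved. Each component is initialised
#' at the signal maximum inside its window; centres are constrained to their
#' windows and widths to (0, window width], so neighbouring components cannot
#' swap roles during optimisation.
#'
#' @param data A data frame with columns `time_min` and `signal`.
#' @param init_windows A named list of length-2 numeric windows (min), one per
#'   component; must be pairwise disjoint. Names become component labels.
#' @param baseline Fit a linear baseline? Default `TRUE`; with `FALSE` the
#'   baseline is fixed at zero.
#'
#' @return An object of class `deconvolution`: list with `peaks` (tibble of
#'   [gaussian_peak()] rows ordered by centre), `baseline` (intercept, slope),
#'   `residual_rms`, `fitted`, `empty` (all-flat input), `converged`.
#' @export
fit_baseline_and_deconvolve <- function(data, init_windows, baseline = TRUE) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "signal") %in% names(data)))
  n <- length(init_windows)
  if (n < 1 || n > 3) {
    abort("Between one and three components are supported.",
          class = "af4saxs_domain_error")
  }
  wins <- map(init_windows, ~ sort(as.numeric(.x)))
  if (is.null(names(wins)) || any(!nzchar(names(wins)))) {
    names(wins) <- paste0("component_", seq_len(n))
  }
  ord <- order(map_dbl(wins, 1))
  wins <- wins[ord]
  for (k in seq_len(n - 1)) {
    if (wins[[k]][2] > wins[[k + 1]][1]) {
      abort("Initialisation windows must be disjoint.",
            class = "af4saxs_domain_error")
    }
  }
  npar <- 2 + 3 * n
  if (nrow(data) < 10 * (npar - 2 + 2 * baseline)) {
    abort("Signal too short for the number of free parameters.",
          class = "af4saxs_domain_error")
  }
  t <- data$time_min; y <- data$signal

  # flat/empty signal: report zero-area peaks rather than failing
  if (max(abs(y - median(y))) <= 1e-12 * max(1, abs(median(y)))) {
    peaks <- list_rbind(imap(wins, function(w, nm) {
      gaussian_peak(mean(w), diff(w) / 6, 0, label = nm)
    }))
    return(structure(list(peaks = peaks, baseline = c(median(y), 0),
                          residual_rms = 0, fitted = rep(median(y), length(t)),
                          empty = TRUE, converged = TRUE),
                     class = "deconvolution"))
  }

  base0 <- if (baseline) median(c(head(y, 10), tail(y, 10))) else 0
  dt <- median(diff(t))
  sigma_floor <- 2 * dt   # narrower than two samples is not resolvable
  start <- c(b0 = base0, b1 = 0)
  lower <- c(-Inf, -Inf); upper <- c(Inf, Inf)
  for (k in seq_len(n)) {
    w <- wins[[k]]
    sel <- t >= w[1] & t <= w[2]
    if (!any(sel)) abort("An initialisation window contains no data.",
                         class = "af4saxs_domain_error")
    i_max <- which(sel)[which.max(y[sel])]
    amp0 <- max(y[i_max] - base0, 1e-3 * max(abs(y)))
    # width from the half-maximum extent around the window maximum
    half <- sum(y[sel] - base0 > amp0 / 2) * dt
    sig0 <- min(max(half / 2.355, sigma_floor * 2), diff(w) / 4)
    start <- c(start, amp0, t[i_max], sig0)
    lower <- c(lower, 0, w[1], sigma_floor)
    upper <- c(upper, Inf, w[2], diff(w))
  }
  if (!baseline) {
    lower[1:2] <- upper[1:2] <- 0
    start[1:2] <- 0
  }
  names(start) <- c("b0", "b1",
                    paste0(rep(c("a", "c", "s"), n), rep(seq_len(n), each = 3)))
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p) y - .gauss_sum(t, p, n),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!fit$info %in% 1:4) {
    abort(paste0("Deconvolution did not converge (", fit$message, ")."),
          class = "af4saxs_convergence_error",
          best_iterate = fit$par)
  }
  p <- fit$par
  peaks <- list_rbind(map(seq_len(n), function(k) {
    gaussian_peak(p[[paste0("c", k)]], p[[paste0("s", k)]],
                  p[[paste0("a", k)]], label = names(wins)[k])
  }))
  peaks <- arrange(peaks, .data$center)
  fitted <- .gauss_sum(t, p, n)
  structure(
    list(peaks = peaks,
         baseline = c(intercept = p[["b0"]], slope = p[["b1"]]),
         residual_rms = sqrt(mean((y - fitted)^2)),
         fitted = fitted,
         empty = FALSE,
         converged = TRUE),
    class = "deconvolution"
  )
}

#' @export
print.deconvolution <- function(x, ...) {
  cat(sprintf("Fractogram deconvolution (%d component%s, residual RMS %.3g)\n",
              nrow(x$peaks), if (nrow(x$peaks) > 1) "s" else "", x$residual_rms))
  print(x$peaks)
  invisible(x)
}

#' @method tidy deconvolution
#' @export
tidy.deconvolution <- function(x, ...) x$peaks

#' @method glance deconvolution
#' @export
glance.deconvolution <- function(x, ...) {
  tibble(n_peaks = nrow(x$peaks), residual_rms = x$residual_rms,
         baseline_intercept = x$baseline[["intercept"]],
         baseline_slope = x$baseline[["slope"]], empty = x$empty)
}

#' Area under a signal within an elution window
#'
#' Trapezoidal integration of the (optionally baseline-subtracted) signal.
#'
#' @param data A data frame with columns `time_min` and `signal`.
#' @param window Length-2 numeric window (min).
#' @param baseline Either `NULL` (no subtraction) or a numeric length-2
#'   `c(intercept, slope)` as returned in a `deconvolution`.
#'
#' @return Area in signal * min. An empty window returns 0 with a warning.
#' @export
area_under_peak <- function(data, window, baseline = NULL) {
  stopifnot(all(c("time_min", "signal") %in% names(data)))
  sel <- data$time_min >= min(window) & data$time_min <= max(window)
  if (sum(sel) < 2) {
    warn("Window contains fewer than two samples; area is 0.",
         class = "af4saxs_empty_window_warning")
    return(0)
  }
  t <- data$time_min[sel]
  y <- data$signal[sel]
  if (!is.null(baseline)) y <- y - (baseline[1] + baseline[2] * t)
  pracma::trapz(t, y)
}

#' Monomer and dimer content from a pure-component fractogram
#'
#' Window areas of the UV trace divided by their sum; with identical
#' extinction coefficients for monomer and dimer this is the mass fraction of
#' each form.
#'
#' @param data A data frame with columns `time_min` and `signal` (UV).
#' @param monomer_window,dimer_window Length-2 windows (min).
#' @param baseline Optional `c(intercept, slope)` baseline.
#'
#' @return A tibble with `monomer_fraction` and `dimer_fraction` (sum to 1).
#' @export
monomer_dimer_content <- function(data, monomer_window, dimer_window,
                                  baseline = NULL) {
  a_m <- area_under_peak(data, monomer_window, baseline)
  a_d <- area_under_peak(data, dimer_window, baseline)
  tot <- a_m + a_d
  if (tot <= 0) {
    abort("Total window area is zero; cannot form content fractions.",
          class = "af4saxs_domain_error")
  }
  tibble(monomer_fraction = a_m / tot, dimer_fraction = a_d / tot)
}

#' Area-to-concentration conversion factor from a pure injection
#'
#' `Konv = (molar concentration of the injected pure sample) / (its UV peak
#' area)`. Assumes a linear UV response; the extinction coefficient, detector
#' gain and injection volume all cancel when the factor is applied to runs
#' recorded under identical settings.
#'
#' @param area UV area of the pure injection (AU * min), > 0.
#' @param concentration_mg_ml Injected mass concentration (mg/mL).
#' @param molar_mass_kda Molar mass of the species (kDa).
#'
#' @return Konv in (mol/L) per (AU * min).
#' @export
konv_from_pure_injection <- function(area, concentration_mg_ml, molar_mass_kda) {
  if (area <= 0) abort("Pure-injection area must be positive.",
                       class = "af4saxs_domain_error")
  molar <- concentration_mg_ml / (molar_mass_kda * 1000)  # (g/L)/(g/mol) = mol/L
  molar / area
}

#' Binding ratios from deconvoluted mixture and reference fractograms
#'
#' Implements the area-based bookkeeping for a titration point: the ligand
#' bound per albumin-dimer particle is the excess dimer-window area of the
#' mixture over the pure-albumin run, converted to molarity with `konv`; the
#' free ligand per total albumin comes from the free-ligand window; the amount
#' bound to monomers closes the mass balance
#' `added = free + in_dimer + per_monomer * C(monomer)` exactly.
#'
#' Albumin pools assume binding does not shift the monomer-dimer ratio:
#' `C(monomer) = f * C(tot)` and, counting dimer particles,
#' `C(dimer) = (1 - f) * C(tot) / 2`.
#'
#' @param mixture_deconv A `deconvolution` of the mixture UV trace whose peak
#'   labels include `"free"` and `"dimer"` components (labels containing those
#'   strings are matched).
#' @param pure_hsa_deconv A `deconvolution` of the pure-albumin UV trace with a
#'   `"dimer"`-labelled component, recorded at the same albumin load.
#' @param konv Conversion factor from [konv_from_pure_injection()].
#' @param hsa_total_mol_l Total albumin concentration in the mixture (mol/L of
#'   monomer-equivalent protein).
#' @param monomer_fraction Albumin monomer fraction in [0, 1].
#' @param gaz_added_mol_l Total ligand added (mol/L).
#' @param noise_area Propagated area noise (same units as the peak areas) used
#'   to decide whether a negative subtraction is clipped quietly or flagged.
#'
#' @return A one-row tibble of class `binding_result`: `gaz_per_hsa_dimer`,
#'   `free_gaz_per_hsa_tot`, `gaz_per_hsa_monomer`, `overall_gaz_per_hsa`, and
#'   the underlying molar concentrations.
#' @export
binding_ratios <- function(mixture_deconv, pure_hsa_deconv, konv,
                           hsa_total_mol_l, monomer_fraction, gaz_added_mol_l,
                           noise_area = 0) {
  stopifnot(inherits(mixture_deconv, "deconvolution"),
            inherits(pure_hsa_deconv, "deconvolution"))
  if (monomer_fraction < 0 || monomer_fraction > 1) {
    abort("monomer_fraction must lie in [0, 1].", class = "af4saxs_domain_error")
  }
  pick_area <- function(deconv, what) {
    hit <- grepl(what, deconv$peaks$label, ignore.case = TRUE)
    if (!any(hit)) 0 else sum(deconv$peaks$area[hit])
  }
  auc_mix_dimer <- pick_area(mixture_deconv, "dimer")
  auc_hsa_dimer <- pick_area(pure_hsa_deconv, "dimer")
  auc_free <- pick_area(mixture_deconv, "free")

  c_tot <- hsa_total_mol_l
  c_mono <- monomer_fraction * c_tot
  c_dimer <- (1 - monomer_fraction) * c_tot / 2   # dimer particles

  clip <- function(x, label) {
    if (x >= 0) return(x)
    if (abs(x) <= 2 * noise_area * konv) {
      0
    } else {
      warn(sprintf("Negative %s concentration (%.3g M) beyond noise; clipped to 0.",
                   label, x),
           class = "af4saxs_inconsistency_warning")
      0
    }
  }

  c_in_dimer <- clip((auc_mix_dimer - auc_hsa_dimer) * konv, "dimer-bound ligand")
  c_free <- clip(auc_free * konv, "free ligand")

  gaz_per_dimer <- if (c_dimer > 0) c_in_dimer / c_dimer else NA_real_
  free_per_tot <- c_free / c_tot
  c_on_monomer <- gaz_added_mol_l - c_free - c_in_dimer
  gaz_per_monomer <- if (c_mono > 0) c_on_monomer / c_mono else NA_real_
  overall <- (gaz_added_mol_l - c_free) / c_tot

  out <- tibble(
    gaz_per_hsa_dimer = gaz_per_dimer,
    free_gaz_per_hsa_tot = free_per_tot,
    gaz_per_hsa_monomer = gaz_per_monomer,
    overall_gaz_per_hsa = overall,
    c_hsa_monomer = c_mono,
    c_hsa_dimer = c_dimer,
    c_hsa_tot = c_tot,
    c_gaz_added = gaz_added_mol_l,
    c_gaz_free = c_free,
    c_gaz_in_dimer = c_in_dimer
  )
  class(out) <- c("binding_result", class(out))
  out
}

#' Molar mixing ratio of two stocks
#'
#' Moles of ligand per mole of albumin after volumetric mixing;
#' `mix_ratio` is the ligand:albumin volume ratio (1 for the usual 1:1 mix,
#' in which case the volumes cancel).
#'
#' @param gaz_stock_mg_ml,hsa_stock_mg_ml Stock concentrations (mg/mL).
#' @param mw_gaz_kda,mw_hsa_kda Molar masses (kDa).
#' @param mix_ratio Volume ratio v(ligand)/v(albumin).
#'
#' @return Dimensionless molar ratio.
#' @export
mixing_molar_ratio <- function(gaz_stock_mg_ml, hsa_stock_mg_ml,
                               mw_gaz_kda = 11.5, mw_hsa_kda = 66.5,
                               mix_ratio = 1) {
  if (hsa_stock_mg_ml <= 0) {
    abort("Albumin stock concentration must be positive.",
          class = "af4saxs_domain_error")
  }
  if (gaz_stock_mg_ml < 0 || mix_ratio <= 0) {
    abort("Inputs must be positive.", class = "af4saxs_domain_error")
  }
  (gaz_stock_mg_ml * mix_ratio / mw_gaz_kda) / (hsa_stock_mg_ml / mw_hsa_kda)
}
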