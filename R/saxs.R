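#' Construct/validate a 1-D scattering curve
#'
#' @param q Momentum transfer grid (1/nm), strictly increasing and positive.
#' @param intensity Scattered intensity I(q).
#' @param sigma Experimental errors, > 0.
#' @param label,concentration_mg_ml Optional metadata attached as attributes.
#'
#' @return A tibble with columns `q`, `intensity`, `sigma` and class
#'   `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = NULL,
                             concentration_mg_ml = NULL) {
  if (length(q) != length(intensity)) {
    abort("q and intensity must have equal length.", class = "af4saxs_format_error")
  }
  if (any(q <= 0) || is.unsorted(q, strictly = TRUE)) {
    abort("q must be positive and strictly increasing.",
          class = "af4saxs_format_error")
  }
  if (is.null(sigma)) sigma <- pmax(abs(intensity) * 0.01, 1e-12)
  if (any(sigma <= 0)) {
    abort("sigma must be positive.", class = "af4saxs_format_error")
  }
  out <- tibble(q = q, intensity = intensity, sigma = sigma)
  attr(out, "label") <- label
  attr(out, "concentration_mg_ml") <- concentration_mg_ml
  class(out) <- c("scattering_curve", class(out))
  out
}

#' Reduced chi-squared between an experimental and a calculated curve
#'
#' `chi2 = (1/(N-1)) * sum(((Iexp - c * Icalc) / sigma)^2)`, with the scale
#' factor `c` either fixed at 1 or set to its analytic weighted least-squares
#' optimum `c = sum(Iexp Icalc / sigma^2) / sum(Icalc^2 / sigma^2)`.
#'
#' @param experimental A data frame with `q`, `intensity`, `sigma`.
#' @param calculated_intensity Numeric vector of model intensities on the same
#'   q grid.
#' @param optimize_scale Optimise the scale factor? Default `TRUE`.
#'
#' @return A one-row tibble: `chi2`, `n_points`, `scale_c`.
#' @export
saxs_chi2 <- function(experimental, calculated_intensity, optimize_scale = TRUE) {
  stopifnot(all(c("intensity", "sigma") %in% names(experimental)))
  i_exp <- experimental$intensity
  s <- experimental$sigma
  n <- length(i_exp)
  if (n < 2) abort("At least two points are required.", class = "af4saxs_domain_error")
  if (length(calculated_intensity) != n) {
    abort("Grids of experimental and calculated intensities differ.",
          class = "af4saxs_domain_error")
  }
  cc <- if (optimize_scale) {
    sum(i_exp * calculated_intensity / s^2) / sum(calculated_intensity^2 / s^2)
  } else 1
  chi2 <- sum(((i_exp - cc * calculated_intensity) / s)^2) / (n - 1)
  tibble(chi2 = chi2, n_points = n, scale_c = cc)
}

#' Select similar frames and average them
#'
#' Screens repeated exposures of the same sample for outliers (aggregation,
#' damage, a different particle) by pairwise reduced chi-squared against the
#' most central ("median") frame, then forms the inverse-variance weighted
#' average of the frames that pass. Pairwise comparison uses the combined
#' error `sqrt(sigma_a^2 + sigma_b^2)`, so identically-distributed pure-noise
#' frames score chi2 ~ 1.
#'
#' @param frames A list of data frames sharing a common `q` grid.
#' @param threshold Keep frames whose chi2 against the median frame is at most
#'   this value (default 1.5).
#'
#' @return A list: `curve` (the averaged [scattering_curve()]),
#'   `kept` (integer indices), `chi2` (per-frame statistic vs the median
#'   frame), `median_frame` (its index).
#' @export
select_and_average_frames <- function(frames, threshold = 1.5) {
  if (length(frames) < 2) {
    abort("At least two frames are required.", class = "af4saxs_domain_error")
  }
  q <- frames[[1]]$q
  for (f in frames) {
    if (length(f$q) != length(q) || any(abs(f$q - q) > 1e-9)) {
      abort("Frames must share a common q grid.", class = "af4saxs_format_error")
    }
  }
  pair_chi2 <- function(a, b) {
    s <- sqrt(a$sigma^2 + b$sigma^2)
    sum(((a$intensity - b$intensity) / s)^2) / (length(q) - 1)
  }
  m <- length(frames)
  cmat <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    cmat[i, j] <- cmat[j, i] <- pair_chi2(frames[[i]], frames[[j]])
  }
  med_idx <- which.min(apply(cmat, 1, median))
  stat <- cmat[med_idx, ]
  stat[med_idx] <- 0
  kept <- which(stat <= threshold)
  if (length(kept) < 2) {
    warn("No frame pair falls below the similarity threshold; returning the median frame alone.",
         class = "af4saxs_frame_warning")
    kept <- med_idx
  }
  w <- map(frames[kept], ~ 1 / .x$sigma^2)
  wsum <- Reduce(`+`, w)
  i_avg <- Reduce(`+`, map2(frames[kept], w, ~ .x$intensity * .y)) / wsum
  s_avg <- sqrt(1 / wsum)
  list(curve = scattering_curve(q, i_avg, s_avg),
       kept = kept, chi2 = stat, median_frame = med_idx)
}

.runs_test_p <- function(resid) {
  s <- sign(resid)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / (n1 + n2) + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n1 - n2) /
    ((n1 + n2)^2 * (n1 + n2 - 1))
  if (v <= 0) return(1)
  2 * pnorm(-abs((runs - mu) / sqrt(v)))
}

#' Guinier fit with automatic range selection
#'
#' Weighted linear fit of `ln I` against `q^2` over the largest low-q window
#' that satisfies `q_max * Rg <= q_rg_limit` self-consistently. The fit starts
#' at the third lowest usable (positive-intensity) point and grows outward,
#' re-estimating Rg until the range is stable. Systematic curvature of the
#' residuals (a Wald-Wolfowitz runs test at 5%) clears the `linear` flag --
#' the signature of aggregation or interparticle interference.
#'
#' @param curve A data frame with `q`, `intensity`, `sigma`.
#' @param q_rg_limit Upper limit on `q_max * Rg` (default 1.3).
#' @param min_points Minimum number of points in the fit window (default 10).
#'
#' @return An object of class `guinier_fit`: `rg_nm`, `i_zero`, `q_range`,
#'   `q_max_rg`, `r_squared`, `linear` (logical), `n_points`, `residuals`.
#' @export
guinier_fit <- function(curve, q_rg_limit = 1.3, min_points = 10) {
  stopifnot(all(c("q", "intensity") %in% names(curve)))
  sigma <- if ("sigma" %in% names(curve)) curve$sigma else abs(curve$intensity) * 0.01
  usable <- which(is.finite(curve$intensity) & curve$intensity > 0)
  if (length(usable) < min_points + 2) {
    abort("Too few positive-intensity points for a Guinier fit.",
          class = "af4saxs_fit_failure")
  }
  start <- usable[3]  # skip the first two points (beamstop / subtraction edge)
  idx_all <- usable[usable >= start]
  q <- curve$q[idx_all]; i <- curve$intensity[idx_all]; s <- sigma[idx_all]
  y <- log(i); x <- q^2
  wts <- (i / s)^2   # var(log I) = (sigma/I)^2

  fit_n <- function(n) {
    sel <- seq_len(n)
    f <- lm.wfit(cbind(1, x[sel]), y[sel], wts[sel])
    b <- f$coefficients
    rg2 <- -3 * b[2]
    list(i0 = exp(b[1]), rg = if (rg2 > 0) sqrt(rg2) else NA_real_,
         fit = f, n = n)
  }

  n <- min_points
  if (n > length(x)) n <- length(x)
  res <- fit_n(n)
  for (iter in 1:50) {
    if (is.na(res$rg)) break
    n_new <- max(min_points, sum(q * res$rg <= q_rg_limit))
    n_new <- min(n_new, length(x))
    if (n_new == res$n) break
    res <- fit_n(n_new)
  }
  if (is.na(res$rg)) {
    abort("Guinier slope is non-negative: no valid radius of gyration (check for aggregation).",
          class = "af4saxs_fit_failure")
  }
  sel <- seq_len(res$n)
  resid <- res$fit$residuals
  p_runs <- .runs_test_p(resid)
  ss_tot <- sum(wts[sel] * (y[sel] - weighted.mean(y[sel], wts[sel]))^2)
  r2 <- 1 - sum(wts[sel] * resid^2) / ss_tot
  structure(
    list(rg_nm = res$rg,
         i_zero = res$i0,
         q_range = c(q[1], q[res$n]),
         q_max_rg = q[res$n] * res$rg,
         r_squared = r2,
         linear = p_runs > 0.05,
         runs_p = p_runs,
         n_points = res$n,
         residuals = resid),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f nm, I(0) = %.4g (%d pts, q in [%.3g, %.3g], qmax*Rg = %.2f)\n",
              x$rg_nm, x$i_zero, x$n_points, x$q_range[1], x$q_range[2], x$q_max_rg))
  if (!x$linear) {
    cat("  WARNING: systematic curvature detected (runs test p = ",
        signif(x$runs_p, 3), ") - possible aggregation.\n", sep = "")
  }
  invisible(x)
}

#' @method glance guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble(rg_nm = x$rg_nm, i_zero = x$i_zero, q_min = x$q_range[1],
         q_max = x$q_range[2], q_max_rg = x$q_max_rg,
         r_squared = x$r_squared, linear = x$linear, n_points = x$n_points)
}

# design matrix mapping p(r) at interior nodes to I(q): I = 4 pi sum p sinc(qr) dr
.ift_design <- function(q, r) {
  dr <- r[2] - r[1]
  qr <- outer(q, r)
  k <- ifelse(qr < 1e-8, 1, sin(qr) / qr)
  4 * pi * k * dr
}

.second_diff <- function(m) {
  # second-difference operator on an interior vector with implicit zero endpoints
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    d[i, i] <- -2
    if (i > 1) d[i, i - 1] <- 1
    if (i < m) d[i, i + 1] <- 1
  }
  d
}

.ift_solve <- function(B, yw, D, alpha, nonneg) {
  H <- crossprod(B) + alpha * crossprod(D)
  g <- crossprod(B, yw)
  p <- tryCatch(drop(solve(H, g)), error = function(e) {
    abort("IFT normal equations are singular; increase the regularisation weight alpha.",
          class = "af4saxs_ift_error")
  })
  if (nonneg && any(p < 0)) {
    fn <- function(v) {
      r1 <- B %*% v - yw
      sum(r1^2) + alpha * sum((D %*% v)^2)
    }
    gr <- function(v) drop(2 * (H %*% v - g))
    p0 <- pmax(p, 0)
    opt <- optim(p0, fn, gr, method = "L-BFGS-B", lower = 0,
                 control = list(maxit = 500, factr = 1e7))
    p <- opt$par
  }
  p
}

#' Indirect Fourier transform: pair-distance distribution p(r)
#'
#' Solves `I(q) = 4 pi integral_0^Dmax p(r) sin(qr)/(qr) dr` for p(r) on a
#' regular grid by Tikhonov-regularised weighted least squares with a
#' second-difference smoothness penalty and hard endpoint constraints
#' `p(0) = p(Dmax) = 0`. `alpha = "auto"` picks the corner of the L-curve
#' (maximum curvature of log residual vs log penalty). Real-space invariants
#' are reported from the moments of p(r): `rg_real^2 = int r^2 p / (2 int p)`
#' and `i_zero_real = 4 pi int p dr`.
#'
#' @param curve A data frame with `q`, `intensity`, `sigma`.
#' @param d_max Assumed maximum particle dimension (nm), > 0.
#' @param alpha `"auto"` or a positive regularisation weight.
#' @param n_r Number of r-grid points including both endpoints (default 101).
#' @param nonneg Constrain p(r) >= 0 (default `TRUE`; disable when
#'   oscillations around zero are physical).
#'
#' @return An object of class `pddf`: `pr` (tibble `r`, `p`), `d_max`,
#'   `alpha`, `rg_real_nm`, `i_zero_real`, `chi2` (reduced, of the
#'   reconstruction), `fitted`.
#' @export
pddf_ift <- function(curve, d_max, alpha = "auto", n_r = 101, nonneg = TRUE) {
  stopifnot(all(c("q", "intensity") %in% names(curve)))
  if (d_max <= 0) abort("d_max must be positive.", class = "af4saxs_domain_error")
  if (max(curve$q) * d_max < pi) {
    warn("Curve barely reaches q*d_max ~ pi; p(r) will be poorly determined.",
         class = "af4saxs_resolution_warning")
  }
  sigma <- if ("sigma" %in% names(curve)) curve$sigma else abs(curve$intensity) * 0.01
  r_full <- seq(0, d_max, length.out = n_r)
  r <- r_full[-c(1, n_r)]
  A <- .ift_design(curve$q, r)
  W <- 1 / sigma
  B <- A * W
  yw <- curve$intensity * W
  D <- .second_diff(length(r))
  scale0 <- mean(diag(crossprod(B))) / mean(diag(crossprod(D)))

  if (identical(alpha, "auto")) {
    alphas <- scale0 * 10^seq(-8, 2, length.out = 25)
    pts <- map(alphas, function(a) {
      p <- .ift_solve(B, yw, D, a, nonneg = FALSE)
      c(rho = log(sum((B %*% p - yw)^2)), eta = log(sum((D %*% p)^2) + 1e-300))
    })
    rho <- map_dbl(pts, "rho"); eta <- map_dbl(pts, "eta")
    # discrete curvature of the L-curve
    k <- seq(2, length(alphas) - 1)
    d1r <- (rho[k + 1] - rho[k - 1]) / 2; d1e <- (eta[k + 1] - eta[k - 1]) / 2
    d2r <- rho[k + 1] - 2 * rho[k] + rho[k - 1]
    d2e <- eta[k + 1] - 2 * eta[k] + eta[k - 1]
    curv <- (d1r * d2e - d1e * d2r) / (d1r^2 + d1e^2)^1.5
    alpha <- alphas[k[which.max(curv)]]
  }
  p <- .ift_solve(B, yw, D, alpha, nonneg = nonneg)
  fitted <- drop(A %*% p)
  chi2 <- sum(((curve$intensity - fitted) / sigma)^2) / (length(fitted) - 1)

  p_full <- c(0, p, 0)
  dr <- r_full[2] - r_full[1]
  m0 <- pracma::trapz(r_full, p_full)
  m2 <- pracma::trapz(r_full, r_full^2 * p_full)
  rg_real <- if (m0 > 0) sqrt(m2 / (2 * m0)) else NA_real_
  structure(
    list(pr = tibble(r = r_full, p = p_full),
         d_max = d_max,
         alpha = alpha,
         rg_real_nm = rg_real,
         i_zero_real = 4 * pi * m0,
         chi2 = chi2,
         fitted = fitted,
         nonneg = nonneg),
    class = "pddf"
  )
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf("p(r) by regularised IFT: Dmax = %.2f nm, alpha = %.3g\n",
              x$d_max, x$alpha))
  cat(sprintf("  Rg(real) = %.3f nm, I(0)(real) = %.4g, reconstruction chi2 = %.3g\n",
              x$rg_real_nm, x$i_zero_real, x$chi2))
  invisible(x)
}

#' @method tidy pddf
#' @export
tidy.pddf <- function(x, ...) x$pr

#' @method glance pddf
#' @export
glance.pddf <- function(x, ...) {
  tibble(d_max = x$d_max, alpha = x$alpha, rg_real_nm = x$rg_real_nm,
         i_zero_real = x$i_zero_real, chi2 = x$chi2)
}

#' Scan d_max for the IFT
#'
#' Runs [pddf_ift()] over a grid of trial maximum dimensions and selects the
#' smallest d_max whose reconstruction chi2 is within 5% of the plateau
#' minimum: underestimating d_max leaves structure the model cannot fit
#' (chi2 rises sharply), while overestimating merely wastes grid, so the
#' elbow marks the particle's true extent.
#'
#' @inheritParams pddf_ift
#' @param d_max_values Numeric vector of trial d_max (nm).
#'
#' @return A list: `scan` (tibble `d_max`, `chi2`, `rg_real_nm`), `best`
#'   (selected d_max), `pddf` (the fit at `best`).
#' @export
pddf_dmax_scan <- function(curve, d_max_values, alpha = "auto", n_r = 101,
                           nonneg = TRUE) {
  stopifnot(length(d_max_values) >= 3)
  d_max_values <- sort(d_max_values)
  fits <- map(d_max_values, function(d)
    pddf_ift(curve, d, alpha = alpha, n_r = n_r, nonneg = nonneg))
  scan <- tibble(
    d_max = d_max_values,
    chi2 = map_dbl(fits, "chi2"),
    rg_real_nm = map_dbl(fits, "rg_real_nm")
  )
  best_i <- which(scan$chi2 <= 1.05 * min(scan$chi2))[1]
  list(scan = scan, best = scan$d_max[best_i], pddf = fits[[best_i]])
}

#' Porod invariant, Porod volume and Porod molecular weight
#'
#' Computes the invariant `Q = int q^2 I(q) dq` with both tails modelled: the
#' unmeasured low-q region from the Guinier extrapolation to q = 0, and the
#' high-q region from a Porod law `I = K/q^4` with `K` the mean of `q^4 I`
#' over the last decade of the measured range. Then `Vp = 2 pi^2 I(0) / Q`
#' and the protein molecular weight estimate is `Vp / 1.6` (kDa per nm^3),
#' reported rounded half away from zero to integer kDa.
#'
#' @param curve A data frame with `q` (1/nm), `intensity`, optionally `sigma`.
#' @param i_zero Forward scattering I(0); if `NULL`, taken from an internal
#'   [guinier_fit()].
#' @param rg_nm Radius of gyration for the low-q extrapolation; if `NULL`,
#'   from the same Guinier fit.
#'
#' @return A one-row tibble of class `porod_result`: `invariant_q`,
#'   `porod_volume_nm3`, `mw_porod_kda` (rounded), `mw_porod_raw_kda`,
#'   `porod_constant`.
#' @export
porod_volume <- function(curve, i_zero = NULL, rg_nm = NULL) {
  stopifnot(all(c("q", "intensity") %in% names(curve)))
  if (is.null(i_zero) || is.null(rg_nm)) {
    gf <- guinier_fit(curve)
    if (is.null(i_zero)) i_zero <- gf$i_zero
    if (is.null(rg_nm)) rg_nm <- gf$rg_nm
  }
  q <- curve$q; i <- curve$intensity
  # high-q tail: Porod constant from the last decade of q
  tail_sel <- q >= max(q) / 10^0.5
  porod_k <- mean(q[tail_sel]^4 * i[tail_sel])
  if (porod_k <= 0) {
    abort("Negative Porod constant: background over-subtraction suspected.",
          class = "af4saxs_domain_error")
  }
  # low-q tail from the Guinier model
  low <- integrate(function(x) x^2 * i_zero * exp(-x^2 * rg_nm^2 / 3),
                   0, q[1])$value
  mid <- pracma::trapz(q, q^2 * i)
  high <- porod_k / max(q)
  qq <- low + mid + high
  vp <- 2 * pi^2 * i_zero / qq
  out <- tibble(invariant_q = qq,
                porod_volume_nm3 = vp,
                mw_porod_kda = mw_from_porod(vp),
                mw_porod_raw_kda = vp / 1.6,
                porod_constant = porod_k)
  class(out) <- c("porod_result", class(out))
  out
}

# round half away from zero
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Molecular weight from the Porod volume
#'
#' Protein rule of thumb: hydrated-particle Porod volume in nm^3 divided by
#' 1.6 gives the molecular weight in kDa, rounded half away from zero to an
#' integer for reporting.
#'
#' @param vp_nm3 Porod volume(s) in nm^3.
#' @return Integer kDa.
#' @export
mw_from_porod <- function(vp_nm3) {
  .round_half_away(vp_nm3 / 1.6)
}

#' Molecular weight from an ab initio model's excluded volume
#'
#' Bead-model excluded volumes overcount protein volume roughly twofold, so
#' the molecular weight estimate is the excluded volume (nm^3) divided by 2,
#' in kDa.
#'
#' @param v_a_nm3 Excluded volume(s) in nm^3, >= 0.
#' @return kDa.
#' @export
mw_from_excluded_volume <- function(v_a_nm3) {
  if (any(v_a_nm3 < 0)) abort("Excluded volume must be non-negative.",
                              class = "af4saxs_domain_error")
  v_a_nm3 / 2
}

#' Molecular weight from a concentration standard
#'
#' `MW = MW_ref * (I(0)/c) / (I(0)_ref / c_ref)`: forward scattering per unit
#' mass concentration is proportional to molecular weight, so a single
#' well-characterised standard (classically BSA) calibrates the scale.
#'
#' @param i_zero,concentration_mg_ml Sample forward scattering and
#'   concentration.
#' @param ref_i_zero,ref_concentration_mg_ml,ref_mw_kda Reference standard.
#'
#' @return Molecular weight in kDa.
#' @export
mw_from_standard <- function(i_zero, concentration_mg_ml,
                             ref_i_zero, ref_concentration_mg_ml, ref_mw_kda) {
  if (ref_i_zero <= 0 || ref_concentration_mg_ml <= 0 || ref_mw_kda <= 0 ||
      concentration_mg_ml <= 0) {
    abort("Reference and sample quantities must be positive.",
          class = "af4saxs_domain_error")
  }
  ref_mw_kda * (i_zero / concentration_mg_ml) /
    (ref_i_zero / ref_concentration_mg_ml)
}

#' Shape factor rho = Rg / Rh
#'
#' The ratio of the radius of gyration (from SAXS) to the hydrodynamic radius
#' (from AF4 retention theory). A homogeneous solid sphere gives
#' `sqrt(3/5) ~ 0.77`; larger values indicate elongation or flexibility.
#' Reports carry the value to two significant figures.
#'
#' @param rg_nm Radius of gyration (nm), > 0.
#' @param rh_nm Hydrodynamic radius (nm), > 0.
#'
#' @return A one-row tibble: `rho`, `rho_reported` (2 significant figures),
#'   `rg_nm`, `rh_nm`.
#' @export
shape_factor <- function(rg_nm, rh_nm) {
  if (any(rg_nm <= 0) || any(rh_nm <= 0)) {
    abort("Both radii must be positive.", class = "af4saxs_domain_error")
  }
  rho <- rg_nm / rh_nm
  tibble(rho = rho, rho_reported = signif(rho, 2), rg_nm = rg_nm, rh_nm = rh_nm)
}
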