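#' AF4 channel geometry
#'
#' Describes a trapezoidal asymmetrical flow field-flow fractionation channel.
#' The effective channel height is the nominal spacer thickness multiplied by a
#' calibration factor (`thickness_scale`): membranes swell or compress under
#' operating pressure, so the effective height generally differs from the
#' spacer, and printed hydrodynamic radii are reproducible only after
#' calibrating the scale against a reference species (see
#' [calibrate_thickness()]).
#'
#' @param length_cm Tip-to-tip channel length (cm).
#' @param inlet_width_cm Channel breadth at the inlet end (cm).
#' @param outlet_width_cm Channel breadth at the outlet end (cm); must not
#'   exceed `inlet_width_cm`.
#' @param spacer_um Nominal spacer thickness (micrometres).
#' @param thickness_scale Dimensionless calibration factor applied to the
#'   nominal thickness; defaults to 1 (uncalibrated).
#' @param focus_cm Focusing position measured from the inlet (cm). Only the
#'   channel volume downstream of this position contributes to the void time.
#'
#' @return An object of class `channel_geometry`.
#' @examples
#' geom <- channel_geometry()
#' channel_void_volume(geom)
#' @export
channel_geometry <- function(length_cm = 26.5,
                             inlet_width_cm = 2.2,
                             outlet_width_cm = 0.6,
                             spacer_um = 350,
                             thickness_scale = 1,
                             focus_cm = 2) {
  if (!all(is.finite(c(length_cm, inlet_width_cm, outlet_width_cm, spacer_um,
                       thickness_scale, focus_cm)))) {
    abort("All channel dimensions must be finite numbers.",
          class = "af4saxs_invalid_geometry")
  }
  if (length_cm <= 0 || inlet_width_cm <= 0 || outlet_width_cm <= 0 ||
      spacer_um <= 0 || thickness_scale <= 0) {
    abort("Channel dimensions and thickness scale must be positive.",
          class = "af4saxs_invalid_geometry")
  }
  if (outlet_width_cm > inlet_width_cm) {
    abort("Outlet width must not exceed inlet width.",
          class = "af4saxs_invalid_geometry")
  }
  if (focus_cm < 0 || focus_cm >= length_cm) {
    abort("Focus position must lie in [0, length).",
          class = "af4saxs_invalid_geometry")
  }
  structure(
    list(length_cm = length_cm,
         inlet_width_cm = inlet_width_cm,
         outlet_width_cm = outlet_width_cm,
         spacer_um = spacer_um,
         thickness_scale = thickness_scale,
         focus_cm = focus_cm),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat("AF4 channel geometry\n")
  cat(sprintf("  tip-to-tip length : %.2f cm\n", x$length_cm))
  cat(sprintf("  inlet/outlet width: %.2f / %.2f cm\n",
              x$inlet_width_cm, x$outlet_width_cm))
  cat(sprintf("  spacer            : %.0f um (scale %.4f -> w = %.1f um)\n",
              x$spacer_um, x$thickness_scale,
              x$spacer_um * x$thickness_scale))
  cat(sprintf("  focus position    : %.2f cm\n", x$focus_cm))
  invisible(x)
}

#' Flow conditions for an AF4 run
#'
#' @param detector_ml_min Channel (detector) flow rate (mL/min).
#' @param crossflow_ml_min Cross-flow rate (mL/min); zero means unretained
#'   elution.
#' @param duration_min Elution duration (min).
#'
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(detector_ml_min = 1.0,
                            crossflow_ml_min = 4.5,
                            duration_min = 30) {
  if (detector_ml_min <= 0) {
    abort("Detector flow must be positive.", class = "af4saxs_invalid_flows")
  }
  if (crossflow_ml_min < 0) {
    abort("Cross-flow must be non-negative.", class = "af4saxs_invalid_flows")
  }
  structure(
    list(detector_ml_min = detector_ml_min,
         crossflow_ml_min = crossflow_ml_min,
         duration_min = duration_min),
    class = "flow_conditions"
  )
}

#' Solvent and optical conditions
#'
#' Carrier-liquid properties used by both the retention model (temperature,
#' viscosity, via Stokes-Einstein) and the light-scattering optics (refractive
#' index, vacuum laser wavelength). Defaults describe an aqueous buffer at room
#' temperature read out with a 658 nm MALS laser.
#'
#' @param temperature_K Absolute temperature (K).
#' @param viscosity_Pa_s Dynamic viscosity (Pa s).
#' @param refractive_index Solvent refractive index (dimensionless).
#' @param laser_nm Vacuum laser wavelength (nm).
#'
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature_K = 298.15,
                               viscosity_Pa_s = 8.9e-4,
                               refractive_index = 1.331,
                               laser_nm = 658) {
  if (temperature_K <= 0 || viscosity_Pa_s <= 0) {
    abort("Temperature and viscosity must be positive.",
          class = "af4saxs_invalid_solvent")
  }
  if (refractive_index < 1) {
    abort("Refractive index must be >= 1.", class = "af4saxs_invalid_solvent")
  }
  structure(
    list(temperature_K = temperature_K,
         viscosity_Pa_s = viscosity_Pa_s,
         refractive_index = refractive_index,
         laser_nm = laser_nm),
    class = "solvent_conditions"
  )
}

# effective channel height in cm
.channel_height_cm <- function(geometry) {
  geometry$spacer_um * 1e-4 * geometry$thickness_scale
}

# plan area (cm^2) of the trapezoid between positions z1 and z2 from the inlet
.plan_area_cm2 <- function(geometry, z1 = 0, z2 = geometry$length_cm) {
  b <- function(z) {
    geometry$inlet_width_cm +
      (geometry$outlet_width_cm - geometry$inlet_width_cm) * z / geometry$length_cm
  }
  (z2 - z1) * (b(z1) + b(z2)) / 2
}

#' Geometric void volume of the channel
#'
#' Effective thickness times the trapezoidal plan area. With
#' `downstream_of_focus = TRUE` only the volume between the focusing position
#' and the outlet is counted; that sub-volume divided by the detector flow is
#' the void time used throughout the retention model.
#'
#' @param geometry A [channel_geometry()].
#' @param downstream_of_focus Count only the volume downstream of the focus
#'   position? Default `FALSE` (full channel).
#'
#' @return Volume in mL.
#' @export
channel_void_volume <- function(geometry, downstream_of_focus = FALSE) {
  stopifnot(inherits(geometry, "channel_geometry"))
  z1 <- if (downstream_of_focus) geometry$focus_cm else 0
  .plan_area_cm2(geometry, z1) * .channel_height_cm(geometry)
}

#' FFF retention ratio from the retention parameter
#'
#' Classical field-flow fractionation retention equation
#' `R = 6 * lambda * (coth(1/(2*lambda)) - 2*lambda)`, relating the
#' dimensionless thickness `lambda` of the exponential concentration layer at
#' the accumulation wall to the retention ratio `R = t0 / tr`. The
#' implementation is numerically stable from the high-retention limit
#' (`R ~ 6*lambda` for small `lambda`) up to the unretained limit (`R -> 1`),
#' where a series expansion avoids catastrophic cancellation.
#'
#' @param lambda_parameter Retention parameter(s), > 0. Vectorised.
#' @return Retention ratio(s) in (0, 1).
#' @export
retention_ratio_from_lambda <- function(lambda_parameter) {
  if (any(!is.finite(lambda_parameter)) || any(lambda_parameter <= 0)) {
    abort("lambda must be positive and finite.", class = "af4saxs_domain_error")
  }
  l <- lambda_parameter
  r <- numeric(length(l))
  big <- l > 10
  # coth(1/(2l)) - 2l expanded for large lambda; direct form elsewhere
  r[big] <- 1 - 1 / (60 * l[big]^2) + 1 / (2520 * l[big]^4)
  x <- 1 / (2 * l[!big])
  r[!big] <- 6 * l[!big] * (1 / tanh(x) - 2 * l[!big])
  pmin(r, 1)
}

# t0 (min): downstream-of-focus volume over detector flow
.void_time_min <- function(geometry, flows) {
  channel_void_volume(geometry, downstream_of_focus = TRUE) / flows$detector_ml_min
}

# Stokes-Einstein: diffusion coefficient (cm^2/s) from Rh (nm)
.diffusion_from_rh <- function(rh_nm, solvent) {
  d_m2 <- .kB * solvent$temperature_K /
    (6 * pi * solvent$viscosity_Pa_s * rh_nm * 1e-9)
  d_m2 * 1e4
}

.rh_from_diffusion <- function(d_cm2_s, solvent) {
  rh_m <- .kB * solvent$temperature_K /
    (6 * pi * solvent$viscosity_Pa_s * d_cm2_s * 1e-4)
  rh_m * 1e9
}

# lambda for a given diffusion coefficient (cm^2/s)
.lambda_from_diffusion <- function(d_cm2_s, geometry, flows) {
  v0 <- channel_void_volume(geometry)            # cm^3
  vc <- flows$crossflow_ml_min / 60              # cm^3/s
  w <- .channel_height_cm(geometry)
  d_cm2_s * v0 / (vc * w^2)
}

#' Predicted retention time for a hydrodynamic radius
#'
#' Forward retention model: Stokes-Einstein diffusion coefficient, retention
#' parameter `lambda = D V0 / (Vc w^2)`, then `tr = t0 / R(lambda)`. Strictly
#' increasing in `rh_nm`. Species with `lambda >= 10` are effectively
#' unretained and elute at the void time (flagged by the `unretained`
#' attribute); with zero cross-flow everything elutes at `t0`.
#'
#' @param rh_nm Hydrodynamic radius(es) in nm, > 0. Vectorised.
#' @param geometry A [channel_geometry()].
#' @param flows A [flow_conditions()].
#' @param solvent A [solvent_conditions()].
#'
#' @return Retention time(s) in minutes, with attribute `unretained` (logical).
#' @export
time_from_radius <- function(rh_nm, geometry, flows, solvent) {
  if (any(rh_nm <= 0)) {
    abort("Hydrodynamic radius must be positive.", class = "af4saxs_domain_error")
  }
  t0 <- .void_time_min(geometry, flows)
  if (flows$crossflow_ml_min == 0) {
    tr <- rep(t0, length(rh_nm))
    attr(tr, "unretained") <- rep(TRUE, length(rh_nm))
    return(tr)
  }
  d <- .diffusion_from_rh(rh_nm, solvent)
  lam <- .lambda_from_diffusion(d, geometry, flows)
  tr <- t0 / retention_ratio_from_lambda(lam)
  attr(tr, "unretained") <- lam >= 10
  tr
}

#' Hydrodynamic radius from a retention time
#'
#' Inverts the retention model: solves `R(lambda) = t0 / tr` for `lambda` by
#' bracketed root finding (relative tolerance 1e-10), converts to a diffusion
#' coefficient `D = lambda Vc w^2 / V0`, and applies Stokes-Einstein. Inverse
#' of [time_from_radius()] to better than 1e-6 relative.
#'
#' If the geometry carries an uncalibrated thickness (`thickness_scale == 1`),
#' a one-time warning reminds that absolute radii depend on the effective
#' channel height; calibrate with [calibrate_thickness()] to match instrument
#' numbers.
#'
#' @param tr_min Retention time(s) in minutes; must exceed the void time.
#' @inheritParams time_from_radius
#' @param quiet Suppress the uncalibrated-geometry warning.
#'
#' @return A tibble with columns `retention_time`, `void_time`,
#'   `retention_ratio`, `lambda`, `diffusion_cm2_s`, `rh_nm` (one row per input
#'   time).
#' @export
radius_from_retention_time <- function(tr_min, geometry, flows, solvent,
                                       quiet = FALSE) {
  t0 <- .void_time_min(geometry, flows)
  if (any(tr_min <= t0)) {
    abort(sprintf("Retention time must exceed the void time (t0 = %.3f min): unretained species.", t0),
          class = "af4saxs_unretained_error")
  }
  if (flows$crossflow_ml_min == 0) {
    abort("Zero cross-flow: retention carries no size information.",
          class = "af4saxs_unretained_error")
  }
  if (!quiet && isTRUE(all.equal(geometry$thickness_scale, 1))) {
    warn(paste("Channel thickness is uncalibrated (thickness_scale = 1);",
               "absolute radii may be biased. See calibrate_thickness()."),
         class = "af4saxs_uncalibrated_warning")
  }
  v0 <- channel_void_volume(geometry)
  vc <- flows$crossflow_ml_min / 60
  w <- .channel_height_cm(geometry)

  one <- function(tr) {
    r_target <- t0 / tr
    f <- function(u) retention_ratio_from_lambda(exp(u)) - r_target
    lo <- log(1e-12); hi <- log(1e6)
    if (f(lo) > 0 || f(hi) < 0) {
      abort(sprintf("No retention parameter brackets R = %.4g (tr = %.4g min).",
                    r_target, tr),
            class = "af4saxs_convergence_error")
    }
    root <- uniroot(f, c(lo, hi), tol = 1e-12)
    lam <- exp(root$root)
    d <- lam * vc * w^2 / v0
    tibble(
      retention_time = tr,
      void_time = t0,
      retention_ratio = r_target,
      lambda = lam,
      diffusion_cm2_s = d,
      rh_nm = .rh_from_diffusion(d, solvent)
    )
  }
  list_rbind(map(tr_min, one))
}

#' Calibrate the effective channel thickness against a reference species
#'
#' Searches `thickness_scale` in [0.2, 2] so that the forward model maps the
#' reference hydrodynamic radius to the observed reference retention time
#' (relative tolerance 1e-6). This is the supported way to reproduce
#' instrument-reported radii: the nominal spacer thickness is not the effective
#' channel height.
#'
#' @param reference_rh_nm Known hydrodynamic radius of the reference (nm).
#' @param reference_tr_min Observed retention time of the reference (min).
#' @inheritParams time_from_radius
#'
#' @return The input geometry with `thickness_scale` replaced by the calibrated
#'   value.
#' @export
calibrate_thickness <- function(reference_rh_nm, reference_tr_min,
                                geometry, flows, solvent) {
  stopifnot(inherits(geometry, "channel_geometry"))
  f <- function(s) {
    g <- geometry
    g$thickness_scale <- s
    as.numeric(time_from_radius(reference_rh_nm, g, flows, solvent)) -
      reference_tr_min
  }
  lo <- 0.2; hi <- 2.0
  flo <- f(lo); fhi <- f(hi)
  if (f(lo) * f(hi) > 0) {
    abort(paste0("No thickness scale in [0.2, 2] reproduces the reference ",
                 "retention time (f(0.2) = ", signif(flo, 4),
                 ", f(2) = ", signif(fhi, 4), " min)."),
          class = "af4saxs_calibration_error")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-10)
  geometry$thickness_scale <- root$root
  geometry
}
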