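#' Characterise AF4 peaks: hydrodynamic radius and Berry molar mass
#'
#' For each named elution window, reports the UV peak position, the
#' hydrodynamic radius at the peak maximum from retention theory, and the
#' weight-average Berry molar mass over the window.
#'
#' @param fractogram A fractogram tibble.
#' @param windows Named list of length-2 windows (min).
#' @param geometry,flows,solvent Channel model (geometry should be
#'   calibrated, see [calibrate_thickness()]).
#' @param dn_dc Refractive-index increment used for concentration and K*.
#' @param ... Passed to [peak_mass_profile()].
#'
#' @return A tibble with one row per window: `peak`, `window_lo`, `window_hi`,
#'   `tr_peak_min`, `rh_nm`, `mw_wavg_kda`, `mw_sd_kda`, `n_slices`,
#'   `determined`.
#' @export
analyze_af4_peaks <- function(fractogram, windows, geometry, flows, solvent,
                              dn_dc = 0.185, ...) {
  stopifnot(is.list(windows), length(windows) >= 1)
  rows <- imap(windows, function(w, nm) {
    sel <- fractogram$time_min >= w[1] & fractogram$time_min <= w[2]
    if (!any(sel)) {
      abort(sprintf("Window `%s` contains no data.", nm),
            class = "af4saxs_domain_error")
    }
    tr_peak <- fractogram$time_min[sel][which.max(fractogram$uv_au[sel])]
    rh <- radius_from_retention_time(tr_peak, geometry, flows, solvent,
                                     quiet = TRUE)$rh_nm
    prof <- peak_mass_profile(fractogram, w, dn_dc, solvent, ...)
    tibble(peak = nm, window_lo = w[1], window_hi = w[2],
           tr_peak_min = tr_peak, rh_nm = rh,
           mw_wavg_kda = prof$mw_wavg_kda, mw_sd_kda = prof$mw_sd_kda,
           n_slices = prof$n_slices, determined = prof$determined)
  })
  list_rbind(unname(rows))
}

#' Analyse a binding titration series
#'
#' Runs the full area-based binding pipeline on a [simulate_titration_series()]
#' bundle (or an equivalently shaped list of measured fractograms): the
#' pure-ligand run defines the area-to-molarity conversion factor, the
#' pure-albumin run the reference dimer area and the monomer/dimer content,
#' and each mixture is deconvoluted into free-ligand, monomer-region and
#' dimer-region Gaussians before the bound-ratio bookkeeping.
#'
#' Default deconvolution windows are wider than the pure-component elution
#' ranges because complex peaks shift to later times as occupancy grows.
#'
#' @param series A `titration_series` (see [simulate_titration_series()]).
#' @param mixture_windows Named list of three windows (`free`, `monomer`,
#'   `dimer`), minutes.
#' @param hsa_windows Named list of two windows for the pure-albumin run.
#'
#' @return A tibble of class `binding_isotherm`, one row per titration point:
#'   `molar_ratio_added`, `gaz_per_monomer`, `gaz_per_dimer`, `free_per_hsa`,
#'   `overall`, plus the underlying concentrations and (when the series is
#'   synthetic) the ground-truth columns.
#' @export
analyze_binding_titration <- function(series,
                                      mixture_windows = list(
                                        free = c(3.0, 4.2),
                                        monomer = c(4.2, 6.2),
                                        dimer = c(6.2, 8.6)),
                                      hsa_windows = list(
                                        monomer = c(3.8, 5.6),
                                        dimer = c(5.8, 7.5))) {
  stopifnot(inherits(series, "titration_series"))
  uv <- function(fr) tibble(time_min = fr$time_min, signal = fr$uv_au)

  gaz_area <- area_under_peak(uv(series$pure_gaz),
                              c(0, max(series$pure_gaz$time_min)))
  konv <- konv_from_pure_injection(gaz_area, series$pure_gaz_conc_mg_ml,
                                   series$gaz_mw_kda)
  hsa_deconv <- fit_baseline_and_deconvolve(uv(series$pure_hsa), hsa_windows)
  content <- monomer_dimer_content(uv(series$pure_hsa),
                                   hsa_windows$monomer, hsa_windows$dimer)
  f_mono <- content$monomer_fraction

  # propagated area noise from the baseline of the pure-albumin run
  base_sd <- .baseline_stats(series$pure_hsa, "uv_au")$uv_au$sd
  dt <- median(diff(series$pure_hsa$time_min))
  width <- diff(mixture_windows$dimer)
  noise_area <- base_sd * sqrt(width * dt)

  rows <- map(seq_len(nrow(series$points)), function(i) {
    pt <- series$points[i, ]
    mix_deconv <- fit_baseline_and_deconvolve(uv(pt$fractogram[[1]]),
                                              mixture_windows)
    # detection limit: components below 3x the baseline noise carry no area
    nd <- mix_deconv$peaks$amplitude < 3 * base_sd
    mix_deconv$peaks$area[nd] <- 0
    br <- binding_ratios(mix_deconv, hsa_deconv, konv,
                         hsa_total_mol_l = series$hsa_total_mol_l,
                         monomer_fraction = f_mono,
                         gaz_added_mol_l = pt$gaz_added_mol_l,
                         noise_area = noise_area)
    bind_cols(
      tibble(molar_ratio_added = pt$molar_ratio,
             gaz_per_monomer = br$gaz_per_hsa_monomer,
             gaz_per_dimer = br$gaz_per_hsa_dimer,
             free_per_hsa = br$free_gaz_per_hsa_tot,
             overall = br$overall_gaz_per_hsa),
      br[, c("c_gaz_added", "c_gaz_free", "c_gaz_in_dimer",
             "c_hsa_monomer", "c_hsa_dimer", "c_hsa_tot")],
      pt[, intersect(c("true_free_mol_l", "true_in_dimer_mol_l",
                       "true_per_monomer", "true_per_dimer", "true_overall"),
                     names(pt))]
    )
  })
  out <- list_rbind(rows)
  attr(out, "konv") <- konv
  attr(out, "monomer_fraction") <- f_mono
  class(out) <- c("binding_isotherm", class(out))
  out
}

#' Primary SAXS analysis of one curve
#'
#' Guinier fit, regularised p(r) (with an optional d_max scan), Porod volume
#' and the molecular-weight estimators, returned as a single summary row.
#'
#' @param curve A data frame with `q`, `intensity`, `sigma`.
#' @param d_max Maximum dimension (nm), or `"scan"` to select it with
#'   [pddf_dmax_scan()].
#' @param d_max_grid Trial values when scanning.
#' @param reference Optional list with `i_zero`, `concentration_mg_ml`,
#'   `mw_kda` describing a concentration standard for [mw_from_standard()];
#'   requires the curve to carry a `concentration_mg_ml` attribute.
#' @param rh_nm Optional hydrodynamic radius for the shape factor.
#'
#' @return A one-row tibble: `rg_nm`, `i_zero`, `q_min`, `q_max`, `guinier_linear`,
#'   `d_max_nm`, `rg_real_nm`, `porod_volume_nm3`, `mw_porod_kda`,
#'   `mw_standard_kda`, `shape_factor`.
#' @export
analyze_saxs_curve <- function(curve, d_max = "scan",
                               d_max_grid = seq(6, 20, by = 1),
                               reference = NULL, rh_nm = NULL) {
  gf <- guinier_fit(curve)
  pd <- if (identical(d_max, "scan")) {
    pddf_dmax_scan(curve, d_max_grid)$pddf
  } else {
    pddf_ift(curve, d_max)
  }
  po <- porod_volume(curve, i_zero = gf$i_zero, rg_nm = gf$rg_nm)
  mw_s <- NA_real_
  conc <- attr(curve, "concentration_mg_ml")
  if (!is.null(reference) && !is.null(conc)) {
    mw_s <- mw_from_standard(gf$i_zero, conc, reference$i_zero,
                             reference$concentration_mg_ml, reference$mw_kda)
  }
  rho <- if (!is.null(rh_nm)) shape_factor(gf$rg_nm, rh_nm)$rho_reported else NA_real_
  tibble(rg_nm = gf$rg_nm, i_zero = gf$i_zero,
         q_min = gf$q_range[1], q_max = gf$q_range[2],
         guinier_linear = gf$linear,
         d_max_nm = pd$d_max, rg_real_nm = pd$rg_real_nm,
         porod_volume_nm3 = po$porod_volume_nm3,
         mw_porod_kda = po$mw_porod_kda,
         mw_standard_kda = mw_s,
         shape_factor = rho)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages named in the config -- channel calibration, AF4 peak
#' characterisation, binding-titration analysis and SAXS primary analysis --
#' with partial-failure isolation: an error in one stage is recorded in the
#' report without voiding the others. Reports are deterministic given the
#' same config and seed.
#'
#' Config shape (YAML file or list): sections `channel`, `flows`, `solvent`
#' (see [read_config()]); optional `calibration` (`reference_rh_nm`,
#' `reference_tr_min`); optional `af4` (`fractogram` path or `"simulate"`,
#' `windows`, `dn_dc`); optional `binding` (`simulate: true` plus generator
#' parameters); optional `saxs` (`curve` path or a simulation spec, `d_max`);
#' optional `seed`.
#'
#' @param config Path to a YAML config or an equivalent named list.
#'
#' @return An object of class `analysis_report`: a list with `config`,
#'   `calibration`, `af4`, `binding`, `saxs`, `errors`, `seed`, `version`.
#' @export
run_pipeline <- function(config) {
  cfg_in <- if (is.list(config)) config else yaml::read_yaml(config)
  required <- c("channel", "flows", "solvent")
  if (length(cfg_in) == 0 || !any(required %in% names(cfg_in))) {
    abort(paste0("Config is empty or lacks the instrument sections; required keys: ",
                 paste(required, collapse = ", "),
                 " (plus at least one analysis stage: af4, binding, saxs)."),
          class = "af4saxs_config_error")
  }
  cfg <- read_config(cfg_in)
  seed <- cfg_in$seed %||% 1L
  errors <- list()
  note_error <- function(stage, e) {
    errors[[stage]] <<- conditionMessage(e)
    NULL
  }

  geometry <- cfg$geometry
  calibration <- NULL
  if (!is.null(cfg_in$calibration)) {
    calibration <- tryCatch({
      geometry <- calibrate_thickness(cfg_in$calibration$reference_rh_nm,
                                      cfg_in$calibration$reference_tr_min,
                                      geometry, cfg$flows, cfg$solvent)
      list(thickness_scale = geometry$thickness_scale,
           reference_rh_nm = cfg_in$calibration$reference_rh_nm,
           reference_tr_min = cfg_in$calibration$reference_tr_min)
    }, error = function(e) note_error("calibration", e))
  }

  af4 <- NULL
  if (!is.null(cfg_in$af4)) {
    af4 <- tryCatch({
      spec <- cfg_in$af4
      fr <- if (identical(spec$fractogram, "simulate")) {
        mix <- bind_rows(hsa_monomer(), hsa_dimer())
        mix$conc_mg_ml <- c(spec$monomer_fraction %||% 0.93,
                            1 - (spec$monomer_fraction %||% 0.93)) *
          (spec$conc_mg_ml %||% 2)
        simulate_fractogram(mix, geometry, cfg$flows, cfg$solvent,
                            noise_rel = spec$noise_rel %||% 0.005,
                            seed = seed)
      } else {
        read_fractogram(spec$fractogram)
      }
      windows <- map(spec$windows %||%
                       list(monomer = c(3.8, 5.6), dimer = c(5.8, 7.5)),
                     as.numeric)
      analyze_af4_peaks(fr, windows, geometry, cfg$flows, cfg$solvent,
                        dn_dc = spec$dn_dc %||% 0.185)
    }, error = function(e) note_error("af4", e))
  }

  binding <- NULL
  if (!is.null(cfg_in$binding)) {
    binding <- tryCatch({
      spec <- cfg_in$binding
      series <- simulate_titration_series(
        gaz_stocks_mg_ml = unlist(spec$gaz_stocks_mg_ml %||%
                                    c(0.01, 0.05, 0.1, 0.3, 0.5, 1, 2)),
        hsa_stock_mg_ml = spec$hsa_stock_mg_ml %||% 2,
        kd = spec$kd %||% 1e-9,
        gaz_dimer_fraction = spec$gaz_dimer_fraction %||% (6 / 13),
        monomer_fraction = spec$monomer_fraction %||% 0.93,
        geometry = geometry, flows = cfg$flows, solvent = cfg$solvent,
        noise_rel = spec$noise_rel %||% 0.005,
        seed = seed
      )
      iso <- analyze_binding_titration(series)
      iso$fractogram <- NULL
      iso
    }, error = function(e) note_error("binding", e))
  }

  saxs <- NULL
  if (!is.null(cfg_in$saxs)) {
    saxs <- tryCatch({
      spec <- cfg_in$saxs
      curve <- if (!is.null(spec$curve)) {
        read_saxs_curve(spec$curve)
      } else {
        simulate_saxs_curve(
          model = spec$model %||% "sphere",
          radius_nm = spec$radius_nm %||% 3,
          semi_axes_nm = unlist(spec$semi_axes_nm %||% c(4, 4, 1.5)),
          noise_rel = spec$noise_rel %||% 0.01,
          seed = seed
        )
      }
      analyze_saxs_curve(curve,
                         d_max = spec$d_max %||% "scan",
                         rh_nm = spec$rh_nm)
    }, error = function(e) note_error("saxs", e))
  }

  structure(
    list(config = cfg_in,
         calibration = calibration,
         af4 = af4,
         binding = binding,
         saxs = saxs,
         errors = errors,
         seed = seed,
         version = as.character(utils::packageVersion("af4saxs"))),
    class = "analysis_report"
  )
}

#' Write an analysis report as JSON
#'
#' Full numeric precision; deterministic for a given report object.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("af4saxs analysis report (version ", x$version, ", seed ", x$seed, ")\n",
      sep = "")
  for (stage in c("calibration", "af4", "binding", "saxs")) {
    status <- if (!is.null(x[[stage]])) "ok"
      else if (!is.null(x$errors[[stage]])) paste0("FAILED: ", x$errors[[stage]])
      else "skipped"
    cat(sprintf("  %-12s %s\n", stage, status))
  }
  invisible(x)
}
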