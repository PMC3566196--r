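# End-to-end per-subject pipeline: acquire (phantom or NIfTI files) ->
# segment -> quantify -> venous correction -> ICVC -> pressure gradient ->
# compliance / MRICP, with CSV/NIfTI/JSON artifact export.

#' Default synthetic subject: vessel geometry and acquisition settings
#'
#' A two-series phantom with the ten lumina of the cervical measurement plane:
#' four arteries and two jugular veins on the high-VENC series, three
#' secondary veins and the CSF channel on the low-VENC series. Pressure
#' gradient harmonics are chosen to give flows, stroke volume and
#' pressure-gradient amplitudes in the range reported for healthy adults
#' (tCBF ~ 750 ml/min, jugular fraction ~ 75 %, CSF stroke volume ~ 0.5 ml,
#' PTP-PG ~ 0.04 mmHg/cm); the measured venous sum is ~ 85 % of arterial
#' inflow so the steady-state venous correction is exercised.
#'
#' @param noise_sd Phase-noise SD (radians) for both series.
#' @param n_phases Cardiac phases per cycle.
#' @param cycle_duration Cardiac period (s).
#' @param pixel_size Pixel edge length (cm).
#' @param dim Grid size.
#' @return List with `vessels`, `params_high`, `params_low`, `dim` and
#'   `seeds` (per-lumen seed pixels at the vessel centres).
#' @export
default_subject_phantom <- function(noise_sd = 0, n_phases = 32L,
                                    cycle_duration = 1.0, pixel_size = 0.02,
                                    dim = c(192L, 192L)) {
  pa <- pixel_size^2
  params_high <- acquisition_params(venc = 80, n_phases = n_phases,
                                    pixel_area = pa,
                                    cycle_duration = cycle_duration,
                                    noise_sd = noise_sd)
  params_low <- acquisition_params(venc = 8, n_phases = n_phases,
                                   pixel_area = pa,
                                   cycle_duration = cycle_duration,
                                   noise_sd = noise_sd)
  ica <- function(label, center)
    vessel_spec(label, center, radius = 0.25, direction = 1,
                pg_harmonics = c(130, 70 * exp(-0.5i), 25 * exp(-1.2i),
                                 8 * exp(-2.0i)))
  va <- function(label, center)
    vessel_spec(label, center, radius = 0.15, direction = 1,
                pg_harmonics = c(241, 120 * exp(-0.5i), 40 * exp(-1.2i)))
  jug <- function(label, center)
    vessel_spec(label, center, radius = 0.40, direction = -1,
                pg_harmonics = c(19.1, 5.5 * exp(-0.9i), 1.8 * exp(-1.5i)))
  sec <- function(label, center)
    vessel_spec(label, center, radius = 0.15, direction = -1,
                pg_harmonics = c(40, 8 * exp(-0.7i)))
  csf <- vessel_spec("CSF", c(96, 96), radius = 0.35, direction = -1,
                     pg_harmonics = c(0, 29.3 * exp(0.178i), 6 * exp(-2.2i)))
  vessels <- list(ica("RICA", c(50, 50)), ica("LICA", c(50, 140)),
                  va("RVA", c(100, 40)), va("LVA", c(100, 150)),
                  jug("RIJV", c(150, 60)), jug("LIJV", c(150, 130)),
                  sec("VV", c(50, 50)), sec("EV", c(50, 140)),
                  sec("DCV", c(140, 50)), csf)
  seeds <- lapply(vessels, function(v) round(v$center))
  names(seeds) <- vapply(vessels, `[[`, "", "label")
  list(vessels = vessels, params_high = params_high, params_low = params_low,
       dim = dim, seeds = seeds)
}

#' Analytic ground-truth subject record of a phantom
#'
#' Evaluates the analytic flow and pressure-gradient waveforms of every lumen
#' on a fine time grid and derives the same quantities the pipeline measures:
#' drainage summary, CSF stroke volume, venous correction factor, ICVC,
#' PTP-PG, compliance index and MRICP. This is the oracle end-to-end runs are
#' compared against.
#'
#' @param phantom A phantom description as from [default_subject_phantom()].
#' @param calibration A [calibration_config()].
#' @param n_fine Number of fine time samples per cycle.
#' @return One-row data frame of ground-truth subject quantities.
#' @export
truth_hydro <- function(phantom, calibration = calibration_config(),
                        n_fine = 4096L) {
  vessels <- phantom$vessels
  names(vessels) <- vapply(vessels, `[[`, "", "label")
  Tc <- phantom$params_high$cycle_duration
  t <- (seq_len(n_fine) - 1L) * Tc / n_fine
  dt <- Tc / n_fine
  # outflow/inflow-positive analytic waveforms (ml/min)
  q_of <- function(label) {
    v <- vessels[[label]]
    womersley_flow_waveform(v, vessel_fluid(label), phantom$params_high,
                            t = t, signed = FALSE)
  }
  A <- Reduce(`+`, lapply(ARTERY_LABELS, q_of))
  Vmeas <- Reduce(`+`, lapply(c(JUGULAR_LABELS, SECONDARY_LABELS), q_of))
  csf <- q_of("CSF")                                  # caudal-positive
  tcbf <- mean(A)
  tjvf <- mean(Reduce(`+`, lapply(JUGULAR_LABELS, q_of)))
  sec_means <- vapply(SECONDARY_LABELS, function(l) mean(q_of(l)), 0)
  scale <- tcbf / mean(Vmeas)
  n_rate <- (A - Vmeas * scale - csf) / 60
  n_rate <- n_rate - mean(n_rate)
  dv <- c(0, cumsum((n_rate[-n_fine] + n_rate[-1L]) / 2 * dt))
  csf0 <- csf / 60 - mean(csf) / 60
  sv <- sum(pmax(csf0, 0)) * dt
  pg <- analytic_pressure_gradient(vessels[["CSF"]], phantom$params_low, t = t)
  ptp <- max(pg) - min(pg)
  icvc <- max(dv) - min(dv)
  ci <- icvc / (ptp * calibration$d)
  data.frame(tcbf = tcbf, tjvf = tjvf, jvf_pct = 100 * tjvf / tcbf,
             dcv_pct = 100 * sec_means[["DCV"]] / tcbf,
             vv_pct = 100 * sec_means[["VV"]] / tcbf,
             ev_pct = 100 * sec_means[["EV"]] / tcbf,
             svf_total_pct = 100 * sum(sec_means) / tcbf,
             csf_sv = sv, ptp_pg = ptp, icvc = icvc, venous_scale = scale,
             compliance_index = ci,
             mricp = calibration$a / ci + calibration$b)
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[subject %s | stage %s] %s", subject_id, stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full per-subject analysis
#'
#' Executes segment -> quantify -> venous correction -> ICVC -> pressure
#' gradient -> compliance/MRICP on a subject given either a phantom
#' description (generated in memory) or paths to the two cine NIfTI series
#' with JSON sidecars. One seed pixel per lumen drives the pulsatility-based
#' segmentation; the CSF channel is segmented with `polarity = TRUE` since its
#' flow direction alternates. Venous waveforms are converted to
#' outflow-positive and CSF to caudal-positive assuming the through-plane axis
#' is positive toward the cranium.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `subject_id`; either `phantom` (as from [default_subject_phantom()],
#'   plus optional `phantom_seed`) or `files` (named paths `high`, `low` and
#'   optionally `high_sidecar`, `low_sidecar`); `seeds` (named list of
#'   `c(row, col)` per lumen label); optional `pubs` ([pubs_config()]),
#'   `calibration` ([calibration_config()]), `outdir`.
#' @return List of class `subject_run`: `record` (one-row data frame),
#'   `drainage`, `hydro`, `waveforms`, `masks`, `provenance`.
#' @export
run_subject <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  sid <- config$subject_id %||% "subject"
  pubs <- config$pubs %||% pubs_config()
  cal <- config$calibration %||% calibration_config()

  acq <- with_stage("acquire", sid, {
    if (!is.null(config$phantom)) {
      ph <- config$phantom
      gen <- generate_cine(ph$vessels, ph$params_high, ph$params_low,
                           dim = ph$dim, seed = config$phantom_seed %||% 1L)
      list(high = gen$high, low = gen$low)
    } else if (!is.null(config$files)) {
      for (f in unlist(config$files))
        if (!file.exists(f))
          stop(sprintf("configuration error: file not found: %s", f))
      list(high = read_cine_nifti(config$files$high,
                                  config$files$high_sidecar %||% NULL),
           low = read_cine_nifti(config$files$low,
                                 config$files$low_sidecar %||% NULL))
    } else stop("configuration error: neither 'phantom' nor 'files' given")
  })

  seeds <- config$seeds
  if (is.null(seeds) && !is.null(config$phantom))
    seeds <- config$phantom$seeds
  if (is.null(seeds)) stop("configuration error: no seed pixels given")
  seeds <- lapply(seeds, function(s) as.numeric(unlist(s)))  # YAML-safe

  masks <- with_stage("segment", sid, {
    out <- list()
    for (label in names(seeds)) {
      cine <- acq[[vessel_series(label)]]
      cfg <- if (label == "CSF")
        pubs_config(pubs$correlation_threshold, pubs$min_region_px,
                    polarity = TRUE)
      else pubs
      ref <- build_reference_waveform(cine, seeds[[label]])
      out[[label]] <- segment_lumen(cine, ref, seeds[[label]], cfg,
                                    label = label)
    }
    out
  })

  waveforms <- with_stage("quantify", sid, {
    out <- list()
    for (label in names(masks)) {
      cine <- acq[[vessel_series(label)]]
      fw <- integrate_flow(cine, masks[[label]])
      # axis is positive toward the cranium: flip veins to outflow-positive
      # and CSF to caudal-positive
      if (!label %in% ARTERY_LABELS) fw$q <- -fw$q
      if (label %in% c(JUGULAR_LABELS, SECONDARY_LABELS) && mean(fw$q) < 0)
        fw$q <- -fw$q                      # operator flipped the axis
      out[[label]] <- fw
    }
    out
  })

  drainage <- with_stage("drainage", sid, drainage_profile(waveforms))

  hydro <- with_stage("hydro", sid, {
    Tc <- waveforms[[1L]]$cycle_duration
    np <- length(waveforms[[1L]]$q)
    sum_fw <- function(labels, name) {
      qs <- lapply(labels[labels %in% names(waveforms)],
                   function(l) waveforms[[l]]$q)
      flow_waveform(name, if (length(qs)) Reduce(`+`, qs) else rep(0, np), Tc)
    }
    A <- sum_fw(ARTERY_LABELS, "arterial")
    V <- sum_fw(c(JUGULAR_LABELS, SECONDARY_LABELS), "venous")
    corr <- correct_venous_outflow(A, V)
    csf_fw <- waveforms[["CSF"]]
    icv <- icvc_waveform(A, corr$waveform, csf_fw)
    pg <- csf_pressure_gradient(acq$low, masks[["CSF"]])
    res <- compliance_and_mricp(icv, pg, cal, venous_scale = corr$venous_scale)
    sv <- if (!is.null(csf_fw)) csf_stroke_volume(csf_fw) else NA_real_
    list(result = res, icv = icv, pg = pg, csf_sv = sv)
  })

  record <- data.frame(subject_id = sid, tcbf = drainage$tcbf,
                       jvf = drainage$tjvf, jvf_pct = drainage$jvf_pct,
                       dcv_pct = drainage$dcv_pct, vv_pct = drainage$vv_pct,
                       ev_pct = drainage$ev_pct,
                       svf_total_pct = drainage$svf_pct,
                       csf_sv = hydro$csf_sv, ptp_pg = hydro$result$ptp_pg,
                       icvc = hydro$result$icvc,
                       compliance_index = hydro$result$compliance_index,
                       mricp = hydro$result$mricp,
                       venous_scale = hydro$result$venous_scale,
                       stringsAsFactors = FALSE)

  provenance <- list(subject_id = sid, package = "cranioflow",
                     version = as.character(utils::packageVersion("cranioflow")),
                     r_version = R.version.string,
                     phantom_seed = config$phantom_seed %||% NA,
                     calibration = unclass(cal), pubs = unclass(pubs),
                     seeds = seeds,
                     timestamp = NA)   # deterministic outputs: no wall clock
  out <- structure(list(record = record, drainage = drainage, hydro = hydro,
                        waveforms = waveforms, masks = masks,
                        provenance = provenance),
                   class = "subject_run")
  if (!is.null(config$outdir))
    with_stage("export", sid, export_subject_run(out, config$outdir))
  out
}

export_subject_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sid <- run$record$subject_id
  # tidy waveforms
  wf <- do.call(rbind, lapply(names(run$waveforms), function(l) {
    f <- run$waveforms[[l]]
    np <- length(f$q)
    data.frame(subject = sid, label = l, phase_index = seq_len(np),
               time_s = (seq_len(np) - 1L) * f$cycle_duration / np,
               q_ml_per_min = f$q, stringsAsFactors = FALSE)
  }))
  utils::write.csv(wf, file.path(outdir, sprintf("%s_waveforms.csv", sid)),
                   row.names = FALSE)
  dr <- run$drainage
  utils::write.csv(data.frame(subject = sid, TCBF = dr$tcbf, JVF = dr$tjvf,
                              JVF_pct = round(dr$jvf_pct, 1),
                              DCV_pct = round(dr$dcv_pct, 1),
                              VV_pct = round(dr$vv_pct, 1),
                              EV_pct = round(dr$ev_pct, 1),
                              SVF_total_pct = round(dr$svf_pct, 1)),
                   file.path(outdir, sprintf("%s_drainage.csv", sid)),
                   row.names = FALSE)
  hr <- run$hydro$result
  cal <- hr$calibration
  hydro_path <- file.path(outdir, sprintf("%s_hydro.csv", sid))
  header <- sprintf("# calibration: d=%g cm, a=%g, b=%g", cal$d, cal$a, cal$b)
  writeLines(c(header, paste(
    c("subject", "CSF_SV_ml", "PTP_PG_mmHg_per_cm", "ICVC_ml", "MRICP_mmHg",
      "compliance_index", "venous_scale"), collapse = ",")), hydro_path)
  cat(sprintf("%s,%.4f,%.6f,%.4f,%.1f,%.4f,%.4f\n", sid, run$hydro$csf_sv,
              hr$ptp_pg, hr$icvc, hr$mricp, hr$compliance_index,
              hr$venous_scale),
      file = hydro_path, append = TRUE)
  write_mask_nifti(run$masks, file.path(outdir, sprintf("%s_masks.nii.gz", sid)))
  prov_path <- file.path(outdir, sprintf("%s_provenance.json", sid))
  jsonlite::write_json(run$provenance, prov_path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  prov <- jsonlite::read_json(prov_path)
  prov$config_md5 <- unname(tools::md5sum(prov_path))
  jsonlite::write_json(prov, prov_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(outdir)
}
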