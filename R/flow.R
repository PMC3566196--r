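# Flow quantification: mask + cine -> volumetric flow waveforms, drainage
# summary quantities and the craniospinal CSF stroke volume.

#' One cardiac cycle of volumetric flow rate for a labelled lumen
#'
#' @param label Anatomical class.
#' @param q Flow-rate samples (ml/min), one per cardiac phase. Sign follows
#'   the caller's convention (the pipeline stores arterial inflow and venous
#'   outflow as positive).
#' @param cycle_duration Cardiac period (s).
#' @return An object of class `flow_waveform`.
#' @export
flow_waveform <- function(label, q, cycle_duration) {
  if (any(!is.finite(q))) stop("flow waveform must be finite")
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  structure(list(label = label, q = as.numeric(q),
                 cycle_duration = cycle_duration),
            class = "flow_waveform")
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("flow waveform '%s': %d phases, cycle mean %.1f ml/min\n",
              x$label, length(x$q), mean(x$q)))
  invisible(x)
}

#' Integrate velocities over a lumen mask into a flow waveform
#'
#' For each of the cardiac phases, sums velocity times pixel area over the
#' mask and converts to ml/min.
#'
#' @param cine A `velocity_cine`.
#' @param mask A [lumen_mask] drawn on this cine's grid.
#' @return A [flow_waveform] (sign as measured on the through-plane axis).
#' @export
integrate_flow <- function(cine, mask) {
  stopifnot(inherits(cine, "velocity_cine"), inherits(mask, "lumen_mask"))
  d <- dim(cine$velocity)
  if (!all(mask$dim == d[2:3]))
    stop("bounds error: mask grid does not match the cine")
  if (any(mask$pixels[, 1L] > d[2L]) || any(mask$pixels[, 2L] > d[3L]))
    stop("bounds error: mask outside image")
  idx <- mask$pixels[, 1L] + (mask$pixels[, 2L] - 1L) * d[2L]
  V <- matrix(aperm(cine$velocity, c(2L, 3L, 1L)), nrow = d[2L] * d[3L])
  q <- colSums(V[idx, , drop = FALSE]) * cine$params$pixel_area * 60
  flow_waveform(mask$label, q, cine$params$cycle_duration)
}

#' Cerebral drainage summary from labelled flow waveforms
#'
#' Total cerebral blood flow (tCBF) is the sum of the cycle-mean flows of the
#' four cervical arteries; total jugular venous flow (tJVF) the sum of both
#' internal jugular veins; secondary venous flow the sum of the vertebral,
#' epidural and deep cervical veins. Venous channels are expressed as
#' percentages of tCBF; absent channels count as zero flow. Venous waveforms
#' must be supplied outflow-positive.
#'
#' @param waveforms Named list of [flow_waveform] objects (names are labels).
#' @return An object of class `drainage_profile` with unrounded fields `tcbf`,
#'   `tjvf`, `jvf_pct`, `dcv_pct`, `vv_pct`, `ev_pct`, `svf_pct` (percentages
#'   are reported to one decimal by `format`/`print`).
#' @export
drainage_profile <- function(waveforms) {
  labs <- names(waveforms)
  if (!all(ARTERY_LABELS %in% labs))
    stop("all four arteries (RICA, LICA, RVA, LVA) are required")
  cmean <- function(lab) if (lab %in% labs) mean(waveforms[[lab]]$q) else 0
  tcbf <- sum(vapply(ARTERY_LABELS, cmean, 0))
  if (tcbf <= 0) stop("degenerate input: tCBF must be positive")
  tjvf <- sum(vapply(JUGULAR_LABELS, cmean, 0))
  pct <- function(x) 100 * x / tcbf
  dcv <- pct(cmean("DCV")); vv <- pct(cmean("VV")); ev <- pct(cmean("EV"))
  structure(list(tcbf = tcbf, tjvf = tjvf, jvf_pct = pct(tjvf),
                 dcv_pct = dcv, vv_pct = vv, ev_pct = ev,
                 svf_pct = dcv + vv + ev),
            class = "drainage_profile")
}

#' @export
print.drainage_profile <- function(x, ...) {
  cat(sprintf(paste0("tCBF %.0f ml/min; tJVF %.0f ml/min (%.1f%%); secondary ",
                     "DCV %.1f%% VV %.1f%% EV %.1f%% (total %.1f%%)\n"),
              x$tcbf, x$tjvf, round(x$jvf_pct, 1), round(x$dcv_pct, 1),
              round(x$vv_pct, 1), round(x$ev_pct, 1), round(x$svf_pct, 1)))
  invisible(x)
}

#' Craniospinal CSF stroke volume
#'
#' Volume of CSF displaced in one direction between cranium and spinal canal
#' per cardiac cycle: the time integral of the positive lobe of the
#' mean-subtracted CSF flow waveform (the oscillatory component of the
#' back-and-forth motion). Set `oscillatory = FALSE` to integrate the positive
#' lobe of the raw waveform instead.
#'
#' @param csf A [flow_waveform] of the CSF channel.
#' @param oscillatory Subtract the cycle mean before integrating (default).
#' @return Stroke volume (ml).
#' @export
csf_stroke_volume <- function(csf, oscillatory = TRUE) {
  stopifnot(inherits(csf, "flow_waveform"))
  q <- csf$q / 60                                   # ml/min -> ml/s
  if (oscillatory) q <- q - mean(q)
  dt <- csf$cycle_duration / length(q)
  # periodic trapezoid on a uniform grid reduces to dt * sum
  sum(pmax(q, 0)) * dt
}
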