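# Craniospinal hydrodynamics: the intracranial volume-change waveform from the
# transcranial flow balance, the CSF pressure gradient from the axial momentum
# (Navier-Stokes) balance, and the compliance index / MR-based ICP estimate.

#' Scale measured venous outflow to balance arterial inflow
#'
#' In steady state the intracranial volume is on average constant over a
#' cardiac cycle, so cycle-mean venous outflow must equal cycle-mean arterial
#' inflow. The measured venous sum underestimates total outflow because some
#' channels are not measured; it is multiplied by
#' `mean(arterial) / mean(venous)`, modelling the unmeasured channels as
#' proportional parallel pathways. Set `mode = "additive"` to add a constant
#' offset instead.
#'
#' @param arterial [flow_waveform] of total arterial inflow (positive).
#' @param venous [flow_waveform] of total measured venous outflow (positive).
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return List with `waveform` (corrected venous [flow_waveform]) and
#'   `venous_scale` (the Eq.-2 correction factor; for additive mode the offset
#'   in ml/min).
#' @export
correct_venous_outflow <- function(arterial, venous,
                                   mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(arterial, "flow_waveform"), inherits(venous, "flow_waveform"))
  check_aligned(arterial, venous)
  ma <- mean(arterial$q); mv <- mean(venous$q)
  if (mv <= 0) stop("degenerate input: mean venous outflow must be positive")
  if (mode == "multiplicative") {
    scale <- ma / mv
    q <- venous$q * scale
  } else {
    scale <- ma - mv
    q <- venous$q + scale
  }
  list(waveform = flow_waveform(venous$label, q, venous$cycle_duration),
       venous_scale = scale)
}

check_aligned <- function(...) {
  fws <- list(...)
  n <- vapply(fws, function(f) length(f$q), 0L)
  tt <- vapply(fws, `[[`, 0, "cycle_duration")
  if (length(unique(n)) != 1L || diff(range(tt)) > 1e-12)
    stop("alignment error: waveforms are not on the same phase grid")
}

#' Intracranial volume-change waveform (ICVC)
#'
#' The net transcranial rate is arterial inflow minus corrected venous outflow
#' minus craniospinal CSF flow (CSF positive when leaving the cranium toward
#' the spine). Its cumulative periodic integral gives the momentary change in
#' intracranial volume relative to cycle start; ICVC is the peak-to-peak
#' excursion. The steady-state constraint (zero net volume gain per cycle) is
#' enforced by removing the residual cycle mean of the net rate - after venous
#' correction this residual is the (physiologically negligible) net CSF mean.
#'
#' @param arterial,venous,csf [flow_waveform]s on a common phase grid
#'   (venous already corrected; csf may be `NULL`).
#' @param enforce_closure Remove the residual cycle mean of the net rate
#'   (default `TRUE`).
#' @return Object of class `icvc_waveform`: `t` (s), `dv` (ml, `dv[1] = 0`),
#'   `icvc` (ml), `closure` (ml, volume offset after one full cycle).
#' @export
icvc_waveform <- function(arterial, venous, csf = NULL,
                          enforce_closure = TRUE) {
  stopifnot(inherits(arterial, "flow_waveform"), inherits(venous, "flow_waveform"))
  if (is.null(csf))
    csf <- flow_waveform("CSF", rep(0, length(arterial$q)),
                         arterial$cycle_duration)
  check_aligned(arterial, venous, csf)
  n <- (arterial$q - venous$q - csf$q) / 60          # ml/s
  if (enforce_closure) n <- n - mean(n)
  np <- length(n)
  dt <- arterial$cycle_duration / np
  dv <- c(0, cumsum((n[-np] + n[-1L]) / 2 * dt))
  closure <- dv[np] + (n[np] + n[1L]) / 2 * dt
  structure(list(t = (seq_len(np) - 1L) * dt, dv = dv,
                 icvc = max(dv) - min(dv), closure = closure),
            class = "icvc_waveform")
}

#' CSF pressure-gradient waveform from the axial momentum balance
#'
#' For every interior pixel of the CSF lumen (all four neighbours inside the
#' mask) the axial Navier-Stokes momentum balance is evaluated per phase:
#' the driving gradient -dp/dz = rho dv/dt - mu lap(v), with a 5-point
#' Laplacian on the pixel grid and centred cyclic temporal differences. The
#' per-phase gradient is aggregated over interior pixels by the median
#' (robust against rim partial-volume pixels) and converted to mmHg/cm.
#'
#' @param cine A `velocity_cine` (velocities unwrapped).
#' @param mask [lumen_mask] of the CSF channel.
#' @param fluid A [fluid_props()]; CSF by default.
#' @param aggregate `"median"` (default) or `"mean"` over interior pixels.
#' @return Object of class `pg_waveform`: `t` (s), `pg` (mmHg/cm),
#'   `ptp_pg` (mmHg/cm) and `n_interior`.
#' @export
csf_pressure_gradient <- function(cine, mask, fluid = fluid_props("csf"),
                                  aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(cine, "velocity_cine"), inherits(mask, "lumen_mask"))
  d <- dim(cine$velocity)
  if (!all(mask$dim == d[2:3]))
    stop("bounds error: mask grid does not match the cine")
  inmask <- matrix(FALSE, d[2L], d[3L])
  inmask[mask$pixels] <- TRUE
  px <- mask$pixels
  interior <- px[, 1L] > 1L & px[, 1L] < d[2L] & px[, 2L] > 1L & px[, 2L] < d[3L]
  if (any(interior)) {
    p <- px[interior, , drop = FALSE]
    interior[interior] <- inmask[cbind(p[, 1L] - 1L, p[, 2L])] &
      inmask[cbind(p[, 1L] + 1L, p[, 2L])] &
      inmask[cbind(p[, 1L], p[, 2L] - 1L)] &
      inmask[cbind(p[, 1L], p[, 2L] + 1L)]
  }
  if (!any(interior))
    stop("geometry too thin: no interior pixel with a full finite-difference neighbourhood")
  p <- px[interior, , drop = FALSE]
  h2 <- cine$params$pixel_area                       # h^2 for square pixels
  np <- d[1L]
  dt <- cine$params$cycle_duration / np
  at <- function(k, dr, dc) cine$velocity[cbind(k, p[, 1L] + dr, p[, 2L] + dc)]
  pg <- numeric(np)
  for (k in seq_len(np)) {
    kk <- rep(k, nrow(p))
    lap <- (at(kk, -1L, 0L) + at(kk, 1L, 0L) + at(kk, 0L, -1L) +
              at(kk, 0L, 1L) - 4 * at(kk, 0L, 0L)) / h2
    kp <- if (k == np) 1L else k + 1L
    km <- if (k == 1L) np else k - 1L
    dvdt <- (at(rep(kp, nrow(p)), 0L, 0L) - at(rep(km, nrow(p)), 0L, 0L)) /
      (2 * dt)
    g <- fluid$density * dvdt - fluid$viscosity * lap      # dyn/cm^3
    pg[k] <- if (aggregate == "median") stats::median(g) else mean(g)
  }
  pg <- pg / MMHG_DYN_CM2
  structure(list(t = (seq_len(np) - 1L) * dt, pg = pg,
                 ptp_pg = max(pg) - min(pg), n_interior = nrow(p),
                 aggregate = aggregate),
            class = "pg_waveform")
}

#' Compliance index and MR estimate of intracranial pressure
#'
#' The intracranial compliance index is the ratio of the maximal volume change
#' over the cycle (ICVC) to the pressure fluctuation, taken as PTP-PG times
#' the calibration distance d. MRICP follows the inverse compliance-pressure
#' law MRICP = a / compliance + b, capped (with a warning) as compliance tends
#' to zero.
#'
#' @param icvc An `icvc_waveform` or the ICVC value in ml.
#' @param pg A `pg_waveform` or the PTP-PG value in mmHg/cm.
#' @param cal A [calibration_config()].
#' @param venous_scale Optional Eq.-2 correction factor to record.
#' @return Object of class `hydro_result` with fields `icvc`, `ptp_pg`,
#'   `compliance_index`, `mricp`, `venous_scale`, `calibration`.
#' @export
compliance_and_mricp <- function(icvc, pg, cal = calibration_config(),
                                 venous_scale = NA_real_) {
  stopifnot(inherits(cal, "calibration_config"))
  icvc_val <- if (inherits(icvc, "icvc_waveform")) icvc$icvc else icvc
  ptp <- if (inherits(pg, "pg_waveform")) pg$ptp_pg else pg
  if (!is.finite(ptp) || ptp <= 0)
    stop("undefined compliance: PTP-PG must be positive")
  ci <- icvc_val / (ptp * cal$d)
  mricp <- cal$a / ci + cal$b
  if (!is.finite(mricp) || mricp > cal$mricp_cap) {
    warning(sprintf("MRICP capped at %.0f mmHg (compliance index ~ 0)",
                    cal$mricp_cap))
    mricp <- cal$mricp_cap
  }
  structure(list(icvc = icvc_val, ptp_pg = ptp, compliance_index = ci,
                 mricp = mricp, venous_scale = venous_scale,
                 calibration = cal),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf(paste0("ICVC %.2f ml; PTP-PG %.3f mmHg/cm; compliance index ",
                     "%.2f; MRICP %.1f mmHg (venous scale %.3f)\n"),
              x$icvc, x$ptp_pg, x$compliance_index, x$mricp, x$venous_scale))
  invisible(x)
}
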