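#' Vessel and CSF channel labels
#'
#' Anatomical classes quantified by the pipeline: the four cervical arteries
#' (left/right internal carotid, left/right vertebral), the two internal
#' jugular veins, the three secondary venous channels (vertebral, epidural and
#' deep cervical veins) and the craniospinal CSF space.
#'
#' @format Character vector of the ten recognised labels.
#' @export
VESSEL_LABELS <- c("RICA", "LICA", "RVA", "LVA", "RIJV", "LIJV",
                   "VV", "EV", "DCV", "CSF")

ARTERY_LABELS    <- c("RICA", "LICA", "RVA", "LVA")
JUGULAR_LABELS   <- c("RIJV", "LIJV")
SECONDARY_LABELS <- c("VV", "EV", "DCV")

#' Which cine series (high or low VENC) a labelled lumen is measured on
#'
#' Arteries and jugular veins are segmented on the high-VENC series; the
#' slower secondary veins and the CSF channel on the low-VENC series.
#'
#' @param label One of [VESSEL_LABELS].
#' @return `"high"` or `"low"`.
#' @export
vessel_series <- function(label) {
  label <- match.arg(label, VESSEL_LABELS)
  if (label %in% c(ARTERY_LABELS, JUGULAR_LABELS)) "high" else "low"
}

#' Acquisition parameters of a velocity-encoded cine series
#'
#' @param venc Velocity-encoding limit (cm/s). Velocity maps linearly to image
#'   phase, wrapping beyond +/- venc.
#' @param n_phases Number of cardiac phases per cycle (retrospective gating);
#'   at least 8.
#' @param pixel_area In-plane pixel area (cm^2).
#' @param cycle_duration Cardiac period (s).
#' @param noise_sd Standard deviation of Gaussian noise added in the phase
#'   image (radians).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(venc, n_phases = 32L, pixel_area,
                               cycle_duration = 1.0, noise_sd = 0) {
  if (!is.numeric(venc) || length(venc) != 1L || !is.finite(venc) || venc <= 0)
    stop("invalid acquisition spec: 'venc' must be a positive number")
  n_phases <- as.integer(n_phases)
  if (is.na(n_phases) || n_phases < 8L)
    stop("invalid acquisition spec: 'n_phases' must be >= 8")
  if (!is.numeric(pixel_area) || pixel_area <= 0 || !is.finite(pixel_area))
    stop("invalid acquisition spec: 'pixel_area' must be positive")
  if (!is.numeric(cycle_duration) || cycle_duration <= 0)
    stop("invalid acquisition spec: 'cycle_duration' must be positive")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid acquisition spec: 'noise_sd' must be >= 0")
  structure(list(venc = venc, n_phases = n_phases, pixel_area = pixel_area,
                 cycle_duration = cycle_duration, noise_sd = noise_sd),
            class = "acquisition_params")
}

#' Geometric and dynamic specification of one circular lumen
#'
#' A lumen is modelled as a rigid circular tube carrying fully developed
#' laminar pulsatile flow driven by an axially uniform pressure gradient with
#' a small number of Fourier harmonics.
#'
#' @param label Anatomical class, one of [VESSEL_LABELS].
#' @param center Pixel coordinates `c(row, col)` of the lumen centre.
#' @param radius Lumen radius (cm).
#' @param pg_harmonics Complex vector of driving pressure-gradient amplitudes
#'   (dyn/cm^3). Element 1 is the steady term (harmonic 0), element n+1 the
#'   n-th cardiac harmonic. The driving gradient is -dp/dz, so a positive
#'   steady term produces flow in the + direction.
#' @param direction Flow sign on the through-plane axis: +1 toward the
#'   cranium, -1 away from it.
#' @param waveform Optional explicit velocity waveform (cm/s, one value per
#'   cardiac phase) applied uniformly over the disc instead of the Womersley
#'   profile; used for encoding and segmentation phantoms.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(label, center, radius, pg_harmonics = NULL,
                        direction = 1, waveform = NULL) {
  label <- match.arg(label, VESSEL_LABELS)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("invalid vessel spec: 'radius' must be a positive number")
  if (length(center) != 2L || !all(is.finite(center)))
    stop("invalid vessel spec: 'center' must be c(row, col)")
  if (!direction %in% c(-1, 1))
    stop("invalid vessel spec: 'direction' must be +1 or -1")
  if (is.null(waveform)) {
    if (is.null(pg_harmonics) || length(pg_harmonics) < 1L ||
        any(!is.finite(Re(pg_harmonics))) || any(!is.finite(Im(pg_harmonics))))
      stop("invalid vessel spec: 'pg_harmonics' must be at least one finite value")
    pg_harmonics <- as.complex(pg_harmonics)
  } else {
    if (any(!is.finite(waveform)))
      stop("invalid vessel spec: 'waveform' must be finite")
  }
  structure(list(label = label, center = as.numeric(center), radius = radius,
                 pg_harmonics = pg_harmonics, direction = direction,
                 waveform = waveform),
            class = "vessel_spec")
}

#' Fluid properties in CGS units
#'
#' @param fluid `"blood"` or `"csf"` for the built-in defaults, or omit and
#'   supply `density` and `viscosity` directly.
#' @param density Density rho (g/cm^3).
#' @param viscosity Dynamic viscosity mu (poise).
#' @return An object of class `fluid_props`.
#' @export
fluid_props <- function(fluid = c("blood", "csf"), density = NULL,
                        viscosity = NULL) {
  if (is.null(density) || is.null(viscosity)) {
    fluid <- match.arg(fluid)
    if (fluid == "blood") {
      density <- 1.05; viscosity <- 0.04
    } else {
      density <- 1.0007; viscosity <- 0.01
    }
  }
  if (density <= 0 || viscosity <= 0 || !is.finite(density) ||
      !is.finite(viscosity))
    stop("invalid fluid spec: density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Fluid assigned to each lumen class
#' @param label One of [VESSEL_LABELS].
#' @return A [fluid_props()] object (CSF properties for the CSF channel,
#'   blood otherwise).
#' @export
vessel_fluid <- function(label) {
  if (label == "CSF") fluid_props("csf") else fluid_props("blood")
}

#' Configuration of the pulsatility-based segmentation
#'
#' @param correlation_threshold Minimum Pearson correlation between a pixel's
#'   velocity-time series and the reference waveform for inclusion (pixels at
#'   exactly the threshold are included). The default 0.6 keeps the slow,
#'   phase-shifted boundary layer of high-Womersley-number lumina (whose
#'   velocity waveform genuinely differs in shape from the core) while still
#'   rejecting background at realistic noise levels; see the methods vignette.
#' @param min_region_px Minimum accepted region size in pixels.
#' @param polarity If `TRUE`, anticorrelated pixels (same waveform shape,
#'   opposite flow direction) are also accepted; used for channels on the
#'   low-VENC series where flow direction varies over the cycle.
#' @return An object of class `pubs_config`.
#' @export
pubs_config <- function(correlation_threshold = 0.6, min_region_px = 2L,
                        polarity = FALSE) {
  if (!is.numeric(correlation_threshold) || correlation_threshold <= 0 ||
      correlation_threshold > 1)
    stop("invalid PUBS config: threshold must be in (0, 1]")
  min_region_px <- as.integer(min_region_px)
  if (is.na(min_region_px) || min_region_px < 1L)
    stop("invalid PUBS config: min_region_px must be >= 1")
  structure(list(correlation_threshold = correlation_threshold,
                 min_region_px = min_region_px,
                 polarity = isTRUE(polarity)),
            class = "pubs_config")
}

#' Calibration constants linking volume/pressure-gradient ratios to ICP
#'
#' The compliance index is ICVC / (PTP-PG * d), where d converts the axial
#' pressure gradient amplitude into an effective pressure fluctuation, and the
#' MR estimate of ICP follows the inverse law MRICP = a / compliance + b.
#' The constants are not ground truth: defaults are chosen to be consistent
#' with typical group-mean values of the compliance index and MRICP in adults
#' (see the methods vignette).
#'
#' @param d Effective gradient-to-pressure distance (cm).
#' @param a Inverse-law coefficient (mmHg * index units).
#' @param b ICP offset (mmHg).
#' @param mricp_cap Upper guard for MRICP as compliance tends to zero (mmHg).
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(d = 1.8, a = 73, b = 0, mricp_cap = 1000) {
  if (d <= 0 || a <= 0) stop("invalid calibration: 'd' and 'a' must be > 0")
  structure(list(d = d, a = a, b = b, mricp_cap = mricp_cap),
            class = "calibration_config")
}
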