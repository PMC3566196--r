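# Analytic rigid-tube pulsatile (Womersley) flow: the exact solution used as
# ground truth by the phantom generator and as the oracle for the
# pressure-gradient inversion.

# Bessel functions J0/J1 for complex argument by power series. Base R's
# besselJ is real-only; for |z| <= ~15 (Womersley number alpha <= ~10) the
# series is accurate to ~1e-10 relative.
bessel_j_complex <- function(z, nu = 0L, terms = 80L) {
  stopifnot(nu %in% c(0L, 1L))
  z <- as.complex(z)
  q <- -(z * z) / 4
  term <- if (nu == 0L) rep(1 + 0i, length(z)) else z / 2
  total <- term
  for (k in seq_len(terms)) {
    term <- term * q / (k * (k + nu))
    total <- total + term
  }
  total
}

# exp(i * 3*pi/4): the standard Womersley argument rotation
I_THREE_HALVES <- complex(modulus = 1, argument = 3 * pi / 4)

womersley_alpha <- function(radius, omega, fluid) {
  radius * sqrt(omega * fluid$density / fluid$viscosity)
}

# Complex radial velocity profile of harmonic n (omega > 0) for a unit driving
# gradient G = -dp/dz (dyn/cm^3): u_hat(r) = (G/(i rho omega)) *
# (1 - J0(zeta r/R) / J0(zeta R)), zeta R = i^{3/2} alpha. Zero-frequency
# (steady) flow is the Poiseuille parabola G (R^2 - r^2) / (4 mu).
womersley_profile_complex <- function(G, r, radius, omega, fluid) {
  alpha <- womersley_alpha(radius, omega, fluid)
  zeta <- I_THREE_HALVES * alpha
  (G / (1i * fluid$density * omega)) *
    (1 - bessel_j_complex(zeta * r / radius, 0L) / bessel_j_complex(zeta, 0L))
}

# Complex cross-sectional flow amplitude (cm^3/s) for harmonic n:
# Q_hat = (G pi R^2 / (i rho omega)) (1 - 2 J1(zeta) / (zeta J0(zeta)))
womersley_flow_complex <- function(G, radius, omega, fluid) {
  alpha <- womersley_alpha(radius, omega, fluid)
  zeta <- I_THREE_HALVES * alpha
  (G * pi * radius^2 / (1i * fluid$density * omega)) *
    (1 - 2 * bessel_j_complex(zeta, 1L) / (zeta * bessel_j_complex(zeta, 0L)))
}

#' Womersley velocity field of a pulsatile lumen
#'
#' Evaluates the exact oscillatory laminar solution for a rigid circular tube
#' driven by the vessel's pressure-gradient harmonics: the steady term gives
#' the Poiseuille parabola and each cardiac harmonic the Bessel-function
#' Womersley profile, with no-slip (zero velocity) at the wall.
#'
#' @param spec A [vessel_spec()] (its `waveform` field, if any, is ignored:
#'   this is the analytic route).
#' @param fluid A [fluid_props()].
#' @param params An [acquisition_params()] providing the cardiac period and
#'   the number of phases at which the cycle is sampled.
#' @param r Radial positions (cm) at which to evaluate; defaults to 101 points
#'   spanning the lumen.
#' @return A list with `t` (phase times, s), `r`, `v` (matrix, phases x radii,
#'   cm/s, including the flow-direction sign) and `alpha` (Womersley numbers
#'   per harmonic).
#' @export
womersley_velocity_profile <- function(spec, fluid, params, r = NULL) {
  stopifnot(inherits(spec, "vessel_spec"), inherits(fluid, "fluid_props"),
            inherits(params, "acquisition_params"))
  if (is.null(r)) r <- seq(0, spec$radius, length.out = 101L)
  if (any(r < 0 | r > spec$radius + 1e-12))
    stop("radial positions must lie within the lumen")
  G <- spec$pg_harmonics
  t <- (seq_len(params$n_phases) - 1L) * params$cycle_duration / params$n_phases
  v <- matrix(0, nrow = params$n_phases, ncol = length(r))
  # steady (Poiseuille) term
  v <- v + matrix(rep(Re(G[1L]) * (spec$radius^2 - r^2) / (4 * fluid$viscosity),
                      each = params$n_phases),
                  nrow = params$n_phases)
  alphas <- numeric(0)
  if (length(G) > 1L) {
    for (n in seq_len(length(G) - 1L)) {
      omega <- 2 * pi * n / params$cycle_duration
      alphas <- c(alphas, womersley_alpha(spec$radius, omega, fluid))
      if (G[n + 1L] == 0) next
      prof <- womersley_profile_complex(G[n + 1L], r, spec$radius, omega, fluid)
      v <- v + Re(exp(1i * omega * t) %o% prof)
    }
  }
  list(t = t, r = r, v = v * spec$direction, alpha = alphas)
}

#' Analytic volumetric flow waveform of a Womersley lumen
#'
#' Cross-section integral of the exact velocity field; the cycle mean equals
#' the Poiseuille flow of the steady harmonic alone (oscillatory harmonics
#' integrate to zero over a full cycle).
#'
#' @inheritParams womersley_velocity_profile
#' @param t Times (s) at which to sample; defaults to the cine phase grid.
#' @param signed If `TRUE` (default) the vessel's direction sign is applied,
#'   giving the flow as measured on the through-plane axis.
#' @return Flow-rate samples in ml/min.
#' @export
womersley_flow_waveform <- function(spec, fluid, params, t = NULL,
                                    signed = TRUE) {
  stopifnot(inherits(spec, "vessel_spec"))
  if (is.null(t))
    t <- (seq_len(params$n_phases) - 1L) * params$cycle_duration / params$n_phases
  G <- spec$pg_harmonics
  q <- rep(Re(G[1L]) * pi * spec$radius^4 / (8 * fluid$viscosity), length(t))
  if (length(G) > 1L) {
    for (n in seq_len(length(G) - 1L)) {
      if (G[n + 1L] == 0) next
      omega <- 2 * pi * n / params$cycle_duration
      qhat <- womersley_flow_complex(G[n + 1L], spec$radius, omega, fluid)
      q <- q + Re(qhat * exp(1i * omega * t))
    }
  }
  q <- q * 60                                   # cm^3/s -> ml/min
  if (signed) q * spec$direction else q
}

#' Analytic driving pressure-gradient waveform of a lumen
#'
#' The prescribed -dp/dz waveform (sum of the vessel's harmonics), as it would
#' be recovered from the measured (direction-signed) velocity field.
#'
#' @inheritParams womersley_flow_waveform
#' @param unit `"mmHg_cm"` (default) or `"dyn_cm3"`.
#' @return Pressure-gradient samples.
#' @export
analytic_pressure_gradient <- function(spec, params, t = NULL,
                                       unit = c("mmHg_cm", "dyn_cm3"),
                                       signed = TRUE) {
  unit <- match.arg(unit)
  if (is.null(t))
    t <- (seq_len(params$n_phases) - 1L) * params$cycle_duration / params$n_phases
  G <- spec$pg_harmonics
  g <- rep(Re(G[1L]), length(t))
  if (length(G) > 1L) {
    for (n in seq_len(length(G) - 1L)) {
      omega <- 2 * pi * n / params$cycle_duration
      g <- g + Re(G[n + 1L] * exp(1i * omega * t))
    }
  }
  if (signed) g <- g * spec$direction
  if (unit == "mmHg_cm") g / MMHG_DYN_CM2 else g
}

# 1 mmHg = 1333.22 dyn/cm^2
MMHG_DYN_CM2 <- 1333.22
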