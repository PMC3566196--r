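# Shared builders and independent oracles for the test suite.

# velocity_cine wrapper around a raw (phase x row x col) velocity array
make_cine <- function(velocity, venc = 80, pixel_area = 4e-4,
                      cycle_duration = 1, id = "test") {
  p <- acquisition_params(venc, dim(velocity)[1L], pixel_area,
                          cycle_duration, 0)
  structure(list(velocity = velocity, phase = encode_velocity(velocity, venc),
                 magnitude = NULL, params = p, truth = NULL, id = id),
            class = "velocity_cine")
}

# single-lumen phantom on a small grid
single_vessel_cine <- function(spec, noise_sd = 0, dim = c(48L, 48L),
                               pixel_size = 0.02, seed = 1L,
                               venc_high = 80, venc_low = 8, n_phases = 32L) {
  ph <- acquisition_params(venc_high, n_phases, pixel_size^2, 1, noise_sd)
  pl <- acquisition_params(venc_low, n_phases, pixel_size^2, 1, noise_sd)
  g <- generate_cine(list(spec), ph, pl, dim = dim, seed = seed)
  g$cine <- g[[vessel_series(spec$label)]]
  g
}

# brute-force Mann-Whitney two-sided p by enumeration of all group assignments
mwu_enum_p <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  ustat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- ustat(seq_len(na))
  us <- utils::combn(length(pooled), na, ustat)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# finite-difference boundary-value solve of the radial momentum ODE for one
# oscillatory harmonic: u'' + u'/r - (i rho omega / mu) u = -G/mu, u'(0) = 0,
# u(R) = 0 (Thomas algorithm on a staggered grid)
womersley_fd_oracle <- function(G, R, omega, rho, mu, N = 3000L) {
  h <- R / N
  r <- (seq_len(N) - 0.5) * h
  lower <- 1 / h^2 - 1 / (2 * r * h)
  upper <- 1 / h^2 + 1 / (2 * r * h)
  diagc <- rep(-2 / h^2 - 1i * rho * omega / mu, N)
  diagc[1L] <- diagc[1L] + lower[1L]        # symmetry at the axis
  diagc[N] <- diagc[N] - upper[N]           # wall midway between N and N+1
  rhs <- rep(-G / mu, N)
  cp <- dp <- complex(length.out = N)
  cp[1L] <- upper[1L] / diagc[1L]
  dp[1L] <- rhs[1L] / diagc[1L]
  for (j in 2:N) {
    m <- diagc[j] - lower[j] * cp[j - 1L]
    cp[j] <- upper[j] / m
    dp[j] <- (rhs[j] - lower[j] * dp[j - 1L]) / m
  }
  u <- complex(length.out = N)
  u[N] <- dp[N]
  for (j in (N - 1L):1L) u[j] <- dp[j] - cp[j] * u[j + 1L]
  list(r = r, u = u)
}

# circular ROI of given pixel radius centred on a pixel (manual-delineation
# stand-in used by the reproducibility comparison)
circular_roi_mask <- function(center, radius_px, dim, label = "RICA") {
  grid <- expand.grid(row = seq_len(dim[1L]), col = seq_len(dim[2L]))
  d <- sqrt((grid$row - center[1L])^2 + (grid$col - center[2L])^2)
  lumen_mask(label, as.matrix(grid[d <= radius_px, ]), dim)
}

same_pixel_set <- function(a, b) {
  setequal(paste(a$pixels[, 1L], a$pixels[, 2L]),
           paste(b$pixels[, 1L], b$pixels[, 2L]))
}
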