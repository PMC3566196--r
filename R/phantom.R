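# Synthetic velocity-encoded cine generation: Womersley lumina rendered into
# pixel grids with VENC phase encoding, wrapping and Gaussian phase noise.

#' Encode velocity into image phase
#'
#' Phase is pi * v / venc, wrapped into (-pi, pi] when |v| exceeds the
#' velocity-encoding limit.
#'
#' @param v Velocity (cm/s).
#' @param venc Velocity-encoding limit (cm/s).
#' @return Phase (radians) in (-pi, pi].
#' @export
encode_velocity <- function(v, venc) {
  wrap_phase(pi * v / venc)
}

#' @rdname encode_velocity
#' @param phase Phase (radians).
#' @export
decode_phase <- function(phase, venc) {
  venc * phase / pi
}

wrap_phase <- function(phase) {
  pi - ((pi - phase) %% (2 * pi))
}

#' Undo a single phase wrap in a velocity time series
#'
#' Optional correction for lumina whose peak velocity exceeded the VENC once:
#' each candidate shift of the aliased samples by +/- 2 * venc is tried and the
#' series with the smallest total temporal variation is kept. Off by default
#' in the pipeline, which assumes the operator chose VENC high enough.
#'
#' @param v Decoded velocity time series (cm/s).
#' @param venc Velocity-encoding limit (cm/s).
#' @return Corrected velocity series.
#' @export
correct_single_wrap <- function(v, venc) {
  tv <- function(x) sum(abs(diff(c(x, x[1L]))))
  best <- v; best_tv <- tv(v); best_n <- 0L
  for (shift in c(-2 * venc, 2 * venc)) {
    for (thr in c(0.5, 0) * venc) {
      sel <- if (shift > 0) v < -thr else v > thr
      if (!any(sel)) next
      cand <- v
      cand[sel] <- cand[sel] + shift
      ctv <- tv(cand)
      # require a strict improvement; among equal-TV candidates (shifting a
      # set or its complement is equivalent up to an offset) alter the fewest
      # samples
      if (ctv < best_tv - 1e-9 ||
          (best_n > 0L && ctv < best_tv + 1e-9 && sum(sel) < best_n)) {
        best <- cand; best_tv <- ctv; best_n <- sum(sel)
      }
    }
  }
  best
}

disc_pixels <- function(center, radius_cm, h, dim) {
  rr <- seq_len(dim[1L]); cc <- seq_len(dim[2L])
  rpx <- radius_cm / h
  rows <- rr[abs(rr - center[1L]) <= rpx]
  cols <- cc[abs(cc - center[2L]) <= rpx]
  if (!length(rows) || !length(cols))
    return(list(pixels = matrix(integer(0), 0, 2), r_cm = numeric(0)))
  grid <- expand.grid(row = rows, col = cols)
  d <- h * sqrt((grid$row - center[1L])^2 + (grid$col - center[2L])^2)
  keep <- d <= radius_cm
  list(pixels = as.matrix(grid[keep, , drop = FALSE]), r_cm = d[keep])
}

#' Generate a two-series velocity-encoded cine phantom
#'
#' Renders each lumen's analytic velocity field into a pixel grid (pixel-centre
#' sampling), encodes it as phase at the series' VENC with wrapping, adds
#' Gaussian phase noise, and decodes back to velocity. Arteries and jugular
#' veins are rendered into the high-VENC series, secondary veins and CSF into
#' the low-VENC series. The analytic flow and pressure-gradient waveforms of
#' every lumen are carried along as ground truth.
#'
#' @param vessels List of [vessel_spec()] objects.
#' @param params_high,params_low [acquisition_params()] for the two series.
#' @param dim Image grid size `c(rows, cols)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with elements `high` and `low` (objects of class
#'   `velocity_cine`: `velocity`, `phase`, `magnitude` arrays of shape
#'   phases x rows x cols, plus `params` and per-vessel `truth`), and `masks`,
#'   a named list of true [lumen_mask] objects.
#' @export
generate_cine <- function(vessels, params_high, params_low, dim = c(64L, 64L),
                          seed = 1L) {
  stopifnot(inherits(params_high, "acquisition_params"),
            inherits(params_low, "acquisition_params"))
  if (!length(vessels) || !all(vapply(vessels, inherits, TRUE, "vessel_spec")))
    stop("'vessels' must be a list of vessel_spec objects")
  labels <- vapply(vessels, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate vessel labels")
  names(vessels) <- labels
  series_of <- vapply(labels, vessel_series, "")

  params <- list(high = params_high, low = params_low)
  h <- lapply(params, function(p) sqrt(p$pixel_area))

  # geometry checks: inside grid, no overlap within a series
  for (s in c("high", "low")) {
    vs <- vessels[series_of == s]
    for (v in vs) {
      rpx <- v$radius / h[[s]]
      if (v$center[1L] - rpx < 1 || v$center[1L] + rpx > dim[1L] ||
          v$center[2L] - rpx < 1 || v$center[2L] + rpx > dim[2L])
        stop(sprintf("geometry error: vessel %s extends outside the grid",
                     v$label))
    }
    if (length(vs) > 1L) {
      for (i in seq_len(length(vs) - 1L)) for (j in (i + 1L):length(vs)) {
        d <- h[[s]] * sqrt(sum((vs[[i]]$center - vs[[j]]$center)^2))
        if (d < vs[[i]]$radius + vs[[j]]$radius)
          stop(sprintf("geometry error: vessels %s and %s overlap",
                       vs[[i]]$label, vs[[j]]$label))
      }
    }
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  out <- list()
  masks <- list()
  for (s in c("high", "low")) {
    p <- params[[s]]
    vel <- array(0, dim = c(p$n_phases, dim[1L], dim[2L]))
    mag <- array(100, dim = dim(vel))
    truth <- list()
    for (v in vessels[series_of == s]) {
      dp <- disc_pixels(v$center, v$radius, h[[s]], dim)
      if (nrow(dp$pixels) == 0L)
        stop(sprintf("geometry error: vessel %s covers no pixel centre",
                     v$label))
      fluid <- vessel_fluid(v$label)
      if (!is.null(v$waveform)) {
        if (length(v$waveform) != p$n_phases)
          stop("waveform length must equal n_phases")
        vpx <- (v$waveform * v$direction) %o% rep(1, nrow(dp$pixels))
        q_true <- v$waveform * v$direction * pi * v$radius^2 * 60
        pg_true <- rep(NA_real_, p$n_phases)
      } else {
        prof <- womersley_velocity_profile(v, fluid, p, r = dp$r_cm)
        vpx <- prof$v
        q_true <- womersley_flow_waveform(v, fluid, p)
        pg_true <- analytic_pressure_gradient(v, p)
      }
      for (k in seq_len(nrow(dp$pixels)))
        vel[, dp$pixels[k, 1L], dp$pixels[k, 2L]] <- vpx[, k]
      for (k in seq_len(nrow(dp$pixels)))
        mag[, dp$pixels[k, 1L], dp$pixels[k, 2L]] <- 400
      masks[[v$label]] <- lumen_mask(v$label, dp$pixels, dim,
                                     source_cine = s)
      truth[[v$label]] <- list(label = v$label, q_ml_min = q_true,
                               pg_mmHg_cm = pg_true, radius = v$radius,
                               center = v$center, direction = v$direction)
    }
    phase <- encode_velocity(vel, p$venc)
    if (p$noise_sd > 0)
      phase <- wrap_phase(phase + array(stats::rnorm(length(phase),
                                                     sd = p$noise_sd),
                                        dim = dim(phase)))
    out[[s]] <- structure(list(velocity = decode_phase(phase, p$venc),
                               phase = phase, magnitude = mag, params = p,
                               truth = truth, id = s),
                          class = "velocity_cine")
  }
  list(high = out$high, low = out$low, masks = masks)
}

#' @export
print.velocity_cine <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("velocity cine (%s): %d phases, %d x %d pixels, VENC %.1f cm/s\n",
              x$id %||% "?", d[1L], d[2L], d[3L], x$params$venc))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a velocity cine as NIfTI plus JSON sidecar
#'
#' The velocity array is stored as a rows x cols x 1 x phases NIfTI volume
#' (cardiac phase as the 4th dimension); acquisition parameters go into a JSON
#' sidecar with keys `venc_cm_s`, `n_phases`, `pixel_area_cm2`,
#' `cycle_duration_s`, `noise_sd`.
#'
#' @param cine A `velocity_cine`.
#' @param path Path of the `.nii.gz` file; the sidecar defaults to the same
#'   path with extension `.json`.
#' @param sidecar Optional explicit sidecar path.
#' @return `write_cine_nifti` returns `path` invisibly; `read_cine_nifti`
#'   returns a `velocity_cine`.
#' @export
write_cine_nifti <- function(cine, path, sidecar = NULL) {
  stopifnot(inherits(cine, "velocity_cine"))
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  arr <- aperm(cine$velocity, c(2L, 3L, 1L))
  dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3L])
  RNifti::writeNifti(arr, path)
  p <- cine$params
  jsonlite::write_json(list(venc_cm_s = p$venc, n_phases = p$n_phases,
                            pixel_area_cm2 = p$pixel_area,
                            cycle_duration_s = p$cycle_duration,
                            noise_sd = p$noise_sd),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cine_nifti
#' @export
read_cine_nifti <- function(path, sidecar = NULL) {
  if (!file.exists(path))
    stop(sprintf("configuration error: cine file not found: %s", path))
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop(sprintf("configuration error: sidecar not found: %s", sidecar))
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L) arr <- arr[, , 1L, , drop = TRUE]
  vel <- aperm(arr, c(3L, 1L, 2L))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  p <- acquisition_params(venc = meta$venc_cm_s, n_phases = meta$n_phases,
                          pixel_area = meta$pixel_area_cm2,
                          cycle_duration = meta$cycle_duration_s,
                          noise_sd = meta$noise_sd %||% 0)
  structure(list(velocity = vel, phase = encode_velocity(vel, p$venc),
                 magnitude = NULL, params = p, truth = NULL, id = path),
            class = "velocity_cine")
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write / read labelled lumen masks as integer NIfTI
#'
#' @param masks Named list of [lumen_mask] objects on a common grid.
#' @param path Output `.nii.gz`; the label -> class mapping goes into the JSON
#'   sidecar.
#' @param sidecar Optional explicit sidecar path.
#' @return `write_mask_nifti` returns `path` invisibly; `read_mask_nifti`
#'   returns a named list of [lumen_mask] objects.
#' @export
write_mask_nifti <- function(masks, path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  dims <- masks[[1L]]$dim
  lab <- matrix(0L, dims[1L], dims[2L])
  mapping <- list()
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    lab[m$pixels] <- i
    mapping[[m$label]] <- i
  }
  dim(lab) <- c(dims, 1L)
  RNifti::writeNifti(lab, path)
  jsonlite::write_json(mapping, sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, sidecar = NULL) {
  if (!file.exists(path))
    stop(sprintf("configuration error: mask file not found: %s", path))
  if (is.null(sidecar)) sidecar <- sidecar_path(path)
  lab <- as.array(RNifti::readNifti(path))
  if (length(dim(lab)) == 3L) lab <- lab[, , 1L, drop = TRUE]
  mapping <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  out <- list()
  for (label in names(mapping)) {
    px <- which(lab == mapping[[label]], arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    out[[label]] <- lumen_mask(label, px, dim(lab), source_cine = path)
  }
  out
}
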