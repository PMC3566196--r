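# Pulsatility-based segmentation (PUBS): lumen pixels are identified by the
# similarity of their velocity-time series to a reference waveform taken from
# an operator-supplied seed pixel, exploiting the full cine time series rather
# than a single frame.

#' Labelled pixel set of one lumen
#'
#' @param label Anatomical class, one of [VESSEL_LABELS].
#' @param pixels Two-column integer matrix of (row, col) coordinates.
#' @param dim Grid size `c(rows, cols)` the mask lives on.
#' @param source_cine Identifier of the cine the mask was drawn on.
#' @return An object of class `lumen_mask`.
#' @export
lumen_mask <- function(label, pixels, dim, source_cine = NA_character_) {
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(pixels) == 0L) stop("empty mask")
  if (any(pixels[, 1L] < 1L | pixels[, 1L] > dim[1L] |
          pixels[, 2L] < 1L | pixels[, 2L] > dim[2L]))
    stop("mask pixels outside image bounds")
  structure(list(label = label, pixels = pixels, dim = as.integer(dim),
                 source_cine = source_cine),
            class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("lumen mask '%s': %d pixels on %d x %d grid\n",
              x$label, nrow(x$pixels), x$dim[1L], x$dim[2L]))
  invisible(x)
}

#' Reference waveform from a seed pixel
#'
#' Takes the seed pixel's velocity-time series over the full cardiac cycle,
#' subtracts its mean and scales it to unit Euclidean norm. Amplitude therefore
#' does not matter: two pixels whose series differ only by a scale factor give
#' the same reference.
#'
#' @param cine A `velocity_cine`.
#' @param seed_pixel `c(row, col)` of the seed.
#' @return Zero-mean, unit-norm numeric vector of length `n_phases`.
#' @export
build_reference_waveform <- function(cine, seed_pixel) {
  stopifnot(inherits(cine, "velocity_cine"))
  d <- dim(cine$velocity)
  if (seed_pixel[1L] < 1L || seed_pixel[1L] > d[2L] ||
      seed_pixel[2L] < 1L || seed_pixel[2L] > d[3L])
    stop("seed pixel outside image")
  s <- cine$velocity[, seed_pixel[1L], seed_pixel[2L]]
  s <- s - mean(s)
  nrm <- sqrt(sum(s^2))
  if (nrm == 0) stop("degenerate seed: velocity series has zero variance")
  s / nrm
}

#' Segment one lumen by waveform correlation
#'
#' Computes, for every pixel, the Pearson correlation between its
#' velocity-time series and the reference waveform, thresholds at
#' `correlation_threshold` (pixels exactly at the threshold are included) and
#' returns the 4-connected component containing the seed. Static background
#' pixels have undefined correlation and never pass. With `polarity = TRUE`
#' the absolute correlation is thresholded, admitting pixels of opposite flow
#' direction.
#'
#' @param cine A `velocity_cine`.
#' @param reference Reference waveform from [build_reference_waveform()].
#' @param seed_pixel `c(row, col)` of the seed.
#' @param config A [pubs_config()].
#' @param label Anatomical class recorded on the returned mask.
#' @return A [lumen_mask] with attributes `mean_correlation`, `threshold` and
#'   `n_candidates`.
#' @export
segment_lumen <- function(cine, reference, seed_pixel,
                          config = pubs_config(), label = "CSF") {
  stopifnot(inherits(cine, "velocity_cine"), inherits(config, "pubs_config"))
  d <- dim(cine$velocity)
  nt <- d[1L]
  if (length(reference) != nt) stop("reference length must equal n_phases")
  X <- matrix(aperm(cine$velocity, c(2L, 3L, 1L)), nrow = d[2L] * d[3L],
              ncol = nt)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  refc <- reference - mean(reference)
  refc <- refc / sqrt(sum(refc^2))
  corr <- as.vector(Xc %*% refc) / nrm     # NaN for zero-variance pixels
  score <- if (config$polarity) abs(corr) else corr
  sel <- !is.na(score) & score >= config$correlation_threshold
  selm <- matrix(sel, d[2L], d[3L])
  if (!selm[seed_pixel[1L], seed_pixel[2L]])
    stop("empty segmentation: no pixel (including the seed) passes the threshold")
  comp <- connected_component(selm, seed_pixel)
  if (nrow(comp) < config$min_region_px)
    stop(sprintf("empty segmentation: seed region has %d pixel(s), below min_region_px = %d",
                 nrow(comp), config$min_region_px))
  m <- lumen_mask(label, comp, c(d[2L], d[3L]), source_cine = cine$id)
  attr(m, "mean_correlation") <- mean(matrix(corr, d[2L], d[3L])[comp])
  attr(m, "threshold") <- config$correlation_threshold
  attr(m, "n_candidates") <- sum(sel)
  m
}

# 4-connected component containing the seed, by breadth-first flood fill
connected_component <- function(selm, seed) {
  nr <- nrow(selm); nc <- ncol(selm)
  visited <- matrix(FALSE, nr, nc)
  queue <- matrix(as.integer(seed), 1L, 2L)
  visited[seed[1L], seed[2L]] <- TRUE
  out <- list()
  while (nrow(queue) > 0L) {
    out[[length(out) + 1L]] <- queue
    nxt <- rbind(cbind(queue[, 1L] - 1L, queue[, 2L]),
                 cbind(queue[, 1L] + 1L, queue[, 2L]),
                 cbind(queue[, 1L], queue[, 2L] - 1L),
                 cbind(queue[, 1L], queue[, 2L] + 1L))
    ok <- nxt[, 1L] >= 1L & nxt[, 1L] <= nr & nxt[, 2L] >= 1L & nxt[, 2L] <= nc
    nxt <- nxt[ok, , drop = FALSE]
    nxt <- nxt[selm[nxt] & !visited[nxt], , drop = FALSE]
    nxt <- unique(nxt)
    visited[nxt] <- TRUE
    queue <- nxt
  }
  do.call(rbind, out)
}

#' Dice overlap between two masks
#'
#' @param a,b [lumen_mask] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "lumen_mask"), inherits(b, "lumen_mask"),
            all(a$dim == b$dim))
  ka <- paste(a$pixels[, 1L], a$pixels[, 2L])
  kb <- paste(b$pixels[, 1L], b$pixels[, 2L])
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}
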