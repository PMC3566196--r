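test_that("the reference waveform is the zero-mean unit-norm seed series", {
  t <- (0:31) / 32
  v <- array(0, dim = c(32, 8, 8))
  v[, 3, 3] <- 5 + 2 * sin(2 * pi * t)
  v[, 5, 5] <- 5 + 40 * sin(2 * pi * t)    # same shape, different amplitude
  cine <- make_cine(v)
  ref <- build_reference_waveform(cine, c(3, 3))
  expect_equal(mean(ref), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(ref^2)), 1, tolerance = 1e-12)
  s <- sin(2 * pi * t)
  expect_equal(ref, s / sqrt(sum(s^2)), tolerance = 1e-12)
  # amplitude invariance
  expect_equal(build_reference_waveform(cine, c(5, 5)), ref, tolerance = 1e-12)
  # constant series is a degenerate seed
  expect_error(build_reference_waveform(cine, c(1, 1)), "degenerate seed")
})

test_that("a noiseless uniform-waveform disc is recovered exactly", {
  t <- (0:31) / 32
  spec <- vessel_spec("RICA", c(24, 24), 0.2,
                      waveform = 20 + 15 * sin(2 * pi * t))
  g <- single_vessel_cine(spec)
  ref <- build_reference_waveform(g$cine, c(24, 24))
  m <- segment_lumen(g$cine, ref, c(24, 24), label = "RICA")
  expect_true(same_pixel_set(m, g$masks$RICA))
  expect_equal(dice_coefficient(m, g$masks$RICA), 1)
})

test_that("segmentation returns only the 4-connected component holding the seed", {
  t <- (0:31) / 32
  w <- 10 + 8 * sin(2 * pi * t)
  a <- vessel_spec("RICA", c(14, 14), 0.15, waveform = w)
  b <- vessel_spec("LICA", c(34, 34), 0.15, waveform = w)  # identical waveform
  ph <- acquisition_params(80, 32, 4e-4, 1)
  pl <- acquisition_params(8, 32, 4e-4, 1)
  g <- generate_cine(list(a, b), ph, pl, dim = c(48, 48))
  ref <- build_reference_waveform(g$high, c(14, 14))
  m <- segment_lumen(g$high, ref, c(14, 14), label = "RICA")
  expect_true(same_pixel_set(m, g$masks$RICA))   # disc B excluded
})

test_that("anticorrelated pixels are excluded unless polarity is enabled", {
  t <- (0:31) / 32
  v <- array(0, dim = c(32, 16, 16))
  for (cc in 4:6) v[, 5, cc] <- sin(2 * pi * t)
  for (cc in 7:9) v[, 5, cc] <- -sin(2 * pi * t)   # adjacent, opposite sign
  cine <- make_cine(v)
  ref <- build_reference_waveform(cine, c(5, 4))
  m <- segment_lumen(cine, ref, c(5, 4), pubs_config(0.6), label = "VV")
  expect_equal(nrow(m$pixels), 3L)
  m2 <- segment_lumen(cine, ref, c(5, 4), pubs_config(0.6, polarity = TRUE),
                      label = "VV")
  expect_equal(nrow(m2$pixels), 6L)
})

test_that("raising the correlation threshold never enlarges the mask", {
  spec <- vessel_spec("RICA", c(24, 24), 0.25,
                      pg_harmonics = c(130, 70 * exp(-0.5i), 25 * exp(-1.2i)))
  g <- single_vessel_cine(spec, noise_sd = 0.037, seed = 3L)
  ref <- build_reference_waveform(g$cine, c(24, 24))
  sizes <- c()
  prev <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9, 0.97)) {
    m <- segment_lumen(g$cine, ref, c(24, 24), pubs_config(thr),
                       label = "RICA")
    sizes <- c(sizes, nrow(m$pixels))
    if (!is.null(prev)) {
      keys <- paste(m$pixels[, 1], m$pixels[, 2])
      expect_true(all(keys %in% prev))
    }
    prev <- paste(m$pixels[, 1], m$pixels[, 2])
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("segmentation fails loudly when the seed does not pass", {
  t <- (0:31) / 32
  spec <- vessel_spec("RICA", c(24, 24), 0.2, waveform = 10 * sin(2 * pi * t))
  g <- single_vessel_cine(spec)
  ref <- build_reference_waveform(g$cine, c(24, 24))
  # background pixel has zero variance: correlation undefined, seed fails
  expect_error(segment_lumen(g$cine, ref, c(2, 2), label = "RICA"),
               "empty segmentation")
  # min_region_px larger than the lumen
  expect_error(segment_lumen(g$cine, ref, c(24, 24),
                             pubs_config(0.6, min_region_px = 1e5),
                             label = "RICA"),
               "empty segmentation")
})

test_that("PUBS flow is more reproducible across re-seedings than circular ROIs", {
  spec <- vessel_spec("RICA", c(24, 24), 0.25,
                      pg_harmonics = c(130, 70 * exp(-0.5i), 25 * exp(-1.2i)))
  g <- single_vessel_cine(spec, noise_sd = 0.037, seed = 9L)
  truth_px <- g$masks$RICA$pixels
  # 20 seed pixels inside the core of the lumen
  core <- truth_px[sqrt((truth_px[, 1] - 24)^2 + (truth_px[, 2] - 24)^2) <= 6, ]
  set.seed(1)
  seeds <- core[sample(nrow(core), 20), , drop = FALSE]
  n_px <- nrow(truth_px)
  roi_radius <- sqrt(n_px / pi)            # matched nominal area
  q_pubs <- q_roi <- numeric(20)
  for (i in 1:20) {
    sp <- seeds[i, ]
    ref <- build_reference_waveform(g$cine, sp)
    m <- segment_lumen(g$cine, ref, sp, label = "RICA")
    q_pubs[i] <- mean(integrate_flow(g$cine, m)$q)
    roi <- circular_roi_mask(sp, roi_radius, c(48, 48))
    q_roi[i] <- mean(integrate_flow(g$cine, roi)$q)
  }
  cv <- function(x) sd(x) / abs(mean(x))
  expect_lt(cv(q_pubs), cv(q_roi))
})
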