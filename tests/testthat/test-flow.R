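test_that("a uniform velocity field integrates to velocity x area", {
  # 10 cm/s over 20 pixels of 0.003 cm^2: 0.6 ml/s = 36 ml/min at every phase
  v <- array(0, dim = c(32, 10, 10))
  px <- as.matrix(expand.grid(row = 3:7, col = 4:7))   # 20 pixels
  for (k in seq_len(nrow(px))) v[, px[k, 1], px[k, 2]] <- 10
  cine <- make_cine(v, venc = 80, pixel_area = 0.003)
  mask <- lumen_mask("RICA", px, c(10, 10))
  fw <- integrate_flow(cine, mask)
  expect_equal(fw$q, rep(36, 32), tolerance = 1e-12)
})

test_that("integrated phantom flow matches the analytic Womersley waveform", {
  # >= 8 pixels per radius: R = 0.25 cm at 0.02 cm pixels gives 12.5
  spec <- vessel_spec("RICA", c(24, 24), 0.25,
                      pg_harmonics = c(130, 70 * exp(-0.5i), 25 * exp(-1.2i),
                                       8 * exp(-2i)))
  g <- single_vessel_cine(spec)
  fw <- integrate_flow(g$cine, g$masks$RICA)
  q_true <- g$cine$truth$RICA$q_ml_min
  rel_rms <- sqrt(mean((fw$q - q_true)^2)) / sqrt(mean(q_true^2))
  expect_lt(rel_rms, 0.02)
})

test_that("masks that do not fit the cine raise bounds errors", {
  cine <- make_cine(array(1, dim = c(32, 10, 10)))
  expect_error(integrate_flow(cine, lumen_mask("VV", cbind(2, 2), c(20, 20))),
               "bounds error")
  expect_error(lumen_mask("VV", cbind(25, 2), c(10, 10)), "outside image")
  expect_error(lumen_mask("VV", matrix(integer(0), 0, 2), c(10, 10)), "empty")
})

test_that("drainage percentages reproduce the per-subject table arithmetic", {
  Tc <- 1
  const_fw <- function(label, q) flow_waveform(label, rep(q, 32), Tc)
  # subject with tCBF 883 and JVF 696 ml/min
  wf <- list(RICA = const_fw("RICA", 300), LICA = const_fw("LICA", 300),
             RVA = const_fw("RVA", 141.5), LVA = const_fw("LVA", 141.5),
             RIJV = const_fw("RIJV", 350), LIJV = const_fw("LIJV", 346))
  dp <- drainage_profile(wf)
  expect_equal(dp$tcbf, 883)
  expect_equal(round(dp$jvf_pct, 1), 78.8)
  expect_equal(dp$svf_pct, 0)              # all secondary channels absent
  # subject with tCBF 831 and JVF 747
  wf2 <- list(RICA = const_fw("RICA", 290), LICA = const_fw("LICA", 290),
              RVA = const_fw("RVA", 125.5), LVA = const_fw("LVA", 125.5),
              RIJV = const_fw("RIJV", 380), LIJV = const_fw("LIJV", 367),
              DCV = const_fw("DCV", 15))
  dp2 <- drainage_profile(wf2)
  expect_equal(round(dp2$jvf_pct, 1), 89.9)
  expect_equal(round(dp2$dcv_pct, 1), 1.8)
  # missing arteries and non-positive tCBF are contract errors
  expect_error(drainage_profile(wf[c("RICA", "RIJV")]), "arteries")
  wf0 <- lapply(wf, function(f) { f$q <- f$q * 0; f })
  expect_error(drainage_profile(wf0), "degenerate")
})

test_that("CSF stroke volume integrates the oscillatory positive lobe", {
  t <- (0:31) / 32
  # A sin(2 pi t / T), A = 3 ml/s -> SV = A T / pi
  fw <- flow_waveform("CSF", 180 * sin(2 * pi * t), 1)
  expect_equal(csf_stroke_volume(fw), 3 / pi, tolerance = 5e-3)
  expect_equal(csf_stroke_volume(flow_waveform("CSF", rep(0, 32), 1)), 0)
  # a steady offset does not change the oscillatory stroke volume
  fw_off <- flow_waveform("CSF", 60 + 180 * sin(2 * pi * t), 1)
  expect_equal(csf_stroke_volume(fw_off), csf_stroke_volume(fw),
               tolerance = 1e-12)
  # raw mode integrates the uncentred positive lobe
  expect_gt(csf_stroke_volume(fw_off, oscillatory = FALSE),
            csf_stroke_volume(fw_off))
})

test_that("phantom CSF stroke volume matches the analytic value", {
  spec <- vessel_spec("CSF", c(24, 24), 0.35, direction = -1,
                      pg_harmonics = c(0, 29.3 * exp(0.178i), 6 * exp(-2.2i)))
  g <- single_vessel_cine(spec)
  fw <- integrate_flow(g$cine, g$masks$CSF)
  sv <- csf_stroke_volume(fw)
  # analytic oracle on a fine grid
  tf <- seq(0, 1, length.out = 8193)[-8193]
  qf <- womersley_flow_waveform(spec, fluid_props("csf"),
                                g$cine$params, t = tf, signed = FALSE) / 60
  sv_true <- sum(pmax(qf - mean(qf), 0)) * (1 / 8192)
  expect_lt(abs(sv - sv_true) / sv_true, 0.02)
})

test_that("flow integration is linear and additive over disjoint masks", {
  set.seed(8)
  v <- array(rnorm(32 * 12 * 12), dim = c(32, 12, 12))
  cine1 <- make_cine(v)
  cine3 <- make_cine(3 * v)
  mA <- lumen_mask("RICA", as.matrix(expand.grid(2:4, 2:4)), c(12, 12))
  mB <- lumen_mask("RICA", as.matrix(expand.grid(7:9, 7:9)), c(12, 12))
  mAB <- lumen_mask("RICA", rbind(mA$pixels, mB$pixels), c(12, 12))
  expect_equal(integrate_flow(cine3, mA)$q, 3 * integrate_flow(cine1, mA)$q,
               tolerance = 1e-12)
  expect_equal(integrate_flow(cine1, mAB)$q,
               integrate_flow(cine1, mA)$q + integrate_flow(cine1, mB)$q,
               tolerance = 1e-12)
  expect_equal(csf_stroke_volume(flow_waveform("CSF", 3 * v[, 2, 2], 1)),
               3 * csf_stroke_volume(flow_waveform("CSF", v[, 2, 2], 1)),
               tolerance = 1e-12)
})
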