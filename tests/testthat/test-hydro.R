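test_that("venous correction scales to exact steady-state balance", {
  t <- (0:31) / 32
  A <- flow_waveform("arterial", 700 + 150 * sin(2 * pi * t), 1)
  V_eq <- flow_waveform("venous", 700 + 60 * cos(2 * pi * t), 1)
  c1 <- correct_venous_outflow(A, V_eq)
  expect_equal(c1$venous_scale, 1, tolerance = 1e-12)
  expect_equal(c1$waveform$q, V_eq$q, tolerance = 1e-12)

  V8 <- flow_waveform("venous", 0.8 * (700 + 60 * cos(2 * pi * t)), 1)
  c2 <- correct_venous_outflow(A, V8)
  expect_equal(c2$venous_scale, 1.25, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:20) {
    Ar <- flow_waveform("arterial", 500 + rnorm(32, sd = 80), 1)
    Vr <- flow_waveform("venous", 300 + rnorm(32, sd = 50), 1)
    cc <- correct_venous_outflow(Ar, Vr)
    expect_lt(abs(mean(Ar$q - cc$waveform$q)), 1e-12 * mean(Ar$q))
  }
  expect_error(correct_venous_outflow(A, flow_waveform("venous", rep(0, 32), 1)),
               "degenerate")
})

test_that("additive venous correction also balances the cycle mean", {
  t <- (0:31) / 32
  A <- flow_waveform("arterial", 700 + 150 * sin(2 * pi * t), 1)
  V <- flow_waveform("venous", 560 + 60 * cos(2 * pi * t), 1)
  cc <- correct_venous_outflow(A, V, mode = "additive")
  expect_equal(cc$venous_scale, 140, tolerance = 1e-10)
  expect_lt(abs(mean(A$q - cc$waveform$q)), 1e-10)
})

test_that("the volume-change waveform integrates the net transcranial rate", {
  t <- (0:31) / 32
  # zero net rate: flat volume
  A <- flow_waveform("arterial", rep(600, 32), 1)
  icv0 <- icvc_waveform(A, A)
  expect_equal(icv0$icvc, 0)
  expect_equal(icv0$dv[1L], 0)

  # net rate B sin(2 pi t / T), B = 1.5 ml/s -> ICVC = B T / pi
  B <- 1.5
  A2 <- flow_waveform("arterial", 600 + 60 * B * sin(2 * pi * t), 1)
  V2 <- flow_waveform("venous", rep(600, 32), 1)
  icv <- icvc_waveform(A2, V2)
  expect_equal(icv$icvc, B / pi, tolerance = 1e-2)
  expect_lt(abs(icv$closure), 1e-9)

  # a synthetic subject constructed for an analytic ICVC of 0.60 ml
  B6 <- 0.60 * pi
  A3 <- flow_waveform("arterial", 700 + 60 * B6 * sin(2 * pi * t), 1)
  V3 <- flow_waveform("venous", rep(700, 32), 1)
  expect_equal(icvc_waveform(A3, V3)$icvc, 0.60, tolerance = 0.01)

  expect_error(icvc_waveform(A2, flow_waveform("venous", rep(1, 16), 1)),
               "alignment")
})

test_that("cycle closure is exact after venous correction, for any input", {
  set.seed(12)
  for (i in 1:25) {
    t <- (0:31) / 32
    A <- flow_waveform("arterial", 700 + rnorm(32, sd = 120), 1)
    V <- flow_waveform("venous", 500 + rnorm(32, sd = 90), 1)
    csf <- flow_waveform("CSF", rnorm(32, sd = 70), 1)
    cc <- correct_venous_outflow(A, V)
    icv <- icvc_waveform(A, cc$waveform, csf)
    expect_lt(abs(icv$closure), 1e-9)
    expect_equal(icv$dv[1L], 0)
  }
})

test_that("a static fluid has zero pressure gradient", {
  v <- array(0, dim = c(32, 16, 16))
  cine <- make_cine(v, venc = 8)
  mask <- circular_roi_mask(c(8, 8), 5, c(16, 16), label = "CSF")
  pg <- csf_pressure_gradient(cine, mask)
  expect_equal(pg$pg, rep(0, 32))
  expect_equal(pg$ptp_pg, 0)
})

test_that("steady Poiseuille flow inverts to the prescribed gradient", {
  # centreline 2.25 cm/s, R = 0.3 cm, mu = 0.01 poise -> G = 1 dyn/cm^3
  spec <- vessel_spec("CSF", c(24, 24), 0.3, pg_harmonics = 1)
  g <- single_vessel_cine(spec, pixel_size = 0.02)   # 15 px / radius
  pg <- csf_pressure_gradient(g$cine, g$masks$CSF)
  expect_equal(mean(pg$pg) * 1333.22, 1, tolerance = 0.05)
  expect_lt(pg$ptp_pg, 1e-10)
})

test_that("too-thin masks raise a geometry error", {
  v <- array(rnorm(32 * 16 * 16), dim = c(32, 16, 16))
  cine <- make_cine(v, venc = 8)
  thin <- lumen_mask("CSF", cbind(5:10, 5L), c(16, 16))  # 1-pixel line
  expect_error(csf_pressure_gradient(cine, thin), "geometry too thin")
})

test_that("compliance index and MRICP follow the inverse law", {
  cal <- calibration_config()          # d = 1.8, a = 73, b = 0
  res <- compliance_and_mricp(0.48, 0.043, cal)
  expect_equal(res$compliance_index, 0.48 / (0.043 * 1.8), tolerance = 1e-12)
  expect_equal(round(res$compliance_index, 2), 6.20)
  expect_equal(round(res$mricp, 1), 11.8)
  # doubling PTP-PG halves compliance and doubles (mricp - b)
  res2 <- compliance_and_mricp(0.48, 0.086, cal)
  expect_equal(res2$compliance_index, res$compliance_index / 2,
               tolerance = 1e-12)
  expect_equal(res2$mricp - cal$b, 2 * (res$mricp - cal$b), tolerance = 1e-12)
  # the inverse law holds exactly, also under a non-zero offset
  set.seed(2)
  for (i in 1:20) {
    cal_i <- calibration_config(d = runif(1, 0.5, 3), a = runif(1, 40, 120),
                                b = runif(1, 0, 5))
    r <- compliance_and_mricp(runif(1, 0.1, 1), runif(1, 0.01, 0.1), cal_i)
    expect_equal(r$compliance_index * (r$mricp - cal_i$b), cal_i$a,
                 tolerance = 1e-12)
  }
  # degenerate limits
  expect_error(compliance_and_mricp(0.5, 0, cal), "undefined compliance")
  expect_warning(res0 <- compliance_and_mricp(1e-9, 0.043, cal), "capped")
  expect_equal(res0$mricp, cal$mricp_cap)
})

test_that("CSF tracks the net transcranial flow more closely at low compliance", {
  t <- (0:31) / 32
  av <- 120 * sin(2 * pi * t) + 40 * sin(4 * pi * t - 0.8)  # A - V (ml/min)
  resid <- 30 * sin(6 * pi * t + 0.4)
  csf_low <- flow_waveform("CSF", 0.85 * av + resid, 1)   # low compliance
  csf_high <- flow_waveform("CSF", 0.30 * av + resid, 1)  # high compliance
  expect_gt(cor(csf_low$q, av), cor(csf_high$q, av))
  # and the volume buffering (ICVC) is correspondingly smaller
  A <- flow_waveform("arterial", 700 + av, 1)
  V <- flow_waveform("venous", rep(700, 32), 1)
  icv_low <- icvc_waveform(A, V, csf_low)
  icv_high <- icvc_waveform(A, V, csf_high)
  expect_lt(icv_low$icvc, icv_high$icvc)
})
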