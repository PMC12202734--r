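wm <- default_tissue_params()$WM

test_that("CPMG limits: perfect refocusing and mono-exponential decay", {
  p <- test_protocol(ETL = 16)
  ## T2 finite, T1 effectively infinite: S_i = exp(-i*ESP/T2)
  t_inf <- tissue_params("X", T1 = 1e12, T2 = 50, M0 = 1)
  s <- epg_fse_signal(rep(180, 16), t_inf, p)$S
  expect_equal(s, exp(-(1:16) * 3.8 / 50), tolerance = 1e-10)
  ## lossless: all ones
  t_loss <- tissue_params("Y", T1 = 1e12, T2 = 1e12, M0 = 1)
  s2 <- epg_fse_signal(rep(180, 16), t_loss, p)$S
  expect_equal(s2, rep(1, 16), tolerance = 1e-10)
})

test_that("epg_step reproduces the no-pulse and perfect-refocusing limits", {
  st <- epg_init(K = 8)
  st <- epg_rf_excite(st)
  out <- epg_step(st, 180, 0, E1 = 1, E2 = 1)
  expect_equal(Mod(out$Fp[1]), 1, tolerance = 1e-12)
  ## fa = 0: transverse states only shift, Z only recovers
  st2 <- epg_init(K = 8, M0 = 1)
  st2$Z[1] <- 0.4 + 0i
  E1 <- 0.9
  out2 <- epg_step(st2, 0, 0, E1 = E1, E2 = 0.8)
  z_expect <- (0.4 * E1 + (1 - E1)) * E1 + (1 - E1)
  expect_equal(Re(out2$Z[1]), z_expect, tolerance = 1e-12)
  expect_equal(Mod(out2$Fp[1]), 0)
  expect_error(epg_step(st2, 200, 0, 1, 1), "fa")
})

test_that("EPG matches the brute-force isochromat oracle", {
  p <- test_protocol(ETL = 24)
  ## constant 120 degrees applied to a pure transverse state, and full trains
  for (seed in 1:3) {
    set.seed(seed)
    al <- runif(24, 15, 165)
    s_epg <- epg_fse_signal(al, wm, p)$S
    s_iso <- iso_cpmg(al, wm$T1, wm$T2, p$ESP, M0 = wm$M0, nspins = 2e4)
    expect_equal(s_epg, s_iso, tolerance = 1e-3)
  }
  s_epg <- epg_fse_signal(rep(120, 24), wm, p)$S
  s_iso <- iso_cpmg(rep(120, 24), wm$T1, wm$T2, p$ESP, M0 = wm$M0,
                    nspins = 2e4)
  expect_equal(s_epg, s_iso, tolerance = 1e-3)
})

test_that("inversion preparation matches the isochromat oracle and nulls", {
  pf <- sequence_protocol(ETL = 16, ESP = 4.04, TR = 8000, center_echo = 8,
                          inversion = TRUE, TI = 2250)
  s_epg <- epg_fse_signal(rep(100, 16), wm, pf)$S
  s_iso <- iso_cpmg(rep(100, 16), wm$T1, wm$T2, pf$ESP, M0 = wm$M0,
                    nspins = 2e4, inversion = TRUE, TI = 2250)
  expect_equal(s_epg, s_iso, tolerance = 1e-3)
  ## at the null TI the signal vanishes
  pnull <- sequence_protocol(ETL = 8, ESP = 4, TR = 8000, center_echo = 4,
                             inversion = TRUE, TI = wm$T1 * log(2))
  expect_lt(max(epg_fse_signal(rep(120, 8), wm, pnull)$S), 1e-12)
})

test_that("propagated Jacobian agrees with central finite differences", {
  p <- test_protocol(ETL = 16)
  set.seed(11)
  al <- runif(16, 20, 160)
  J <- epg_fse_signal(al, wm, p, gradient = TRUE)$J
  h <- 1e-4
  for (j in c(1, 5, 9, 16)) {
    ap <- al; am <- al
    ap[j] <- ap[j] + h; am[j] <- am[j] - h
    fd <- (epg_fse_signal(ap, wm, p)$S - epg_fse_signal(am, wm, p)$S) / (2 * h)
    expect_equal(J[, j], fd, tolerance = 1e-4)
  }
})

test_that("energy bound and truncation invariance hold", {
  p <- test_protocol(ETL = 20)
  set.seed(4)
  for (i in 1:5) {
    al <- runif(20, 0, 180)
    s <- epg_fse_signal(al, wm, p)$S
    expect_lte(max(s), wm$M0 + 1e-12)
  }
  al <- runif(20, 10, 170)
  s1 <- epg_fse_signal(al, wm, p, K = 21)$S
  s2 <- epg_fse_signal(al, wm, p, K = 60)$S
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("csf_null_weight evaluates the closed form", {
  expect_equal(csf_null_weight(wm, TI = wm$T1 * log(2), TR = 1e9), 0,
               tolerance = 1e-12)
  expect_equal(csf_null_weight(wm, TI = 1e6, TR = 1e7), 1, tolerance = 1e-10)
  expect_equal(csf_null_weight(wm, TI = 1800, TR = 1e6),
               1 - 2 * exp(-1.2), tolerance = 1e-12)
  expect_equal(csf_null_weight(wm, TI = 1800, TR = 3200, tr_cycling = TRUE),
               1 - 2 * exp(-1.2) + exp(-3200 / 1500), tolerance = 1e-12)
})

test_that("epg_fse_signal validates its inputs", {
  p <- test_protocol(ETL = 8)
  expect_error(epg_fse_signal(rep(90, 7), wm, p), "ETL")
  expect_error(epg_fse_signal(rep(190, 8), wm, p), "180")
  expect_error(sequence_protocol(ETL = 8, ESP = 4, TR = 3200, center_echo = 4,
                                 inversion = TRUE, TI = 4000), "TI")
})
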