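tis <- default_tissue_params()

test_that("unencoded signal averages tissues with IR-attenuated weights", {
  p <- test_protocol(ETL = 12)
  al <- rep(90, 12)
  ## single tissue: the tissue's own signal scaled by the IR weight
  m <- matrix(FALSE, 16, 16); m[4:12, 4:12] <- TRUE
  d1 <- object_descriptor(tis["WM"], list(WM = m))
  un <- simulate_unencoded_signal(d1, al, p, TI = 1800, tr_cycling = FALSE)
  s_wm <- epg_fse_signal(al, tis$WM, p)$S
  expect_equal(un$S, abs(1 - 2 * exp(-1800 / 1500)) * s_wm, tolerance = 1e-12)
  ## two tissues with equal voxel counts: arithmetic mean of weighted signals
  m2 <- matrix(FALSE, 16, 16); m2[4:12, 1:3] <- TRUE
  m1 <- matrix(FALSE, 16, 16); m1[4:12, 5:7] <- TRUE
  d2 <- object_descriptor(tis[c("WM", "GM")], list(WM = m1, GM = m2))
  un2 <- simulate_unencoded_signal(d2, al, p, TI = 1800, tr_cycling = FALSE)
  wWM <- abs(csf_null_weight(tis$WM, 1800, p$TR))
  wGM <- abs(csf_null_weight(tis$GM, 1800, p$TR))
  s_gm <- epg_fse_signal(al, tis$GM, p)$S
  expect_equal(un2$S, (wWM * s_wm + wGM * s_gm) / 2, tolerance = 1e-12)
  ## at the tissue's null TI its contribution vanishes
  d3 <- object_descriptor(tis[c("WM", "CSF")], list(WM = m1, CSF = m2))
  pnull <- sequence_protocol(ETL = 12, ESP = 3.8, TR = 1e5, center_echo = 6)
  un3 <- simulate_unencoded_signal(d3, al, pnull,
                                   TI = tis$CSF$T1 * log(2),
                                   tr_cycling = FALSE)
  only_wm <- abs(csf_null_weight(tis$WM, tis$CSF$T1 * log(2), 1e5)) *
    epg_fse_signal(al, tis$WM, pnull)$S / 2
  expect_equal(un3$S, only_wm, tolerance = 1e-9)
})

test_that("PSF residual error: reference identity, scale invariance, hand case", {
  tab <- linear_view_ordering(8, 8, 4)
  expect_equal(psf_error(rep(1, 8), tab), 0, tolerance = 1e-12)
  set.seed(9)
  s <- runif(8, 0.2, 1)
  expect_equal(psf_error(s, tab), psf_error(10 * s, tab), tolerance = 1e-12)
  ## two-line hand evaluation via the direct DFT oracle
  tab2 <- linear_view_ordering(2, 2, 1)
  s2 <- c(1, 0.5) / mean(c(1, 0.5))
  psf <- Mod(dft_centred(s2[tab2$echo_of_line]))
  ref <- Mod(dft_centred(c(1, 1)))
  expect_equal(psf_error(c(1, 0.5), tab2),
               sum(abs(ref / sum(ref) - psf / sum(psf))), tolerance = 1e-12)
  expect_error(psf_error(rep(0, 8), tab), "zero")
  ## the error is bounded by 2 under the unit-L1 comparison
  expect_lt(psf_error(c(1, rep(1e-9, 7)), tab), 2 + 1e-12)
})

test_that("pseudo-replica SNR matches the analytic white-noise value", {
  ## constant image c with unit per-component noise and unitary transforms:
  ## per-voxel magnitude SD ~ 1, so the median SNR approximates c
  cval <- 10
  img <- matrix(cval, 24, 24)
  k <- vfadesign:::fft2c(img)
  snr <- pseudo_replica_snr(k, n_rep = 100, seed = 42)
  expect_lt(abs(median(snr$map) - cval), 3 / sqrt(100))
  ## determinism and linearity in the signal
  snr2 <- pseudo_replica_snr(k, n_rep = 100, seed = 42)
  expect_identical(snr$map, snr2$map)
  ## doubling the k-space doubles the SNR up to the Rician nonlinearity of
  ## the magnitude reconstruction (O(1/SNR) with the same noise realisation)
  snr3 <- pseudo_replica_snr(2 * k, n_rep = 100, seed = 42)
  expect_equal(snr3$map, 2 * snr$map, tolerance = 0.02)
  snr4 <- pseudo_replica_snr(k, n_rep = 100, seed = 43)
  expect_false(identical(snr$map, snr4$map))
})

test_that("pre-whitening makes correlated channels equivalent to unit noise", {
  img <- matrix(8, 16, 16)
  k <- vfadesign:::fft2c(img)
  C <- matrix(c(4, 0, 0, 4), 2)
  ## two channels with noise variance 4: whitening divides k by 2, so the
  ## per-channel SNR halves and the RSS combination scales accordingly
  snr_w <- pseudo_replica_snr(list(k, k), noise_covariance = C,
                              n_rep = 80, seed = 7)
  snr_u <- pseudo_replica_snr(list(k / 2, k / 2), n_rep = 80, seed = 7)
  expect_equal(snr_w$map, snr_u$map, tolerance = 1e-10)
  expect_error(pseudo_replica_snr(list(k, k),
                                  noise_covariance = matrix(c(1, 2, 2, 1), 2),
                                  n_rep = 10),
               "positive definite")
})

test_that("CNR follows its defining ratio and antisymmetry", {
  img <- matrix(4, 8, 8)
  img[1:4, ] <- 10
  A <- matrix(FALSE, 8, 8); A[1:4, ] <- TRUE
  B <- !A
  expect_equal(cnr(img, A, B, sigmaA = 2), 3)
  expect_equal(cnr(img, B, A, sigmaA = 2), -3)
  expect_equal(cnr(img, A, A, sigmaA = 5), 0)
  expect_error(cnr(img, matrix(FALSE, 8, 8), B, 1), "non-empty")
})
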