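tis <- default_tissue_params()

test_that("linear view ordering places the centre echo on the centre line", {
  tab <- linear_view_ordering(Ny = 200, ETL = 200, center_echo = 100)
  expect_equal(tab$center_line, 101L)
  expect_equal(tab$echo_of_line[tab$center_line], 100L)
  ## TE_eff of the centre line
  expect_equal(tab$echo_of_line[tab$center_line] * 3.8, 380)
  ## monotone non-decreasing echo numbers along PE, all within [1, ETL]
  expect_true(all(diff(tab$echo_of_line) >= 0))
  expect_true(all(tab$echo_of_line >= 1 & tab$echo_of_line <= 200))

  tab4 <- linear_view_ordering(Ny = 4, ETL = 4, center_echo = 2)
  expect_true(all(diff(tab4$echo_of_line) >= 0))
  expect_equal(tab4$echo_of_line[tab4$center_line], 2L)
  expect_error(linear_view_ordering(Ny = 8, ETL = 4, center_echo = 9), "center_echo")
})

test_that("nearest-echo fill resolves ties toward the lower line index", {
  ## Ny=8, acceleration 2: sampled lines 1,3,5,7 carry echoes 1..4; each
  ## even line is equidistant between two sampled lines -> lower index wins
  tab <- linear_view_ordering(Ny = 8, ETL = 4, center_echo = 3,
                              acceleration = 2)
  expect_equal(which(tab$sampled_mask), c(1L, 3L, 5L, 7L))
  expect_equal(tab$echo_of_line, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("MTF lookup maps amplitudes through the sampling table", {
  tab <- linear_view_ordering(Ny = 8, ETL = 8, center_echo = 4)
  expect_equal(mtf_from_signal(rep(1, 8), tab), rep(1, 8))
  ramp <- seq_len(8)
  expect_equal(mtf_from_signal(ramp, tab), ramp[tab$echo_of_line])
  expect_error(mtf_from_signal(rep(1, 3), tab), "amplitudes")
})

test_that("PSF matches the hand DFT oracle and the delta reference", {
  ## uniform MTF -> all energy in the central voxel
  p <- psf_from_mtf(rep(1, 16))
  expect_equal(p$values[p$center], sqrt(16), tolerance = 1e-12)
  expect_lt(max(p$values[-p$center]), 1e-12)
  ## two-point case against the direct DFT sum
  p2 <- psf_from_mtf(c(1, 0.5))
  expect_equal(p2$values, Mod(dft_centred(c(1, 0.5))), tolerance = 1e-12)
  ## and for a random MTF
  set.seed(21)
  m <- runif(17) # odd length exercises the shift conventions
  expect_equal(psf_from_mtf(m)$values, Mod(dft_centred(m)), tolerance = 1e-10)
  ## linearity in the MTF scale
  expect_equal(psf_from_mtf(3 * m)$values, 3 * psf_from_mtf(m)$values,
               tolerance = 1e-12)
})

test_that("uniform signal responses reproduce the amplitude map exactly", {
  ph <- make_synthetic_brain(c(32, 32), seed = 1)
  tab <- linear_view_ordering(32, 40, 20)
  sim <- simulate_fse_image(ph, signals = list(WM = rep(0.4, 40),
                                               GM = rep(0.7, 40),
                                               CSF = rep(1, 40)),
                            table = tab)
  ref <- 0.4 * ph$masks$WM + 0.7 * ph$masks$GM + ph$masks$CSF
  expect_equal(sim$image, ref, tolerance = 1e-10)
  ## echo-independent signals are equivalent to a single-echo composite
  sim2 <- simulate_fse_image(ph, signals = list(WM = rep(0.4, 40),
                                                GM = rep(0.4, 40),
                                                CSF = rep(0.4, 40)),
                             table = tab)
  comp <- 0.4 * (ph$masks$WM + ph$masks$GM + ph$masks$CSF)
  expect_equal(sim2$image, comp, tolerance = 1e-10)
})

test_that("a one-pixel stripe reproduces the PSF by direct convolution", {
  stripe <- matrix(FALSE, 32, 32)
  stripe[, 12] <- TRUE
  d <- object_descriptor(tis["WM"], list(WM = stripe))
  S <- exp(-(1:32) / 15)
  tab <- linear_view_ordering(32, 32, 16)
  sim <- simulate_fse_image(d, signals = list(WM = S), table = tab)
  ## complex PSF of the stripe's MTF, circularly centred on the stripe
  mtf <- mtf_from_signal(S, tab)
  cp <- dft_centred(mtf)
  c0 <- floor(32 / 2) + 1
  prof <- Mod(cp[((seq_len(32) - 12 + c0 - 1) %% 32) + 1]) / sqrt(32)
  for (row in c(1, 16, 32))
    expect_equal(sim$image[row, ], prof, tolerance = 1e-8)
})

test_that("image simulation is linear in each tissue's signal response", {
  ph <- make_synthetic_brain(c(16, 16), seed = 2, vessels = 0)
  tab <- linear_view_ordering(16, 16, 8)
  set.seed(3)
  sA <- lapply(ph$masks, function(m) runif(16))
  sB <- lapply(ph$masks, function(m) runif(16))
  sAB <- Map(`+`, sA, sB)
  iA <- simulate_fse_image(ph, signals = sA, table = tab)$complex_image
  iB <- simulate_fse_image(ph, signals = sB, table = tab)$complex_image
  iAB <- simulate_fse_image(ph, signals = sAB, table = tab)$complex_image
  expect_equal(iAB, iA + iB, tolerance = 1e-10)
})

test_that("spin-echo target evaluates the closed form and suppression", {
  ph <- make_synthetic_brain(c(32, 32), seed = 1, vessels = 0)
  img <- spin_echo_target(ph, TE = 45, TR = 6000)
  wm_val <- 0.75 * (1 - exp(-4)) * exp(-0.9)
  expect_equal(unique(img[ph$masks$WM]), wm_val, tolerance = 1e-12)
  ## proton-density limit
  pd <- spin_echo_target(ph, TE = 0, TR = 1e9)
  expect_equal(unique(pd[ph$masks$CSF]), 1, tolerance = 1e-12)
  ## dark-fluid target: CSF exactly zero
  fl <- spin_echo_target(ph, TE = 45, TR = 6000, suppressed_tissues = "CSF")
  expect_true(all(fl[ph$masks$CSF] == 0))
  expect_equal(fl[ph$masks$WM], img[ph$masks$WM])
  expect_error(spin_echo_target(ph, 45, 6000, suppressed_tissues = "XX"),
               "unknown")
})
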