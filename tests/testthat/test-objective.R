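test_that("relative SAR evaluates the normalised mean-square flip angle", {
  expect_equal(relative_sar(rep(180, 10)), 1)
  expect_equal(relative_sar(rep(0, 10)), 0)
  expect_equal(relative_sar(c(90, 90)), 0.25)
  expect_equal(relative_sar(init_alpha(0.09, 200)), 0.09, tolerance = 1e-12)
})

test_that("L1 contrast loss measures the mean absolute deviation", {
  t <- matrix(runif(16), 4, 4)
  expect_equal(l1_contrast_loss(0.65 * t, t, cTRG = 0.65), 0)
  expect_equal(l1_contrast_loss(0.65 * t + 1, t, cTRG = 0.65), 1)
  expect_equal(l1_contrast_loss(matrix(c(1, 0, 0, 1), 2), matrix(0, 2, 2)),
               0.5)
  expect_error(l1_contrast_loss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("PSF loss penalises side bands only, linearly in the weights", {
  w <- loss_weights(w = 1)
  delta <- psf_from_mtf(rep(1, 8))
  expect_equal(psf_loss(list(WM = delta, GM = delta), w), 0)
  ## hand case: Ny=2, |PSF| = (0.25 off-centre, 0.75 centre) -> 0.25/2
  p <- list(values = c(0.25, 0.75), center = 2L)
  class(p) <- "psf_profile"
  expect_equal(psf_loss(list(WM = p), w), 0.125)
  w2 <- loss_weights(w = 1, cT = c(WM = 0.5))
  expect_equal(psf_loss(list(WM = p), w2), 0.0625)
})

test_that("smoothness penalty is the L1 total variation of the train", {
  expect_equal(smoothness_penalty(rep(70, 9)), 0)
  expect_equal(smoothness_penalty(c(0, 180)), 180)
  expect_equal(smoothness_penalty(c(10, 30, 20)), 30)
  expect_equal(smoothness_penalty(50), 0) # single echo, by convention
})

make_small_ctx <- function(w, lambda_R = 1 / (1800 * 24)) {
  ph <- make_synthetic_brain(c(16, 24), seed = 2)
  pr <- test_protocol(ETL = 24, center_echo = 12)
  tab <- linear_view_ordering(24, 24, 12)
  loss_context(ph, pr, tab, loss_weights(w = w, lambda_R = lambda_R))
}

test_that("total loss satisfies the breakdown identity and the w limits", {
  set.seed(7)
  al <- runif(24, 30, 150)
  for (w in c(0, 0.5, 1)) {
    ctx <- make_small_ctx(w)
    lb <- total_loss(alpha = al, context = ctx)
    expect_equal(lb$total,
                 w * lb$L_PSF + (1 - w) * lb$L1 +
                   ctx$weights$lambda_R * lb$R,
                 tolerance = 1e-12)
    expect_true(all(c(lb$L1, lb$L_PSF, lb$R, lb$total) >= 0))
    expect_equal(lb$rSAR, relative_sar(al), tolerance = 1e-12)
  }
  ## all components are reported regardless of w
  lb1 <- total_loss(alpha = al, context = make_small_ctx(1))
  lb0 <- total_loss(alpha = al, context = make_small_ctx(0))
  expect_equal(lb1$L1, lb0$L1)
  expect_equal(lb1$L_PSF, lb0$L_PSF)
})

test_that("the analytic gradient matches central finite differences", {
  ctx <- make_small_ctx(0.5)
  set.seed(7)
  al <- runif(24, 30, 150)
  g <- attr(total_loss(alpha = al, context = ctx, gradient = TRUE),
            "gradient")
  h <- 1e-4
  fd <- numeric(24)
  for (j in 1:24) {
    ap <- al; am <- al
    ap[j] <- ap[j] + h; am[j] <- am[j] - h
    fd[j] <- (total_loss(alpha = ap, context = ctx)$total -
              total_loss(alpha = am, context = ctx)$total) / (2 * h)
  }
  expect_equal(g, fd, tolerance = 1e-3)
})

test_that("the internal L1 evaluation equals the explicit image-domain loss", {
  ctx <- make_small_ctx(0.5)
  set.seed(8)
  al <- runif(24, 30, 150)
  lb <- total_loss(alpha = al, context = ctx)
  sim <- simulate_fse_image(ctx$descr, al, ctx$protocol, ctx$table)
  tgt <- spin_echo_target(ctx$descr, 45, 6000)
  expect_equal(lb$L1, l1_contrast_loss(sim, tgt, 0.65), tolerance = 1e-12)
})
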