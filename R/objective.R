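#' Relative SAR of a flip-angle train
#'
#' Mean of the squared flip angles normalised to a 180 degree train:
#' `(1/ETL) * sum((alpha_i / 180)^2)`, in `[0, 1]`. RF power deposition scales
#' with the squared flip angles, so this ratio compares trains independently
#' of hardware calibration.
#'
#' @param alpha flip angles in degrees.
#' @return Scalar in `[0, 1]`.
#' @examples
#' relative_sar(rep(180, 10))  # 1
#' @export
relative_sar <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (!length(alpha)) stopf("'alpha' must be non-empty")
  mean((alpha / 180)^2)
}

#' Loss weights for the VFA objective
#'
#' @param w balance between PSF and contrast/SNR objectives in `[0, 1]`
#'   (1 = pure PSF optimisation, 0 = pure contrast/SNR).
#' @param cTRG target-image scale in `[0, 1]`.
#' @param cT per-tissue PSF weights in `[0, 1]`; a single value is recycled,
#'   or a named vector selects weights per tissue.
#' @param lambda_R weight of the flip-angle smoothness penalty.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(w, cTRG = 0.65, cT = 1, lambda_R = 1) {
  check_number(w, "w", lower = 0, upper = 1)
  check_number(cTRG, "cTRG", lower = 0, upper = 1)
  if (any(cT < 0) || any(cT > 1)) stopf("'cT' entries must lie in [0, 1]")
  check_number(lambda_R, "lambda_R", lower = 0)
  structure(list(w = w, cTRG = cTRG, cT = cT, lambda_R = lambda_R),
            class = "loss_weights")
}

#' L1 contrast/SNR loss
#'
#' Mean absolute deviation of the simulated FSE image from the scaled target:
#' `(1/N) * sum(|I_FSE - cTRG * I_TRG|)`.
#'
#' @param sim a `sim_image` or a numeric matrix (magnitude image).
#' @param target numeric matrix of the same shape.
#' @param cTRG target scale in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
l1_contrast_loss <- function(sim, target, cTRG = 0.65) {
  img <- if (inherits(sim, "sim_image")) sim$image else as.matrix(sim)
  if (!identical(dim(img), dim(as.matrix(target))))
    stopf("image and target shapes differ")
  mean(abs(img - cTRG * target))
}

#' PSF side-band loss
#'
#' Sum over tissues of the tissue-weighted mean absolute PSF amplitude with
#' the central voxel masked out: only the side bands -- the part of the PSF
#' that blurs neighbouring voxels into the centre -- are penalised. Zero iff
#' every weighted PSF is a pure central delta.
#'
#' @param psfs named list of `psf_profile` objects (or numeric vectors), all
#'   of one length Ny.
#' @param weights a [loss_weights()] object (uses `cT`).
#' @return Non-negative scalar.
#' @export
psf_loss <- function(psfs, weights) {
  if (!inherits(weights, "loss_weights")) stopf("'weights' must be loss_weights")
  vals <- lapply(psfs, function(p)
    if (inherits(p, "psf_profile")) p$values else as.numeric(p))
  ny <- unique(vapply(vals, length, 1L))
  if (length(ny) != 1L) stopf("all PSF profiles must have the same length")
  cT <- tissue_weights(weights$cT, names(psfs))
  c0 <- centre_index(ny)
  tot <- 0
  for (i in seq_along(vals)) {
    v <- abs(vals[[i]]); v[c0] <- 0
    tot <- tot + cT[i] * sum(v) / ny
  }
  tot
}

tissue_weights <- function(cT, nms) {
  if (!is.null(names(cT))) {
    out <- rep(0, length(nms))
    hit <- match(names(cT), nms)
    if (anyNA(hit)) stopf("unknown tissue in cT: %s",
                          paste(names(cT)[is.na(hit)], collapse = ", "))
    out[hit] <- cT
    out
  } else rep_len(cT, length(nms))
}

#' Flip-angle smoothness penalty
#'
#' L1 distance of adjacent flip angles, `sum_i |alpha_{i+1} - alpha_i|`,
#' discouraging discontinuities along the train. Zero for a constant train
#' (and, by convention, for a single-echo train).
#'
#' @param alpha flip angles in degrees.
#' @return Non-negative scalar in degrees.
#' @export
smoothness_penalty <- function(alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) < 2L) return(0)
  sum(abs(diff(alpha)))
}

smoothness_grad <- function(alpha) {
  d <- sign(diff(alpha))
  c(-d, 0) + c(0, d)
}

#' Precompute the invariant parts of the VFA objective
#'
#' Builds everything in the total loss that does not depend on the flip-angle
#' train: the target image, the per-tissue mask k-spaces of the linear FSE
#' image model (the combined k-space is `sum_T MTF_T[line] *
#' fft2c(mask_T)[, line]`, so both the image loss and its adjoint reduce to a
#' Fourier transform plus per-line sums), and the PE line-to-echo maps of the
#' image and PSF sampling tables.
#'
#' @param descr an [object_descriptor()].
#' @param protocol a [sequence_protocol()].
#' @param table sampling table for the image model (Ny = PE grid size).
#' @param weights a [loss_weights()].
#' @param psf_table sampling table for the PSF loss; defaults to `table`. A
#'   full-length table (one line per echo) makes the PSF penalty act on the
#'   whole train even when the image grid is smaller.
#' @param target_spec list with `TE`, `TR` (ms) and optionally `suppressed`
#'   (tissue names zeroed in the target) and `include_t1_weighting`.
#' @return Object of class `loss_context`.
#' @export
loss_context <- function(descr, protocol, table, weights,
                         psf_table = NULL,
                         target_spec = list(TE = 45, TR = 6000)) {
  if (!inherits(descr, "object_descriptor"))
    stopf("'descr' must be an object_descriptor")
  if (!inherits(protocol, "sequence_protocol"))
    stopf("'protocol' must be a sequence_protocol")
  if (!inherits(table, "sampling_table")) stopf("'table' must be a sampling_table")
  if (!inherits(weights, "loss_weights")) stopf("'weights' must be loss_weights")
  if (is.null(psf_table)) psf_table <- table
  if (table$Ny != descr$grid_shape[2])
    stopf("table Ny (%d) must equal the PE grid dimension (%d)",
          table$Ny, descr$grid_shape[2])
  if (max(table$echo_of_line) > protocol$ETL ||
      max(psf_table$echo_of_line) > protocol$ETL)
    stopf("sampling tables require echoes beyond the protocol's ETL")

  suppressed <- target_spec$suppressed %||% character()
  inc_t1 <- target_spec$include_t1_weighting %||% TRUE
  target <- spin_echo_target(descr, target_spec$TE, target_spec$TR,
                             suppressed_tissues = suppressed,
                             include_t1_weighting = inc_t1)

  tnames <- names(descr$tissues)
  kmasks <- lapply(descr$masks, function(m) fft2c(m * 1))
  structure(list(descr = descr, protocol = protocol, table = table,
                 psf_table = psf_table, weights = weights, target = target,
                 tnames = tnames, kmasks = kmasks,
                 nvox = prod(descr$grid_shape)),
            class = "loss_context")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total constrained VFA objective
#'
#' Evaluates the full loss of a flip-angle train: the convex combination of
#' the PSF side-band loss and the L1 contrast loss, plus the weighted
#' smoothness penalty, together with the train's relative SAR. Optionally
#' returns the analytic gradient with respect to the flip angles, obtained by
#' chaining the EPG Jacobian with closed-form derivatives of the image- and
#' PSF-domain losses.
#'
#' @param descr,protocol,table,weights,psf_table,target_spec as in
#'   [loss_context()]; ignored when a prebuilt `context` is supplied.
#' @param alpha flip-angle train in degrees.
#' @param gradient logical; attach the gradient (per degree) as attribute
#'   `"gradient"`.
#' @param context optional [loss_context()] for repeated evaluations.
#' @return Object of class `loss_breakdown` with fields `L1`, `L_PSF`, `R`,
#'   `total` (`= w*L_PSF + (1-w)*L1 + lambda_R*R`) and `rSAR`.
#' @export
total_loss <- function(descr, alpha, protocol, table, weights,
                       psf_table = NULL,
                       target_spec = list(TE = 45, TR = 6000),
                       gradient = FALSE, context = NULL) {
  ctx <- context %||% loss_context(descr, protocol, table, weights,
                                   psf_table = psf_table,
                                   target_spec = target_spec)
  w <- ctx$weights$w
  lam <- ctx$weights$lambda_R
  cTRG <- ctx$weights$cTRG
  ETL <- ctx$protocol$ETL

  sig <- lapply(ctx$descr$tissues, function(t)
    epg_fse_signal(alpha, t, ctx$protocol, gradient = gradient))

  ## ---- L1 contrast loss through the linear image model: the combined
  ## k-space is the per-line signal amplitude times each mask's k-space
  kcomb <- 0i
  for (ti in seq_along(ctx$tnames)) {
    mtf_img <- sig[[ti]]$S[ctx$table$echo_of_line]
    kcomb <- kcomb + sweep(ctx$kmasks[[ti]], 2, mtf_img, `*`)
  }
  r <- ifft2c(kcomb)
  m <- Mod(r)
  resid <- m - cTRG * ctx$target
  L1 <- mean(abs(resid))

  ## ---- PSF loss over the (possibly full-length) PSF table. Each tissue's
  ## MTF is normalised to unit mean first: the penalty targets the blurring
  ## shape (relative side bands); an unnormalised penalty would be minimised
  ## by simply extinguishing the signal.
  cT <- tissue_weights(ctx$weights$cT, ctx$tnames)
  ny_psf <- ctx$psf_table$Ny
  c0 <- centre_index(ny_psf)
  L_PSF <- 0
  u_list <- vector("list", length(ctx$tnames))
  mu_list <- numeric(length(ctx$tnames))
  mtfn_list <- vector("list", length(ctx$tnames))
  for (ti in seq_along(ctx$tnames)) {
    mtf <- sig[[ti]]$S[ctx$psf_table$echo_of_line]
    mu <- max(mean(mtf), 1e-12)
    mtfn <- mtf / mu
    u <- fft1c(mtfn)
    u_list[[ti]] <- u
    mu_list[ti] <- mu
    mtfn_list[[ti]] <- mtfn
    v <- Mod(u); v[c0] <- 0
    L_PSF <- L_PSF + cT[ti] * sum(v) / ny_psf
  }

  R <- smoothness_penalty(alpha)
  out <- structure(list(L1 = L1, L_PSF = L_PSF, R = R,
                        total = w * L_PSF + (1 - w) * L1 + lam * R,
                        rSAR = relative_sar(alpha)),
                   class = "loss_breakdown")

  if (isTRUE(gradient)) {
    g <- lam * smoothness_grad(alpha)
    ## dL1/dr pulled back through the unitary transform to k-space, then
    ## collapsed per PE line against each mask's k-space
    u_img <- (sign(resid) / ctx$nvox) * ifelse(m > 0, 1, 0) * r /
      ifelse(m > 0, m, 1)
    uk <- fft2c(u_img)
    for (ti in seq_along(ctx$tnames)) {
      gline <- Re(colSums(Conj(uk) * ctx$kmasks[[ti]]))
      gS <- (1 - w) * rowsum_by(gline, ctx$table$echo_of_line, ETL)
      ## dL_PSF/dS: adjoint of the centred unitary DFT on the masked phase,
      ## then the chain rule through the unit-mean normalisation
      u <- u_list[[ti]]
      mu_u <- Mod(u)
      vv <- ifelse(mu_u > 0, 1 / mu_u, 0) * u
      vv[c0] <- 0i
      gn <- Re(ifft1c(vv)) * cT[ti] / ny_psf
      gmtf <- (gn - mean(gn * mtfn_list[[ti]])) / mu_list[ti]
      gS <- gS + w * rowsum_by(gmtf, ctx$psf_table$echo_of_line, ETL)
      g <- g + as.vector(crossprod(sig[[ti]]$J, gS))
    }
    attr(out, "gradient") <- g
  }
  out
}

rowsum_by <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss: total=%.6g  (L1=%.6g, L_PSF=%.6g, R=%.6g)  rel.SAR=%.4f\n",
              x$total, x$L1, x$L_PSF, x$R, x$rSAR))
  invisible(x)
}
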