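#' Tissue-averaged dark-fluid unencoded signal
#'
#' Emulates the unencoded echo-train measurement (no phase/partition
#' encoding) used to quantify PSF blurring: the per-tissue EPG signal
#' responses are averaged with weights `voxel fraction x |inversion-recovery
#' weight|`, where the IR weight [csf_null_weight()] at the dark-fluid `TI`
#' attenuates long-T1 fluid so that most of the signal originates from white
#' and grey matter. (Each tissue's response already carries its M0.)
#'
#' @param descr an [object_descriptor()].
#' @param alpha flip-angle train in degrees.
#' @param protocol a [sequence_protocol()] (without inversion; the IR
#'   preparation enters through the recovery weight).
#' @param TI inversion time of the dark-fluid preparation in ms.
#' @param tr_cycling logical; include the steady-state `exp(-TR/T1)` term in
#'   the IR weight (default TRUE, appropriate for TR-periodic acquisitions).
#' @return A `signal_response` whose `S` is the weighted tissue average.
#' @export
simulate_unencoded_signal <- function(descr, alpha, protocol, TI,
                                      tr_cycling = TRUE) {
  if (!inherits(descr, "object_descriptor"))
    stopf("'descr' must be an object_descriptor")
  counts <- vapply(descr$masks, sum, numeric(1))
  frac <- counts / sum(counts)
  S <- numeric(protocol$ETL)
  for (nm in names(descr$tissues)) {
    t <- descr$tissues[[nm]]
    wIR <- abs(csf_null_weight(t, TI, protocol$TR, tr_cycling = tr_cycling))
    S <- S + frac[[nm]] * wIR * epg_fse_signal(alpha, t, protocol)$S
  }
  structure(list(S = S, alpha = as.numeric(alpha), tissue = "tissue-average",
                 ETL = protocol$ETL),
            class = "signal_response")
}

#' PSF residual error against the uniform-signal reference
#'
#' Normalises the signal to unit mean, maps it onto PE lines through the
#' sampling table, Fourier-transforms to the PSF and measures the normalised
#' L1 distance to the reference PSF of a constant (all-ones) signal -- a
#' discrete delta, the ideal decay-free response:
#' `ERR = sum(|PSF_REF - PSF_VFA|) / sum(|PSF_REF|)`.
#'
#' Both PSFs are compared as unit-L1 profiles (each divided by its own
#' absolute sum), so the error measures the fraction of point-spread mass
#' displaced into side bands and is bounded by 2; it is invariant under
#' global rescaling of the signal. The raw (amplitude-carrying) comparison is
#' available with `normalize = "none"`.
#'
#' @param S a `signal_response` or numeric vector of per-echo amplitudes.
#' @param table a [linear_view_ordering()] sampling table.
#' @param normalize `"l1"` (default): compare unit-L1 PSF profiles;
#'   `"none"`: compare the PSFs of the unit-mean signal and the all-ones
#'   reference directly.
#' @return Non-negative scalar; 0 for a perfectly uniform signal.
#' @export
psf_error <- function(S, table, normalize = c("l1", "none")) {
  normalize <- match.arg(normalize)
  s <- if (inherits(S, "signal_response")) S$S else as.numeric(S)
  if (all(s == 0)) stopf("cannot compute the PSF error of an all-zero signal")
  if (any(s < 0)) stopf("signal amplitudes must be non-negative")
  s <- s / mean(s)
  psf <- psf_from_mtf(mtf_from_signal(s, table))$values
  ref <- psf_from_mtf(rep(1, table$Ny))$values
  if (normalize == "l1") {
    psf <- psf / sum(psf)
    ref <- ref / sum(ref)
  }
  sum(abs(ref - psf)) / sum(abs(ref))
}

#' Pseudo-replica Monte-Carlo SNR map
#'
#' Estimates a per-voxel SNR map by the pseudo-replica method: the k-space
#' data are pre-whitened with the channel noise covariance, `n_rep` copies are
#' superimposed with independent complex Gaussian noise of unit level (SD 1
#' per real/imaginary component and channel), each copy is reconstructed by a
#' unitary inverse Fourier transform (root-sum-of-squares across channels),
#' and SNR(k) = mean/SD over the replicas at voxel k.
#'
#' @param kspace complex matrix (single channel) or a list of complex
#'   matrices (one per channel).
#' @param noise_covariance channel covariance matrix (symmetric positive
#'   definite); identity when `NULL`.
#' @param n_rep number of replicas, >= 2.
#' @param seed integer seed; identical seeds give identical maps. The session
#'   RNG state is left untouched.
#' @return Object of class `snr_map`: `map` (SNR), `mean`, `sd`, `n_rep`,
#'   `seed`.
#' @export
pseudo_replica_snr <- function(kspace, noise_covariance = NULL, n_rep = 100,
                               seed = 1) {
  if (is.matrix(kspace)) kspace <- list(kspace)
  if (!is.list(kspace) || !all(vapply(kspace, is.matrix, logical(1))))
    stopf("'kspace' must be a complex matrix or a list of matrices")
  nch <- length(kspace)
  dims <- dim(kspace[[1]])
  if (!all(vapply(kspace, function(k) identical(dim(k), dims), logical(1))))
    stopf("all channels must share one k-space shape")
  if (any(!vapply(kspace, function(k) all(is.finite(Mod(k))), logical(1))))
    stopf("k-space data must be finite")
  check_number(n_rep, "n_rep", lower = 2)
  n_rep <- as.integer(n_rep)

  if (!is.null(noise_covariance)) {
    C <- as.matrix(noise_covariance)
    if (nrow(C) != nch || ncol(C) != nch)
      stopf("noise covariance must be %d x %d", nch, nch)
    if (max(abs(C - t(C))) > 1e-10) stopf("noise covariance must be symmetric")
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stopf("noise covariance must be positive definite")
    Linv <- solve(t(chol(C)))          # whitening transform
    kmat <- sapply(kspace, as.vector)  # voxels x channels
    kmat <- kmat %*% t(Linv)
    kspace <- lapply(seq_len(nch), function(c) matrix(kmat[, c], dims[1], dims[2]))
  }

  with_seed(seed, {
    npt <- prod(dims)
    s1 <- matrix(0, dims[1], dims[2])
    s2 <- matrix(0, dims[1], dims[2])
    for (r in seq_len(n_rep)) {
      sos <- matrix(0, dims[1], dims[2])
      for (c in seq_len(nch)) {
        noise <- matrix(complex(real = stats::rnorm(npt),
                                imaginary = stats::rnorm(npt)),
                        dims[1], dims[2])
        img <- ifft2c(kspace[[c]] + noise)
        sos <- sos + Mod(img)^2
      }
      rec <- sqrt(sos)
      s1 <- s1 + rec
      s2 <- s2 + rec^2
    }
    mu <- s1 / n_rep
    va <- pmax(s2 / n_rep - mu^2, 0) * n_rep / (n_rep - 1)
    sd <- sqrt(va)
    structure(list(map = ifelse(sd > 0, mu / sd, Inf), mean = mu, sd = sd,
                   n_rep = n_rep, seed = as.integer(seed)),
              class = "snr_map")
  })
}

#' Contrast-to-noise ratio between two ROIs
#'
#' `CNR = (mean_A - mean_B) / sigma_A`, with `sigma_A` the pseudo-replica
#' noise SD in ROI A.
#'
#' @param image numeric matrix (magnitude image) or `sim_image`.
#' @param roiA,roiB logical matrices (non-empty ROI masks).
#' @param sigmaA noise SD in ROI A (> 0), e.g. the mean of an [
#'   pseudo_replica_snr()] `sd` map over `roiA`.
#' @return Signed scalar.
#' @export
cnr <- function(image, roiA, roiB, sigmaA) {
  img <- if (inherits(image, "sim_image")) image$image else as.matrix(image)
  if (!any(roiA) || !any(roiB)) stopf("ROIs must be non-empty")
  check_number(sigmaA, "sigmaA", lower = .Machine$double.eps)
  (mean(img[roiA]) - mean(img[roiB])) / sigmaA
}
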