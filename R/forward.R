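#' Simulate the FSE image of an object
#'
#' Forms, for each echo, the composite image of all tissue amplitudes
#' (`sum_T S_T[echo] * mask_T`; the signal responses already carry each
#' tissue's M0), transforms it to k-space, keeps the PE lines the sampling
#' table assigns to that echo, sums the lines into one combined FSE k-space
#' and reconstructs by inverse Fourier transform. All transforms are unitary
#' and centred.
#'
#' @param descr an [object_descriptor()].
#' @param alpha flip-angle train in degrees (ignored when `signals` given).
#' @param protocol a [sequence_protocol()].
#' @param table a [linear_view_ordering()] table with `Ny` equal to the second
#'   (PE) grid dimension of `descr`.
#' @param signals optional named list of per-tissue `signal_response` objects
#'   (or numeric vectors) to reuse instead of re-running the EPG simulation.
#' @return Object of class `sim_image`: magnitude `image` (Nx x Ny),
#'   `complex_image`, combined `kspace`, and the `table` used.
#' @export
simulate_fse_image <- function(descr, alpha = NULL, protocol = NULL, table,
                               signals = NULL) {
  if (!inherits(descr, "object_descriptor"))
    stopf("'descr' must be an object_descriptor")
  if (!inherits(table, "sampling_table")) stopf("'table' must be a sampling_table")
  if (table$Ny != descr$grid_shape[2])
    stopf("table Ny (%d) must equal the PE grid dimension (%d)",
          table$Ny, descr$grid_shape[2])
  if (is.null(signals)) {
    if (is.null(alpha) || is.null(protocol))
      stopf("either 'signals' or both 'alpha' and 'protocol' must be given")
    signals <- lapply(descr$tissues, function(t)
      epg_fse_signal(alpha, t, protocol))
  }
  svec <- lapply(signals, function(s)
    if (inherits(s, "signal_response")) s$S else as.numeric(s))
  need <- max(table$echo_of_line)
  if (any(vapply(svec, length, 1L) < need))
    stopf("signal responses are shorter than echo %d required by the table", need)

  nx <- descr$grid_shape[1]; ny <- descr$grid_shape[2]
  kcomb <- matrix(0i, nx, ny)
  for (e in unique(table$echo_of_line)) {
    img <- matrix(0, nx, ny)
    for (nm in names(descr$tissues))
      img <- img + svec[[nm]][e] * descr$masks[[nm]]
    ke <- fft2c(img)
    cols <- which(table$echo_of_line == e)
    kcomb[, cols] <- ke[, cols]
  }
  cimg <- ifft2c(kcomb)
  structure(list(image = Mod(cimg), complex_image = cimg, kspace = kcomb,
                 table = table),
            class = "sim_image")
}

#' Mono-exponential spin-echo target image
#'
#' The contrast target used by the SNR/contrast loss: each tissue voxel is
#' assigned `M0 * (1 - exp(-TR/T1)) * exp(-TE/T2)` (the saturation factor can
#' be disabled to obtain a pure mono-exponential decay). Tissues listed in
#' `suppressed_tissues` are set to zero, emulating fluid suppression in the
#' dark-fluid/FLAIR target.
#'
#' @param descr an [object_descriptor()].
#' @param TE,TR target contrast settings in ms, > 0.
#' @param suppressed_tissues character vector of tissue names set to zero.
#' @param include_t1_weighting logical; keep the `1 - exp(-TR/T1)` factor.
#' @return Numeric matrix of the grid shape.
#' @export
spin_echo_target <- function(descr, TE, TR, suppressed_tissues = character(),
                             include_t1_weighting = TRUE) {
  if (!inherits(descr, "object_descriptor"))
    stopf("'descr' must be an object_descriptor")
  check_number(TE, "TE", lower = 0)
  check_number(TR, "TR", lower = .Machine$double.eps)
  bad <- setdiff(suppressed_tissues, names(descr$tissues))
  if (length(bad)) stopf("unknown suppressed tissue(s): %s",
                         paste(bad, collapse = ", "))
  img <- matrix(0, descr$grid_shape[1], descr$grid_shape[2])
  for (nm in names(descr$tissues)) {
    if (nm %in% suppressed_tissues) next
    t <- descr$tissues[[nm]]
    v <- t$M0 * exp(-TE / t$T2)
    if (include_t1_weighting) v <- v * (1 - exp(-TR / t$T1))
    img <- img + v * descr$masks[[nm]]
  }
  img
}
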