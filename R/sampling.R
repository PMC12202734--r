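#' Linear view ordering with nearest-echo fill
#'
#' Assigns echoes to phase-encode (PE) lines for a linearly ordered
#' acquisition: echo `i` samples the line `center_line + (i - center_echo) *
#' acceleration`, so echo numbers increase monotonically across PE and the
#' k-space centre line (index `floor(Ny/2) + 1`, matching the centred DFT
#' convention) is acquired by `center_echo`. Lines that are not directly
#' sampled -- either because of undersampling (`acceleration > 1`) or because
#' the echo falls outside the train -- inherit the echo number of the nearest
#' sampled line; equidistant ties go to the lower line index.
#'
#' @param Ny number of PE lines (matrix size in the PE direction).
#' @param ETL echo-train length.
#' @param center_echo echo index (1-based) assigned to the k-space centre.
#' @param acceleration integer undersampling factor (line spacing between
#'   consecutively sampled lines).
#' @return Object of class `sampling_table`: integer vector `echo_of_line`
#'   (length Ny, values in `[1, ETL]`), logical `sampled_mask`, `center_line`,
#'   `Ny`, `ETL`, `center_echo`, `acceleration`.
#' @examples
#' tab <- linear_view_ordering(Ny = 200, ETL = 200, center_echo = 100)
#' tab$echo_of_line[tab$center_line]  # 100
#' @export
linear_view_ordering <- function(Ny, ETL, center_echo, acceleration = 1) {
  check_number(Ny, "Ny", lower = 2)
  check_number(ETL, "ETL", lower = 1)
  check_number(acceleration, "acceleration", lower = 1)
  Ny <- as.integer(Ny); ETL <- as.integer(ETL)
  acceleration <- as.integer(acceleration)
  if (!is.numeric(center_echo) || length(center_echo) != 1L ||
      center_echo < 1 || center_echo > ETL)
    stopf("'center_echo' must lie in [1, %d]", ETL)
  center_echo <- as.integer(center_echo)
  center_line <- centre_index(Ny)

  echoes <- seq_len(ETL)
  lines <- center_line + (echoes - center_echo) * acceleration
  keep <- lines >= 1L & lines <= Ny
  if (!any(keep)) stopf("no echo maps into the PE line range")
  lines <- lines[keep]; echoes <- echoes[keep]

  echo_of_line <- integer(Ny)
  sampled <- logical(Ny)
  echo_of_line[lines] <- echoes
  sampled[lines] <- TRUE
  for (l in which(!sampled)) {
    d <- abs(lines - l)
    cand <- lines[d == min(d)]
    echo_of_line[l] <- echo_of_line[min(cand)]
  }
  structure(list(echo_of_line = echo_of_line, sampled_mask = sampled,
                 center_line = center_line, Ny = Ny, ETL = ETL,
                 center_echo = center_echo, acceleration = acceleration),
            class = "sampling_table")
}

#' @export
print.sampling_table <- function(x, ...) {
  cat(sprintf(
    "sampling table: Ny=%d, ETL=%d, centre line %d <- echo %d, R=%d (%d lines sampled)\n",
    x$Ny, x$ETL, x$center_line, x$center_echo, x$acceleration,
    sum(x$sampled_mask)))
  invisible(x)
}

#' Modulation transfer function from a signal response
#'
#' Maps the per-echo amplitudes onto PE lines through the sampling table:
#' `MTF[line] = S[echo_of_line[line]]`.
#'
#' @param S a `signal_response` or a numeric vector of per-echo amplitudes.
#' @param table a [linear_view_ordering()] sampling table.
#' @return Numeric vector of length `table$Ny`.
#' @export
mtf_from_signal <- function(S, table) {
  s <- if (inherits(S, "signal_response")) S$S else as.numeric(S)
  if (!inherits(table, "sampling_table")) stopf("'table' must be a sampling_table")
  if (max(table$echo_of_line) > length(s))
    stopf("the sampling table needs echo %d but only %d amplitudes were given",
          max(table$echo_of_line), length(s))
  s[table$echo_of_line]
}

#' Point-spread function of an MTF
#'
#' Magnitude of the centred unitary discrete Fourier transform of the MTF.
#' The k-space centre line maps to the profile centre `floor(Ny/2) + 1`; a
#' uniform MTF yields a discrete delta there (the reference PSF of an ideal,
#' decay-free acquisition -- the discrete analogue of a sinc).
#'
#' @param mtf numeric vector over PE lines (length >= 2).
#' @return Object of class `psf_profile`: numeric `values` (non-negative,
#'   length Ny) and `center` index.
#' @export
psf_from_mtf <- function(mtf) {
  mtf <- as.numeric(mtf)
  if (length(mtf) < 2L) stopf("'mtf' must have at least 2 lines")
  structure(list(values = Mod(fft1c(mtf)), center = centre_index(length(mtf))),
            class = "psf_profile")
}
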