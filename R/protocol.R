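#' FSE sequence protocol
#'
#' Bundle of the timing parameters of a 3D fast-spin-echo acquisition that the
#' EPG simulation and the image model need: echo-train length, echo spacing,
#' repetition time, the echo assigned to the k-space centre (which fixes the
#' effective TE), and an optional inversion preparation for dark-fluid (FLAIR)
#' contrast.
#'
#' Either `TE_eff` or `center_echo` can be given; the other is derived via
#' `TE_eff = center_echo * ESP`. When both are supplied they must agree to
#' within half an echo spacing.
#'
#' @param ETL echo-train length (number of refocusing pulses), >= 1.
#' @param ESP echo spacing in ms, > 0.
#' @param TR repetition time in ms; must accommodate the whole train (and the
#'   inversion delay, when present).
#' @param TE_eff effective echo time in ms (TE of the k-space-centre echo).
#' @param center_echo index (1-based) of the echo that samples the k-space
#'   centre line.
#' @param excitation_fa excitation flip angle in degrees (default 90).
#' @param inversion logical; prepend an ideal 180 degree inversion pulse
#'   followed by a delay `TI` of pure T1 recovery before the excitation.
#' @param TI inversion time in ms (required when `inversion = TRUE`).
#' @return An object of class `sequence_protocol`.
#' @examples
#' p <- sequence_protocol(ETL = 200, ESP = 3.8, TR = 3200, TE_eff = 380)
#' p$center_echo  # 100
#' @export
sequence_protocol <- function(ETL, ESP, TR, TE_eff = NULL, center_echo = NULL,
                              excitation_fa = 90, inversion = FALSE,
                              TI = NULL) {
  check_number(ETL, "ETL", lower = 1)
  check_number(ESP, "ESP", lower = .Machine$double.eps)
  check_number(TR, "TR", lower = .Machine$double.eps)
  check_number(excitation_fa, "excitation_fa", lower = 0, upper = 180)
  ETL <- as.integer(ETL)
  if (is.null(center_echo) && is.null(TE_eff))
    stopf("one of 'TE_eff' or 'center_echo' must be given")
  if (is.null(center_echo)) center_echo <- round(TE_eff / ESP)
  check_number(center_echo, "center_echo", lower = 1, upper = ETL)
  center_echo <- as.integer(center_echo)
  if (!is.null(TE_eff) && abs(TE_eff - center_echo * ESP) > ESP / 2)
    stopf("'TE_eff' (%.1f ms) is inconsistent with center_echo * ESP (%.1f ms)",
          TE_eff, center_echo * ESP)
  TE_eff <- center_echo * ESP
  if (ETL * ESP > TR)
    stopf("echo train (%.1f ms) does not fit into TR (%.1f ms)", ETL * ESP, TR)
  if (inversion) {
    if (is.null(TI)) stopf("'TI' is required when inversion = TRUE")
    check_number(TI, "TI", lower = .Machine$double.eps)
    if (TI >= TR) stopf("'TI' (%.1f ms) must be smaller than TR (%.1f ms)",
                        TI, TR)
  } else {
    TI <- NULL
  }
  structure(list(ETL = ETL, ESP = ESP, TR = TR, TE_eff = TE_eff,
                 center_echo = center_echo, excitation_fa = excitation_fa,
                 inversion = isTRUE(inversion), TI = TI),
            class = "sequence_protocol")
}

#' @export
print.sequence_protocol <- function(x, ...) {
  cat(sprintf("FSE protocol: ETL=%d, ESP=%.2f ms, TR=%.0f ms, TE_eff=%.1f ms (echo %d)\n",
              x$ETL, x$ESP, x$TR, x$TE_eff, x$center_echo))
  if (x$inversion)
    cat(sprintf("  inversion preparation: TI=%.0f ms\n", x$TI))
  invisible(x)
}
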