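## Extended phase graph (EPG) simulation of the FSE echo train.
##
## Convention: configuration states F+(k), F-(k), Z(k) for dephasing orders
## k = 0..K, with F-(k) storing the complex conjugate of F(-k). The CPMG
## condition is realised with a 90 degree excitation about +y and refocusing
## pulses about +x, which keeps echo amplitudes real and non-negative for
## symmetric trains. One unit of gradient dephasing is applied per half echo
## spacing (crusher model), with relaxation split into the same halves.

rf_matrix <- function(fa_rad, phase_rad) {
  a <- fa_rad; p <- phase_rad
  e1 <- exp(1i * p); e2 <- e1^2
  matrix(c(
    cos(a / 2)^2,            sin(a / 2)^2 / e2,       -0.5i * sin(a) / e1,
    e2 * sin(a / 2)^2,       cos(a / 2)^2,            0.5i * e1 * sin(a),
    -1i * e1 * sin(a),       1i * sin(a) / e1,        cos(a)
  ), nrow = 3L)
  # columns applied to (F+, F-, Z); filled column-major above
}

#' Initialise an EPG state at thermal equilibrium
#'
#' @param K truncation order: states k = 0..K are tracked.
#' @param M0 equilibrium magnetisation (relative proton density).
#' @return Object of class `epg_state`: complex vectors `Fp`, `Fm`, `Z`
#'   (length K + 1) and the scalar `M0` used for T1 regrowth.
#' @export
epg_init <- function(K, M0 = 1) {
  check_number(K, "K", lower = 1)
  check_number(M0, "M0", lower = 0)
  z <- complex(real = numeric(K + 1))
  z[1] <- M0
  structure(list(Fp = complex(real = numeric(K + 1)),
                 Fm = complex(real = numeric(K + 1)),
                 Z = z, M0 = M0),
            class = "epg_state")
}

epg_rf <- function(state, fa_rad, phase_rad) {
  Tm <- rf_matrix(fa_rad, phase_rad)
  Fp <- Tm[1, 1] * state$Fp + Tm[1, 2] * state$Fm + Tm[1, 3] * state$Z
  Fm <- Tm[2, 1] * state$Fp + Tm[2, 2] * state$Fm + Tm[2, 3] * state$Z
  Z  <- Tm[3, 1] * state$Fp + Tm[3, 2] * state$Fm + Tm[3, 3] * state$Z
  state$Fp <- Fp; state$Fm <- Fm; state$Z <- Z
  state
}

epg_relax_shift <- function(state, E1, E2) {
  K1 <- length(state$Fp)
  Fp <- state$Fp * E2
  Fm <- state$Fm * E2
  Z <- state$Z * E1
  Z[1] <- Z[1] + state$M0 * (1 - E1)
  Fp <- c(0i, Fp[-K1])              # F+ dephases one order up
  Fm <- c(Fm[-1], 0i)               # F- moves one order down
  Fp[1] <- Conj(Fm[1])
  state$Fp <- Fp; state$Fm <- Fm; state$Z <- Z
  state
}

#' One EPG refocusing interval
#'
#' Advances an EPG state through one echo spacing: half-interval relaxation
#' and unit gradient dephasing, the refocusing pulse, then the second
#' half-interval of relaxation and dephasing. The echo forms at the end of the
#' interval as the zeroth transverse state `Fp[1]`.
#'
#' @param state an `epg_state` from [epg_init()] or a previous step.
#' @param fa refocusing flip angle in degrees, in `[0, 180]`.
#' @param phase RF phase in degrees (0 = about +x, the CPMG choice when the
#'   excitation was about +y).
#' @param E1,E2 longitudinal/transverse relaxation factors over *half* an echo
#'   spacing, in (0, 1].
#' @return The updated `epg_state`.
#' @examples
#' st <- epg_init(K = 8)
#' st <- epg_rf_excite(st)                  # 90 degrees about +y
#' st <- epg_step(st, 180, 0, 1, 1)
#' Mod(st$Fp[1])                            # 1: perfect refocusing
#' @export
epg_step <- function(state, fa, phase = 0, E1, E2) {
  if (!inherits(state, "epg_state")) stopf("'state' must be an epg_state")
  check_number(fa, "fa", lower = 0, upper = 180)
  check_number(E1, "E1", lower = .Machine$double.eps, upper = 1)
  check_number(E2, "E2", lower = .Machine$double.eps, upper = 1)
  state <- epg_relax_shift(state, E1, E2)
  state <- epg_rf(state, fa * pi / 180, phase * pi / 180)
  epg_relax_shift(state, E1, E2)
}

#' Ideal excitation pulse for the CPMG condition
#'
#' Applies the excitation (default 90 degrees about +y, i.e. phase 90 degrees)
#' to an EPG state.
#'
#' @param state an `epg_state`.
#' @param fa excitation flip angle in degrees.
#' @param phase excitation phase in degrees.
#' @return The updated `epg_state`.
#' @export
epg_rf_excite <- function(state, fa = 90, phase = 90) {
  check_number(fa, "fa", lower = 0, upper = 180)
  epg_rf(state, fa * pi / 180, phase * pi / 180)
}

#' EPG signal response of a flip-angle train
#'
#' Simulates the per-echo signal amplitudes of one tissue for a refocusing
#' flip-angle train: optional ideal inversion followed by a delay `TI` of pure
#' T1 recovery, excitation, then `ETL` refocusing pulses spaced `ESP` apart
#' with relaxation and unit crusher dephasing in each half interval. The
#' amplitude of echo i is the magnitude of the zeroth transverse configuration
#' state, proportional to the tissue's M0.
#'
#' With `gradient = TRUE` the full Jacobian `dS/dalpha` is propagated through
#' every EPG operator alongside the state (forward-mode differentiation) and
#' returned in units of 1/degree.
#'
#' @param alpha refocusing flip angles in degrees, length `protocol$ETL`.
#' @param tissue a [tissue_params()] object.
#' @param protocol a [sequence_protocol()].
#' @param gradient logical; also return the Jacobian.
#' @param K state truncation order (default `ETL + 1`, which is exact for
#'   `ETL` refocusing intervals).
#' @return Object of class `signal_response`: numeric vector `S` (length ETL,
#'   non-negative) and, when requested, matrix `J` with `J[i, j] = dS_i /
#'   dalpha_j` per degree.
#' @examples
#' wm <- default_tissue_params()$WM
#' p <- sequence_protocol(ETL = 32, ESP = 3.8, TR = 3200, center_echo = 16)
#' s <- epg_fse_signal(rep(120, 32), wm, p)
#' head(s$S)
#' @export
epg_fse_signal <- function(alpha, tissue, protocol, gradient = FALSE,
                           K = NULL) {
  if (!inherits(tissue, "tissue_params")) stopf("'tissue' must be tissue_params")
  if (!inherits(protocol, "sequence_protocol"))
    stopf("'protocol' must be a sequence_protocol")
  alpha <- as.numeric(alpha)
  if (length(alpha) != protocol$ETL)
    stopf("'alpha' has %d angles but the protocol's ETL is %d",
          length(alpha), protocol$ETL)
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 180))
    stopf("all flip angles must lie in [0, 180] degrees")
  if (is.null(K)) K <- protocol$ETL + 1L
  check_number(K, "K", lower = 1)

  half <- protocol$ESP / 2
  E1h <- exp(-half / tissue$T1)
  E2h <- exp(-half / tissue$T2)
  E1ti <- if (protocol$inversion) exp(-protocol$TI / tissue$T1) else 1

  res <- epg_fse_train_cpp(alpha * pi / 180,
                           protocol$excitation_fa * pi / 180,
                           pi / 2, 0,
                           E1h, E2h, tissue$M0,
                           protocol$inversion, E1ti,
                           as.integer(K), isTRUE(gradient))
  out <- list(S = as.numeric(res$S), alpha = alpha,
              tissue = tissue$name, ETL = protocol$ETL)
  if (isTRUE(gradient)) out$J <- res$J * pi / 180
  structure(out, class = "signal_response")
}

#' Longitudinal weight after inversion recovery
#'
#' Fraction of the equilibrium longitudinal magnetisation available at the
#' excitation pulse after an ideal 180 degree inversion and a recovery delay
#' `TI`: `1 - 2 exp(-TI/T1)`, optionally with the steady-state TR-cycling
#' correction `+ exp(-TR/T1)`. Zero at the tissue's null point
#' `TI = T1 log(2)`; used to attenuate tissue contributions when simulating
#' dark-fluid (CSF-suppressed) unencoded signals.
#'
#' @param tissue a [tissue_params()] object.
#' @param TI inversion time in ms.
#' @param TR repetition time in ms; must exceed `TI`.
#' @param tr_cycling logical; include the `exp(-TR/T1)` steady-state term.
#' @return Signed scalar weight (can be negative before the null point).
#' @examples
#' wm <- default_tissue_params()$WM
#' csf_null_weight(wm, TI = wm$T1 * log(2), TR = 1e7)  # ~0
#' @export
csf_null_weight <- function(tissue, TI, TR, tr_cycling = FALSE) {
  if (!inherits(tissue, "tissue_params")) stopf("'tissue' must be tissue_params")
  check_number(TI, "TI", lower = 0)
  check_number(TR, "TR", lower = 0)
  if (TI >= TR) stopf("'TI' must be smaller than 'TR'")
  w <- 1 - 2 * exp(-TI / tissue$T1)
  if (isTRUE(tr_cycling)) w <- w + exp(-TR / tissue$T1)
  w
}

#' @export
print.signal_response <- function(x, ...) {
  cat(sprintf("signal response (%s), ETL=%d, S in [%.4g, %.4g]\n",
              x$tissue, x$ETL, min(x$S), max(x$S)))
  invisible(x)
}
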