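#' Three-part target signal specification
#'
#' The heuristic "standard" VFA design drives the echo-train signal toward a
#' three-part target: (1) an exponential (asymptotic) approach from the
#' natural first-echo amplitude down to a pseudo-steady-state plateau, (2) a
#' constant plateau held until the k-space centre echo, and (3) a linear
#' flip-angle ramp up to `max_fa` over the remaining echoes (the third segment
#' constrains flip angles, not signal amplitudes).
#'
#' @param plateau_level pseudo-steady-state amplitude as a fraction of M0,
#'   in (0, 1).
#' @param center_echo last plateau echo (the k-space-centre echo).
#' @param max_fa ramp endpoint in degrees, <= 180.
#' @param approach_length number of echoes in the asymptotic approach.
#' @param approach_rate exponential constant of the approach, in echoes. The
#'   default (2) drops the target to the plateau within a few echoes, which
#'   parks magnetisation longitudinally early -- a slow approach keeps the
#'   demanded signal high for so long that the plateau becomes unsustainable.
#' @return Object of class `target_signal_spec`.
#' @export
target_signal_spec <- function(plateau_level, center_echo, max_fa = 120,
                               approach_length = 20, approach_rate = 2) {
  check_number(plateau_level, "plateau_level",
               lower = .Machine$double.eps, upper = 1 - 1e-12)
  check_number(center_echo, "center_echo", lower = 1)
  check_number(max_fa, "max_fa", lower = 0, upper = 180)
  check_number(approach_length, "approach_length", lower = 0)
  check_number(approach_rate, "approach_rate", lower = .Machine$double.eps)
  structure(list(plateau_level = plateau_level,
                 center_echo = as.integer(center_echo), max_fa = max_fa,
                 approach_length = as.integer(approach_length),
                 approach_rate = approach_rate),
            class = "target_signal_spec")
}

#' Three-part target signal
#'
#' Evaluates the target amplitudes of the first two segments; ramp-region
#' echoes (after `center_echo`) are marked rather than assigned an amplitude,
#' since the third segment is defined on flip angles.
#'
#' @param spec a [target_signal_spec()].
#' @param ETL echo-train length.
#' @param first_level amplitude the approach starts from (fraction of M0);
#'   defaults to the plateau (i.e. no transient) when `approach_length = 0`.
#' @return List with `signal` (length ETL; `NA` in the ramp region) and
#'   logical `ramp`.
#' @export
three_part_target <- function(spec, ETL, first_level = NULL) {
  if (!inherits(spec, "target_signal_spec"))
    stopf("'spec' must be a target_signal_spec")
  check_number(ETL, "ETL", lower = 1)
  ETL <- as.integer(ETL)
  if (spec$center_echo > ETL)
    stopf("center_echo (%d) exceeds ETL (%d)", spec$center_echo, ETL)
  i <- seq_len(ETL)
  sig <- rep(spec$plateau_level, ETL)
  if (spec$approach_length > 0) {
    if (is.null(first_level)) first_level <- 1
    ap <- i <= spec$approach_length
    sig[ap] <- spec$plateau_level +
      (first_level - spec$plateau_level) * exp(-(i[ap] - 1) / spec$approach_rate)
  }
  ramp <- i > spec$center_echo
  sig[ramp] <- NA_real_
  list(signal = sig, ramp = ramp)
}

## next-echo amplitude if flip angle `fa` (deg) is applied to `state`
next_echo_amplitude <- function(state, fa, E1, E2) {
  Mod(epg_step(state, fa, 0, E1, E2)$Fp[1])
}

#' Standard prospective VFA scheme
#'
#' Computes the heuristic baseline flip-angle train by prospective EPG: for
#' each echo up to the k-space centre, the refocusing angle is found by
#' one-dimensional root search so that the forward EPG step emits the
#' three-part target amplitude (when the target is unreachable, the
#' amplitude-maximising angle is used); after the centre echo the angles
#' increase linearly to `max_fa` at the last echo.
#'
#' @param spec a [target_signal_spec()].
#' @param tissue the design tissue (classically white matter, T1 = 1500 ms,
#'   T2 = 50 ms).
#' @param protocol a [sequence_protocol()].
#' @return Object of class `prospective_vfa`: `alpha` (degrees), the
#'   forward-simulated `signal`, the `target` amplitudes, and logical
#'   `reached` marking echoes where the root search met the target.
#' @export
prospective_vfa <- function(spec, tissue, protocol) {
  if (!inherits(spec, "target_signal_spec"))
    stopf("'spec' must be a target_signal_spec")
  if (!inherits(tissue, "tissue_params")) stopf("'tissue' must be tissue_params")
  if (!inherits(protocol, "sequence_protocol"))
    stopf("'protocol' must be a sequence_protocol")
  ETL <- protocol$ETL
  if (spec$center_echo > ETL)
    stopf("center_echo (%d) exceeds ETL (%d)", spec$center_echo, ETL)
  E1 <- exp(-protocol$ESP / 2 / tissue$T1)
  E2 <- exp(-protocol$ESP / 2 / tissue$T2)

  state <- epg_init(ETL + 1L, tissue$M0)
  state <- epg_rf_excite(state, protocol$excitation_fa)
  ## the approach starts at the natural first-echo amplitude (a 180 pulse)
  first_level <- next_echo_amplitude(state, 180, E1, E2) / tissue$M0
  tgt <- three_part_target(spec, ETL, first_level = first_level)

  alpha <- numeric(ETL)
  signal <- numeric(ETL)
  reached <- logical(ETL)
  nc <- spec$center_echo
  for (i in seq_len(nc)) {
    want <- tgt$signal[i] * tissue$M0
    f <- function(a) next_echo_amplitude(state, a, E1, E2)
    opt <- stats::optimize(f, c(0, 180), maximum = TRUE, tol = 1e-4)
    if (opt$objective <= want) {
      alpha[i] <- opt$maximum
      reached[i] <- FALSE
    } else {
      lofa <- 0
      if (f(0) > want) {
        alpha[i] <- 0
        reached[i] <- abs(f(0) - want) < 1e-9
      } else {
        alpha[i] <- stats::uniroot(function(a) f(a) - want,
                                   c(lofa, opt$maximum), tol = 1e-7)$root
        reached[i] <- TRUE
      }
    }
    state <- epg_step(state, alpha[i], 0, E1, E2)
    signal[i] <- Mod(state$Fp[1])
  }
  if (nc < ETL) {
    ramp <- seq.int(nc + 1L, ETL)
    alpha[ramp] <- alpha[nc] +
      (spec$max_fa - alpha[nc]) * (ramp - nc) / (ETL - nc)
    for (i in ramp) {
      state <- epg_step(state, alpha[i], 0, E1, E2)
      signal[i] <- Mod(state$Fp[1])
    }
  }
  structure(list(alpha = alpha, signal = signal, target = tgt$signal,
                 reached = reached, spec = spec, tissue = tissue$name),
            class = "prospective_vfa")
}

#' SAR-matched standard VFA train
#'
#' Builds the heuristic baseline at a prescribed relative SAR by bisecting the
#' plateau level of the three-part target until the resulting train's
#' [relative_sar()] matches `c_SAR`: the fair comparison used throughout --
#' every scheme is evaluated at equal relative SAR.
#'
#' @param protocol a [sequence_protocol()].
#' @param c_SAR target relative SAR in (0, 1].
#' @param tissue design tissue (default white matter).
#' @param max_fa ramp endpoint in degrees.
#' @param plateau_range search interval for the plateau level.
#' @param tol bisection tolerance on the relative SAR.
#' @return A `prospective_vfa` object whose train has `relative_sar` within
#'   `tol` of `c_SAR`.
#' @export
standard_vfa_train <- function(protocol, c_SAR,
                               tissue = default_tissue_params()$WM,
                               max_fa = 120,
                               plateau_range = c(0.005, 0.6), tol = 1e-6) {
  check_number(c_SAR, "c_SAR", lower = .Machine$double.eps, upper = 1)
  build <- function(p) {
    prospective_vfa(target_signal_spec(p, protocol$center_echo,
                                       max_fa = max_fa),
                    tissue, protocol)
  }
  sar_of <- function(p) relative_sar(build(p)$alpha)
  lo <- plateau_range[1]; hi <- plateau_range[2]
  slo <- sar_of(lo); shi <- sar_of(hi)
  if (c_SAR < slo || c_SAR > shi)
    stopf("c_SAR %.3f outside achievable range [%.4f, %.4f] for this protocol",
          c_SAR, slo, shi)
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    sm <- sar_of(mid)
    if (abs(sm - c_SAR) < tol) break
    if (sm < c_SAR) lo <- mid else hi <- mid
  }
  build(mid)
}
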