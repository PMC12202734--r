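#' Radius of the SAR hypersphere
#'
#' All trains with relative SAR exactly `c_SAR` share one Euclidean norm:
#' `R = 180 * sqrt(c_SAR * ETL)` degrees. The SAR constraint is therefore a
#' hypersphere and can be enforced by global rescaling.
#'
#' @param c_SAR relative SAR level in (0, 1].
#' @param ETL echo-train length.
#' @return Radius in degrees.
#' @export
sar_radius <- function(c_SAR, ETL) {
  check_number(c_SAR, "c_SAR", lower = .Machine$double.eps, upper = 1)
  check_number(ETL, "ETL", lower = 1)
  180 * sqrt(c_SAR * ETL)
}

#' Project a train onto the SAR hypersphere
#'
#' Rescales the train to the norm [sar_radius()] demands, preserving its
#' direction; the result has relative SAR equal to `c_SAR` up to rounding.
#'
#' @param alpha flip angles in degrees (not all zero).
#' @param c_SAR relative SAR level in (0, 1].
#' @return Rescaled train.
#' @export
project_to_sar_sphere <- function(alpha, c_SAR) {
  alpha <- as.numeric(alpha)
  nrm <- sqrt(sum(alpha^2))
  if (nrm == 0) stopf("cannot project the all-zero train onto the SAR sphere")
  alpha * sar_radius(c_SAR, length(alpha)) / nrm
}

#' Feasible constant initialisation
#'
#' The constant train on the SAR sphere: every angle `180 * sqrt(c_SAR)`
#' degrees. (A constant train at `R/ETL` would not satisfy the constraint;
#' its projection onto the sphere is exactly this train.)
#'
#' @param c_SAR relative SAR level in (0, 1].
#' @param ETL echo-train length.
#' @return Flip-angle train in degrees.
#' @export
init_alpha <- function(c_SAR, ETL) {
  check_number(c_SAR, "c_SAR", lower = .Machine$double.eps, upper = 1)
  check_number(ETL, "ETL", lower = 1)
  rep(180 * sqrt(c_SAR), as.integer(ETL))
}

#' Optimizer configuration
#'
#' @param c_SAR relative SAR constraint in (0, 1].
#' @param learning_rate ADAM step size (radians of flip angle per step).
#' @param beta1,beta2 ADAM moment decay rates.
#' @param c_STOP stopping threshold on the change of the total loss between
#'   successive iterations.
#' @param stop_mode `"absolute"` (default) or `"relative"` loss change.
#' @param patience number of consecutive sub-threshold iterations required
#'   before stopping; guards against the near-zero loss changes of ADAM's
#'   momentum warm-up being mistaken for convergence.
#' @param max_iterations iteration cap.
#' @param fa_bounds flip-angle clamp applied before each projection, degrees.
#' @param seed recorded for provenance (the optimisation itself is
#'   deterministic).
#' @return Object of class `optimizer_config`.
#' @export
optimizer_config <- function(c_SAR, learning_rate = 0.001, beta1 = 0.9,
                             beta2 = 0.999, c_STOP = 1e-3,
                             stop_mode = c("absolute", "relative"),
                             patience = 10, max_iterations = 500,
                             fa_bounds = c(0, 180), seed = 1) {
  check_number(c_SAR, "c_SAR", lower = .Machine$double.eps, upper = 1)
  check_number(learning_rate, "learning_rate", lower = .Machine$double.eps)
  check_number(beta1, "beta1", lower = 0, upper = 1)
  check_number(beta2, "beta2", lower = 0, upper = 1)
  check_number(c_STOP, "c_STOP", lower = 0)
  check_number(patience, "patience", lower = 1)
  check_number(max_iterations, "max_iterations", lower = 1)
  if (length(fa_bounds) != 2L || fa_bounds[1] < 0 || fa_bounds[2] > 180 ||
      fa_bounds[1] >= fa_bounds[2])
    stopf("'fa_bounds' must be an increasing pair within [0, 180]")
  structure(list(c_SAR = c_SAR, learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, c_STOP = c_STOP,
                 stop_mode = match.arg(stop_mode),
                 patience = as.integer(patience),
                 max_iterations = as.integer(max_iterations),
                 fa_bounds = fa_bounds, seed = as.integer(seed)),
            class = "optimizer_config")
}

#' SAR-constrained VFA optimisation
#'
#' Minimises the total objective (PSF side-band loss, L1 contrast loss and
#' smoothness penalty; see [total_loss()]) over the refocusing flip-angle
#' train by projected gradient descent: an ADAM step on the analytic gradient,
#' a clamp to `fa_bounds`, then rescaling back onto the SAR hypersphere, so
#' every iterate satisfies the SAR constraint. Starts from the feasible
#' constant train of [init_alpha()]. The iteration stops when the change in
#' total loss drops below `c_STOP` or after `max_iterations`.
#'
#' @param descr an [object_descriptor()].
#' @param protocol a [sequence_protocol()].
#' @param table image-model sampling table.
#' @param weights a [loss_weights()].
#' @param config an [optimizer_config()].
#' @param psf_table optional full-length sampling table for the PSF loss.
#' @param target_spec target contrast settings, see [loss_context()].
#' @param verbose print progress every 25 iterations.
#' @return Object of class `vfa_optimization`: `alpha` (degrees), `history`
#'   (data frame of per-iteration loss components and relative SAR),
#'   `iterations`, `converged`, `config`.
#' @export
optimize_vfa <- function(descr, protocol, table, weights, config,
                         psf_table = NULL,
                         target_spec = list(TE = 45, TR = 6000),
                         verbose = FALSE) {
  if (!inherits(config, "optimizer_config"))
    stopf("'config' must be an optimizer_config")
  ctx <- loss_context(descr, protocol, table, weights,
                      psf_table = psf_table, target_spec = target_spec)
  ETL <- protocol$ETL
  alpha <- project_to_sar_sphere(init_alpha(config$c_SAR, ETL), config$c_SAR)
  theta <- alpha * pi / 180           # optimise in radians
  lo <- config$fa_bounds[1] * pi / 180
  hi <- config$fa_bounds[2] * pi / 180

  m <- numeric(ETL); v <- numeric(ETL)
  eps <- 1e-8
  hist <- vector("list", config$max_iterations)
  prev_total <- NA_real_
  converged <- FALSE
  still <- 0L
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    lb <- total_loss(alpha = theta * 180 / pi, context = ctx, gradient = TRUE)
    g <- attr(lb, "gradient") * 180 / pi   # per-degree -> per-radian
    if (!all(is.finite(g)) || !is.finite(lb$total))
      stopf("non-finite loss or gradient at iteration %d", it)
    hist[[it]] <- data.frame(iteration = it, L1 = lb$L1, L_PSF = lb$L_PSF,
                             R = lb$R, total = lb$total, rSAR = lb$rSAR)
    if (verbose && (it %% 25L == 1L))
      message(sprintf("iter %4d  total=%.6g  L1=%.4g  L_PSF=%.4g  R=%.4g",
                      it, lb$total, lb$L1, lb$L_PSF, lb$R))
    if (!is.na(prev_total)) {
      d <- abs(lb$total - prev_total)
      if (config$stop_mode == "relative") d <- d / max(abs(prev_total), 1e-12)
      still <- if (d < config$c_STOP) still + 1L else 0L
      if (still >= config$patience) {
        converged <- TRUE
        break
      }
    }
    prev_total <- lb$total

    m <- config$beta1 * m + (1 - config$beta1) * g
    v <- config$beta2 * v + (1 - config$beta2) * g^2
    mhat <- m / (1 - config$beta1^it)
    vhat <- v / (1 - config$beta2^it)
    theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
    theta <- pmin(pmax(theta, lo), hi)
    theta <- theta * (pi * sqrt(config$c_SAR * ETL)) / sqrt(sum(theta^2))
  }
  structure(list(alpha = theta * 180 / pi,
                 history = do.call(rbind, hist[seq_len(it)]),
                 iterations = it, converged = converged, config = config),
            class = "vfa_optimization")
}

#' @export
print.vfa_optimization <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "VFA optimisation: %d iterations (%s), final total=%.6g, rel.SAR=%.4f\n",
    x$iterations, if (x$converged) "converged" else "iteration cap", last$total,
    relative_sar(x$alpha)))
  cat(sprintf("  flip angles: %.1f..%.1f deg (mean %.1f)\n",
              min(x$alpha), max(x$alpha), mean(x$alpha)))
  invisible(x)
}
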