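## Internal helpers: argument checks, centered unitary Fourier transforms,
## and a scoped RNG seed that restores the caller's random state.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok)
    stopf("'%s' must be a single number in [%s, %s]", name,
          format(lower), format(upper))
  invisible(x)
}

#' @keywords internal
fftshift <- function(x) {
  n <- length(x)
  x[((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L]
}

#' @keywords internal
ifftshift <- function(x) {
  n <- length(x)
  x[((seq_len(n) - 1L + floor(n / 2)) %% n) + 1L]
}

fftshift2 <- function(x) {
  d <- dim(x)
  x[fftshift(seq_len(d[1])), fftshift(seq_len(d[2])), drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[ifftshift(seq_len(d[1])), ifftshift(seq_len(d[2])), drop = FALSE]
}

## Unitary centered 1-D DFT: the zero-frequency (k-space centre) sample sits at
## index floor(n/2) + 1 before the transform and the PSF centre lands there too.
fft1c <- function(x) fftshift(stats::fft(ifftshift(x))) / sqrt(length(x))

ifft1c <- function(x) {
  fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))
}

fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))

ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

centre_index <- function(n) floor(n / 2) + 1L

## Evaluate `expr` under a fixed seed without disturbing the session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
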