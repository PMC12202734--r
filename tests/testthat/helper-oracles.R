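# Brute-force isochromat (Bloch-rotation) oracle for the EPG simulation:
# an ensemble of spins with static intra-voxel dephasing angles equally
# spaced over [0, 2*pi), each evolved by explicit 3D rotations and
# relaxation. Excitation about +y, refocusing about +x (CPMG), one
# dephasing+relaxation block per half echo spacing; echo amplitude is the
# magnitude of the ensemble-average transverse magnetisation.
iso_cpmg <- function(alpha_deg, T1, T2, ESP, M0 = 1, nspins = 20000,
                     exc = 90, inversion = FALSE, TI = NULL) {
  phi <- 2 * pi * (seq_len(nspins) - 0.5) / nspins
  E1 <- exp(-ESP / 2 / T1)
  E2 <- exp(-ESP / 2 / T2)
  Mx <- rep(0, nspins); My <- rep(0, nspins); Mz <- rep(M0, nspins)
  if (inversion) {
    Mz <- -Mz
    E1ti <- exp(-TI / T1)
    Mz <- Mz * E1ti + M0 * (1 - E1ti)
  }
  a <- exc * pi / 180 # rotation about +y
  tmp <- Mx * cos(a) + Mz * sin(a)
  Mz <- -Mx * sin(a) + Mz * cos(a)
  Mx <- tmp
  cp <- cos(phi); sp <- sin(phi)
  precess_relax <- function() {
    tmp <- Mx * cp - My * sp
    My <<- Mx * sp + My * cp
    Mx <<- tmp
    Mx <<- Mx * E2; My <<- My * E2
    Mz <<- Mz * E1 + M0 * (1 - E1)
  }
  S <- numeric(length(alpha_deg))
  for (i in seq_along(alpha_deg)) {
    precess_relax()
    b <- alpha_deg[i] * pi / 180 # rotation about +x
    tmp <- My * cos(b) - Mz * sin(b)
    Mz <- My * sin(b) + Mz * cos(b)
    My <- tmp
    precess_relax()
    S[i] <- Mod(mean(complex(real = Mx, imaginary = My)))
  }
  S
}

# Plain DFT-by-summation oracle for the centred unitary transform used by the
# PSF machinery (independent of the package's FFT helpers).
dft_centred <- function(x) {
  n <- length(x)
  c0 <- floor(n / 2) # 0-based centre
  j <- seq_len(n) - 1L
  out <- complex(real = numeric(n))
  for (k in seq_len(n) - 1L) {
    out[k + 1L] <- sum(x * exp(-2i * pi * ((j - c0) * (k - c0)) / n)) / sqrt(n)
  }
  out
}

# Small default protocol for unit tests
test_protocol <- function(ETL = 24, ESP = 3.8, center_echo = ETL / 2, ...) {
  sequence_protocol(ETL = ETL, ESP = ESP, TR = 3200,
                    center_echo = center_echo, ...)
}
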