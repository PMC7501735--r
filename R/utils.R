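# Internal numerical helpers shared across modules.

# Circular shift of indices for centered FFT conventions.  For even n
# fftshift and ifftshift coincide; both are supported for odd n so the
# transforms stay exact inverses.
fftshift_idx <- function(n) {
  ((seq_len(n) - 1 - floor(n / 2)) %% n) + 1
}

ifftshift_idx <- function(n) {
  ((seq_len(n) - 1 - ceiling(n / 2)) %% n) + 1
}

# Unitary FFT along the first dimension of an array (any further dims are
# carried along), with centered (DC at floor(n/2)+1) input and output.
fft1c_dim1 <- function(x, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  n <- d[1]
  m <- matrix(x, nrow = n)
  m <- m[ifftshift_idx(n), , drop = FALSE]
  m <- stats::mvfft(m, inverse = inverse) / sqrt(n)  # R's inverse is unnormalized
  m <- m[fftshift_idx(n), , drop = FALSE]
  array(m, dim = d)
}

# Unitary centered FFT along an arbitrary dimension.
fft1c <- function(x, dim = 1, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) return(array(fft1c_dim1(x, inverse), dim = length(x)))
  if (dim == 1) return(fft1c_dim1(x, inverse))
  perm <- seq_along(d)
  perm[c(1, dim)] <- perm[c(dim, 1)]
  y <- aperm(x, perm)
  y <- fft1c_dim1(y, inverse)
  aperm(y, perm)
}

# 2-D unitary centered FFT over the first two dims (spatial transform).
fft2c <- function(x, inverse = FALSE) {
  fft1c(fft1c(x, 1, inverse), 2, inverse)
}

# Hermitian square root via eigendecomposition (base chol() is real-only).
hermitian_sqrt <- function(psi) {
  e <- eigen((psi + Conj(t(psi))) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("covariance matrix is not positive definite (min eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% (sqrt(e$values) * Conj(t(e$vectors)))
}

# n iid CN(0, psi) column draws: real and imaginary parts each N(0, psi/2).
rcomplex_mvnorm <- function(n, psi) {
  nc <- nrow(psi)
  s <- hermitian_sqrt(psi)
  w <- matrix(complex(real = stats::rnorm(nc * n, sd = sqrt(0.5)),
                      imaginary = stats::rnorm(nc * n, sd = sqrt(0.5))),
              nrow = nc)
  s %*% w
}

# Welch power spectral density of a complex time series (two-sided,
# fftshifted so DC is central).  Returns the averaged periodogram.
welch_psd <- function(x, segment = 256, overlap = 0.5) {
  n <- length(x)
  if (n < segment) segment <- 2^floor(log2(n))
  step <- max(1, floor(segment * (1 - overlap)))
  starts <- seq(1, n - segment + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))  # Hann
  norm <- sum(w^2)
  acc <- numeric(segment)
  for (s in starts) {
    seg <- x[s:(s + segment - 1)] * w
    acc <- acc + Mod(stats::fft(seg))^2 / norm
  }
  (acc / length(starts))[fftshift_idx(segment)]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
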