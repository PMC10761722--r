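# DFT helper: stats::fft degrades to near-quadratic cost when the series
# length has a large prime factor (GF-IF series lengths routinely do,
# e.g. 9998 = 2 * 4999). For those lengths we fall back to Bluestein's
# chirp-z algorithm, which evaluates an arbitrary-length DFT with three
# power-of-two FFTs; chirp factors are cached per length.

.fft_cache <- new.env(parent = emptyenv())

max_prime_factor <- function(n) {
  f <- 2L
  while (f * f <= n) {
    if (n %% f == 0L) n <- n %/% f else f <- f + 1L
  }
  n
}

fft_any <- function(x, inverse = FALSE) {
  n <- length(x)
  if (n < 2L || max_prime_factor(n) <= 127L) {
    return(stats::fft(x, inverse = inverse))
  }
  if (inverse) return(Conj(fft_any(Conj(x))))
  key <- as.character(n)
  cc <- .fft_cache[[key]]
  if (is.null(cc)) {
    m <- 2L^ceiling(log2(2 * n - 1))
    j <- 0:(n - 1)
    chirp <- exp(-1i * pi * ((j * j) %% (2 * n)) / n)
    b <- complex(length.out = m)
    b[1:n] <- Conj(chirp)
    b[m - seq_len(n - 1L) + 1L] <- Conj(chirp[2:n])
    cc <- list(m = m, chirp = chirp, B = stats::fft(b))
    .fft_cache[[key]] <- cc
  }
  a <- complex(length.out = cc$m)
  a[1:n] <- x * cc$chirp
  conv <- stats::fft(stats::fft(a) * cc$B, inverse = TRUE) / cc$m
  cc$chirp * conv[1:n]
}
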