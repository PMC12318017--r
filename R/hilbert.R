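# FFT-based analytic signal: negative frequencies zeroed, positive doubled.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) return(complex(0))
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
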