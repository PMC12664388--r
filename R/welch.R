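# Welch power spectral density estimate.
#
# Demeaned segments with fractional overlap, one-sided periodogram
# averaging. The default rectangular taper keeps an on-bin tone concentrated
# in a single frequency bin, which the spectral-concentration metrics
# (entropy, band ratios) rely on; a Hamming taper is available where sidelobe
# suppression matters more than mainlobe width. Absolute scaling is
# consistent across calls, which is all the relative metrics need.
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5,
                      window = c("rect", "hamming")) {
  window <- match.arg(window)
  n <- length(x)
  L <- min(n, max(8L, round(window_s * fs)))
  h <- max(1L, round(L * (1 - overlap)))
  starts <- window_starts(n, L, h)
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1)) else rep(1, L)
  U <- sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[(s + 1L):(s + L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (U * fs)
    half <- P[1:nf]
    # fold negative frequencies into the one-sided spectrum
    if (L %% 2 == 0) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    else half[2:nf] <- 2 * half[2:nf]
    acc <- acc + half
  }
  list(freq = (0:(nf - 1L)) * fs / L, psd = acc / length(starts))
}
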