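# Internal numerical helpers shared across modules.

# Welch power spectral density for a uniformly sampled series.
# Hann-windowed 50%-overlapping segments, mean periodogram, one-sided.
welch_psd <- function(x, fs, nperseg = NULL) {
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(n, 256L)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / scale
    p <- sp[seq_len(nf)]
    # fold negative frequencies into the one-sided estimate
    if (nperseg %% 2 == 0) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)] else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = acc / length(starts))
}

bandpower <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(0)
  sum(psd[sel]) * if (length(freq) > 1) diff(freq[1:2]) else 1
}

# Centered running median with odd window length, edges handled by shrinking.
running_median <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(x)
  if (n == 0) return(x)
  if (k >= n) return(rep(median(x), n))
  out <- stats::runmed(x, k, endrule = "median")
  as.numeric(out)
}

moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

moment_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^4) / s^4
}

# Shannon entropy (bits) of an amplitude histogram.
shannon_entropy <- function(x, bins = 16L) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || diff(range(x)) == 0) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

# Linear interpolation of interior NAs only; leading/trailing gaps preserved.
fill_interior_na <- function(t, x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) return(x)
  filled <- approx(t[ok], x[ok], xout = t, rule = 1)$y
  out <- x
  idx <- !ok & !is.na(filled)
  out[idx] <- filled[idx]
  out
}

# Deterministic child seed derived from a parent seed and a stream label.
child_seed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(lab)) h <- (h * 31 + ch) %% 2147482951
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
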