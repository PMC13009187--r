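# Minimal periodized discrete wavelet transform used by the ECG denoiser and
# the beat-morphology features. Two filter banks are provided: the
# biorthogonal 4.4 (9/7-tap) pair for denoising and Daubechies-3 for
# template approximation coefficients. Coefficients are the published filter
# tables; perfect reconstruction of the periodized bank is covered by tests.

wavelet_filters <- function(name = c("bior4.4", "db3")) {
  name <- match.arg(name)
  if (name == "db3") {
    dec_lo <- c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
                0.45987750211849154, 0.80689150931109250, 0.33267055295008263)
    dec_hi <- c(-0.33267055295008263, 0.80689150931109250, -0.45987750211849154,
                -0.13501102001025458, 0.08544127388202666, 0.03522629188570953)
    list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rev(dec_lo), rec_hi = rev(dec_hi))
  } else {
    dec_lo <- c(0, 0.03782845550726404, -0.023849465019556843, -0.11062440441843718,
                0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
                -0.11062440441843718, -0.023849465019556843, 0.03782845550726404)
    dec_hi <- c(0, -0.06453888262869706, 0.04068941760916406, 0.41809227322161724,
                -0.7884856164055829, 0.41809227322161724, 0.04068941760916406,
                -0.06453888262869706, 0, 0)
    rec_lo <- c(0, -0.06453888262869706, -0.04068941760916406, 0.41809227322161724,
                0.7884856164055829, 0.41809227322161724, -0.04068941760916406,
                -0.06453888262869706, 0, 0)
    # highpass synthesis by alternating-sign rule on the analysis lowpass
    rec_hi <- dec_lo * rep_len(c(1, -1), length(dec_lo))
    list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
  }
}

# y[i] = sum_m f[m] x[(i - m) mod n], via the circular convolution theorem.
circ_filter <- function(x, f) {
  n <- length(x)
  w <- numeric(n)
  pos <- ((seq_along(f) - 1L) %% n) + 1L
  for (m in seq_along(f)) w[pos[m]] <- w[pos[m]] + f[m]
  Re(fft(fft(x) * fft(w), inverse = TRUE)) / n
}

dwt_step <- function(x, fb) {
  n <- length(x)
  a <- circ_filter(x, fb$dec_lo)[seq(1, n, 2)]
  d <- circ_filter(x, fb$dec_hi)[seq(1, n, 2)]
  list(a = a, d = d)
}

idwt_step <- function(a, d, fb) {
  n <- 2L * length(a)
  ua <- numeric(n); ud <- numeric(n)
  ua[seq(1, n, 2)] <- a
  ud[seq(1, n, 2)] <- d
  y <- circ_filter(ua, fb$rec_lo) + circ_filter(ud, fb$rec_hi)
  L <- length(fb$rec_lo)
  y[((seq_len(n) - 1L + (L - 1L)) %% n) + 1L]   # undo the analysis/synthesis delay
}

# Multi-level periodized DWT. x is reflect-padded to a multiple of 2^levels;
# the pad length is recorded so the inverse can truncate.
dwt_periodic <- function(x, wavelet = "bior4.4", levels = 5L) {
  fb <- wavelet_filters(wavelet)
  n0 <- length(x)
  block <- 2^levels
  pad <- (block - n0 %% block) %% block
  if (pad > 0) x <- c(x, rev(tail(x, pad)))
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, fb)
    details[[l]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, wavelet = wavelet, levels = levels, n = n0)
}

idwt_periodic <- function(dec) {
  fb <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (l in rev(seq_len(dec$levels))) a <- idwt_step(a, dec$details[[l]], fb)
  a[seq_len(dec$n)]
}

#' Wavelet shrinkage denoising
#'
#' Multi-level periodized wavelet decomposition (biorthogonal 4.4 by default),
#' soft universal thresholding of the detail coefficients with the noise sd
#' estimated from the finest detail level (MAD / 0.6745), and reconstruction.
#'
#' @param x Numeric signal.
#' @param wavelet `"bior4.4"` or `"db3"`.
#' @param levels Decomposition depth.
#' @return Denoised signal, same length as `x`.
#' @export
wavelet_denoise <- function(x, wavelet = "bior4.4", levels = 5L) {
  if (length(x) < 2^levels) return(x)
  dec <- dwt_periodic(x, wavelet, levels)
  sigma <- median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  dec$details <- lapply(dec$details, soft)
  idwt_periodic(dec)
}

# First `k` approximation coefficients of x at the given level (used as
# beat-template morphology descriptors).
dwt_approx_coefs <- function(x, wavelet = "db3", level = 3L, k = 8L) {
  if (length(x) < 2^level) return(rep(NA_real_, k))
  a <- dwt_periodic(x, wavelet, level)$approx
  out <- rep(NA_real_, k)
  out[seq_len(min(k, length(a)))] <- a[seq_len(min(k, length(a)))]
  out
}

# Shannon entropy of the normalized energy distribution over wavelet levels.
wavelet_entropy <- function(x, wavelet = "db3", levels = 4L) {
  if (length(x) < 2^levels || sd(x) == 0) return(0)
  dec <- dwt_periodic(x - mean(x), wavelet, levels)
  e <- c(vapply(dec$details, function(d) sum(d^2), 0), sum(dec$approx^2))
  if (sum(e) == 0) return(0)
  p <- e[e > 0] / sum(e)
  -sum(p * log(p))
}
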