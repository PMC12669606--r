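# Digital 4-pole Bessel low-pass, designed from the analog prototype and
# applied forward-only (causal), matching an analog acquisition filter.

# Reversed Bessel polynomial theta_n(s) coefficients, highest power first.
# n = 4: s^4 + 10 s^3 + 45 s^2 + 105 s + 105.
bessel_poly_coefs <- function(n) {
  # c_k = (2n - k)! / (2^(n-k) k! (n-k)!), k = 0..n (k = power of s)
  k <- 0:n
  ck <- factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
  rev(ck) # highest power first
}

# Poles of the magnitude-normalized analog prototype: -3 dB at omega = 1.
bessel_prototype_poles <- function(n = 4) {
  coefs <- bessel_poly_coefs(n)
  p <- polyroot(rev(coefs)) # delay-normalized poles
  g0 <- coefs[length(coefs)] # DC numerator
  mag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    Mod(g0 / sum(coefs * s^(n:0)))^2
  }
  # -3 dB frequency of the delay-normalized filter (about 2.114 for n = 4)
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-3, 10),
                       tol = 1e-12)$root
  p / w3
}

# Polynomial (highest power first) with the given roots, real coefficients.
poly_from_roots <- function(r) {
  coefs <- 1
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  Re(coefs)
}

#' Design a digital four-pole Bessel low-pass filter
#'
#' Bilinear transform (with frequency prewarping) of the magnitude-normalized
#' analog 4-pole Bessel prototype, so the digital filter has unit DC gain and
#' its -3 dB point at `cutoff_Hz`.
#'
#' @param cutoff_Hz -3 dB cutoff frequency in Hz.
#' @param fs_Hz Sampling rate in Hz; `cutoff_Hz` must be below Nyquist.
#' @param order Filter order; only the 4-pole design used by the acquisition
#'   chain is supported.
#' @return A list with numerator `b` and denominator `a` coefficients
#'   (direct form, `a[1] = 1`).
#' @export
bessel_lowpass_design <- function(cutoff_Hz, fs_Hz, order = 4) {
  if (cutoff_Hz <= 0 || cutoff_Hz >= fs_Hz / 2) {
    err_config("filter cutoff must lie in (0, Nyquist)")
  }
  p <- bessel_prototype_poles(order)
  warped <- 2 * fs_Hz * tan(pi * cutoff_Hz / fs_Hz) # prewarped analog cutoff
  pa <- p * warped
  k2 <- 2 * fs_Hz
  zp <- (k2 + pa) / (k2 - pa)              # digital poles
  a <- poly_from_roots(zp)
  b <- choose(order, 0:order)              # zeros at z = -1: (1 + z^-1)^n
  b <- b * sum(a) / sum(b)                 # unit DC gain
  list(b = b, a = a)
}

# Causal IIR application (direct form II transposed) with steady-state
# initial conditions at x[1], so a constant input is reproduced exactly.
iir_filter <- function(x, design) {
  b <- design$b; a <- design$a
  n <- length(b) - 1L
  # steady state for constant input c with unit DC gain:
  # z_j = c * sum_{k > j} (b_k - a_k)
  zi <- x[1] * rev(cumsum(rev(b[-1L] - a[-1L])))
  .df2t_filter(x, b, a, zi)
}

#' Apply the analysis low-pass filter to a recording
#'
#' Forward-only four-pole Bessel low-pass at the stated -3 dB cutoff,
#' mirroring the digital analysis filter applied to bilayer recordings
#' before level measurement.
#'
#' @param trace A [recording_trace()].
#' @param cutoff_Hz -3 dB cutoff in Hz (default 800, the conventional
#'   analysis bandwidth); must be below Nyquist.
#' @return A `recording_trace` of the same length with
#'   `meta$analysis_cutoff_Hz` recorded.
#' @export
apply_lowpass <- function(trace, cutoff_Hz = 800) {
  stopifnot(inherits(trace, "recording_trace"))
  fs <- 1 / trace$dt
  des <- bessel_lowpass_design(cutoff_Hz, fs)
  out <- trace
  out$current_pA <- iir_filter(trace$current_pA, des)
  out$meta$analysis_cutoff_Hz <- cutoff_Hz
  out
}
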