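# Independent oracles and fixture builders shared across tests.

# Brute-force inverse of the Fatt-Ginsborg relation by bracketed root
# search on the forward expression (independent of erev_for_fg_ratio).
fg_erev_oracle <- function(ratio, k, ca, rt) {
  f <- function(e) (k / (4 * ca)) * exp(e / rt) * (exp(e / rt) + 1) - ratio
  uniroot(f, c(-2000, 2000), tol = 1e-12)$root
}

# Brute-force P_Cl/P_K from the GHK voltage equation by bracketed root
# search in r (independent of pcl_pk_from_erev's closed form).
ghk_pclpk_oracle <- function(e_rev, k_cis, k_trans, rt) {
  f <- function(r) {
    rt * log((k_trans + r * k_cis) / (k_cis + r * k_trans)) - e_rev
  }
  uniroot(f, c(0, 1e6), tol = 1e-12)$root
}

# Noiseless square-wave trace: n_cycles of (closed half, open half), each
# half `half_n` samples.
square_trace <- function(closed = 0, open = 1, half_n = 100, n_cycles = 10,
                         dt = 1e-4, voltage_mV = 80) {
  x <- rep(c(closed, open), each = half_n, times = n_cycles)
  recording_trace(x, dt, list(voltage_mV = voltage_mV,
                              analysis_cutoff_Hz = 800))
}

# Exact event table carrying a single open/closed level pair, for I/V tests
# that bypass the idealizer.
exact_event_table <- function(voltage_mV, amplitude_pA, replicate = "r1") {
  ev <- data.frame(
    state = c("closed", "open", "closed"),
    t_start_s = c(0, 1, 2),
    duration_s = c(1, 1, 1),
    amplitude_pA = c(0, amplitude_pA, 0)
  )
  structure(ev, meta = list(voltage_mV = voltage_mV, replicate = replicate),
            dead_time_s = 4e-4, class = c("event_table", "data.frame"))
}

# Short-duration acquisition settings used to keep simulator tests fast;
# the production defaults (60 s) are exercised by the acceptance tests.
fast_acq <- function(duration_s = 5, fs_Hz = 1e5) {
  acquisition_settings(fs_Hz = fs_Hz, duration_s = duration_s)
}
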