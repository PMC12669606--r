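# Automated replacement for manual cursor measurement of single-channel
# records: all-points histogram + two-component Gaussian mixture for the
# closed/open levels, then half-amplitude threshold idealization with a
# dead time tied to the analysis bandwidth.

#' Conventional dead time for a given analysis bandwidth
#'
#' The 10-90% rise time of a (near-)Gaussian low-pass, `0.3321 / f_c`;
#' events shorter than this are not resolvable at bandwidth `f_c`.
#'
#' @param cutoff_Hz Analysis filter -3 dB cutoff in Hz.
#' @return Dead time in seconds (about 0.42 ms at 800 Hz).
#' @export
default_dead_time <- function(cutoff_Hz = 800) 0.3321 / cutoff_Hz

# Weighted 2-component Gaussian mixture EM on histogram bins.
# Returns list(mu, sigma, lambda, converged).
gmm2_em <- function(centers, weights, mu0, sigma0, max_iter = 200,
                    tol = 1e-10) {
  mu <- mu0; sigma <- pmax(sigma0, 1e-12); lambda <- c(0.5, 0.5)
  w <- weights / sum(weights)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- lambda[1] * dnorm(centers, mu[1], sigma[1])
    d2 <- lambda[2] * dnorm(centers, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot < 1e-300] <- 1e-300
    r1 <- d1 / tot
    ll <- sum(w * log(tot))
    g1 <- sum(w * r1); g2 <- 1 - g1
    if (g1 < 1e-10 || g2 < 1e-10) {
      return(list(mu = mu, sigma = sigma, lambda = lambda, converged = FALSE))
    }
    mu <- c(sum(w * r1 * centers) / g1,
            sum(w * (1 - r1) * centers) / g2)
    sigma <- sqrt(pmax(c(
      sum(w * r1 * (centers - mu[1])^2) / g1,
      sum(w * (1 - r1) * (centers - mu[2])^2) / g2
    ), 1e-16))
    lambda <- c(g1, g2)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, lambda = lambda, converged = TRUE)
}

# Freedman-Diaconis all-points histogram of a trace. The IQR entering the
# bin-width rule is taken on a decimated copy for long traces (the quantiles
# of a 6e6-sample trace are stable under 10x decimation).
fd_histogram <- function(x) {
  xq <- if (length(x) > 1e6) x[seq(1L, length(x), by = 10L)] else x
  bw <- 2 * IQR(xq) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / 512
  if (bw <= 0) bw <- 1e-6
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mids = h$mids, counts = h$counts, bw = bw)
}

# Two most separated local maxima of smoothed histogram counts; fallback to
# extreme quantiles when only one mode exists.
histogram_mode_pair <- function(h) {
  k <- pmax(3L, round(length(h$mids) / 50))
  sm <- stats::filter(h$counts, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  n <- length(sm)
  is_peak <- sm >= c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > 0
  peaks <- which(is_peak)
  if (length(peaks) >= 2) {
    # strongest peak, then the most separated peak with appreciable mass
    main <- peaks[which.max(sm[peaks])]
    other <- peaks[peaks != main]
    other <- other[sm[other] >= 0.02 * sm[main]]
    if (length(other) >= 1) {
      second <- other[which.max(abs(h$mids[other] - h$mids[main]))]
      return(sort(h$mids[c(main, second)]))
    }
  }
  stats::quantile(rep(h$mids, h$counts), c(0.1, 0.9), names = FALSE)
}

#' Estimate closed and open current levels of a recording
#'
#' Builds an all-points amplitude histogram (Freedman-Diaconis bin width) and
#' fits a two-component Gaussian mixture by EM, initialized at the two most
#' separated histogram modes. The component nearest the baseline is labelled
#' closed. If the mixture degenerates, the raw mode pair is used instead.
#' When the two levels are separated by less than `min_separation` pooled
#' standard deviations the trace is declared channel-free.
#'
#' @param trace A [recording_trace()], already filtered at the analysis
#'   bandwidth.
#' @param baseline_pA Reference baseline used to decide which component is
#'   the closed level; defaults to the trace's recorded baseline or 0.
#' @param min_separation Minimum |open - closed| in units of the pooled
#'   component SD (default 3).
#' @return An object of class `level_estimate` with fields `closed_pA`,
#'   `open_pA`, `sd_closed_pA`, `sd_open_pA`, `method`.
#'   Throws a condition of class `ionpore_no_channel` for unimodal traces.
#' @export
estimate_levels <- function(trace, baseline_pA = NULL, min_separation = 3) {
  stopifnot(inherits(trace, "recording_trace"))
  x <- trace$current_pA
  if (is.null(baseline_pA)) {
    baseline_pA <- if (!is.null(trace$meta$baseline_pA)) {
      trace$meta$baseline_pA
    } else {
      0
    }
  }
  h <- fd_histogram(x)
  modes <- histogram_mode_pair(h)
  s0 <- max(sd(x) / 2, h$bw)
  fit <- gmm2_em(h$mids, h$counts, mu0 = modes, sigma0 = rep(s0, 2))
  if (fit$converged && min(fit$lambda) > 1e-6) {
    mu <- sort(fit$mu)
    method <- "gmm"
  } else {
    mu <- sort(modes)
    method <- "mode-pair"
  }
  # refinement: hard-assign samples at the midpoint of the mixture means and
  # take per-side means/SDs (the automated analogue of cursor placement);
  # exact for noiseless levels, negligible truncation bias at the
  # signal-to-noise ratios where a channel is detectable at all
  thr <- mean(mu)
  lo <- x <= thr
  if (any(lo) && any(!lo)) {
    mu <- c(mean(x[lo]), mean(x[!lo]))
    sig <- c(sd(x[lo]), sd(x[!lo]))
    sig[is.na(sig)] <- 0
  } else {
    sig <- rep(h$bw, 2)
  }
  pooled <- sqrt(mean(sig^2))
  if (abs(diff(mu)) < min_separation * pooled) {
    err_signal(sprintf(
      "no channel detected: level separation %.3g pA < %g x pooled spread %.3g pA",
      abs(diff(mu)), min_separation, pooled
    ), "ionpore_no_channel")
  }
  ord <- order(abs(mu - baseline_pA)) # closed = nearest to baseline
  structure(list(
    closed_pA = mu[ord[1]], open_pA = mu[ord[2]],
    sd_closed_pA = sig[ord[1]], sd_open_pA = sig[ord[2]],
    method = method
  ), class = "level_estimate")
}

#' @export
print.level_estimate <- function(x, ...) {
  cat(sprintf(
    "<level_estimate> closed %.4g pA (SD %.3g), open %.4g pA (SD %.3g) [%s]\n",
    x$closed_pA, x$sd_closed_pA, x$open_pA, x$sd_open_pA, x$method
  ))
  invisible(x)
}

#' Half-amplitude threshold idealization with a dead time
#'
#' The threshold is the midpoint of the closed and open levels; threshold
#' crossings toggle the state, and any excursion shorter than `dead_time_s`
#' is merged into the surrounding state. The resulting events strictly
#' alternate and tile the analyzed interval exactly.
#'
#' Per-event mean amplitudes are computed from the trace, excluding a settle
#' margin (one filter rise time) after each transition when the event is
#' long enough, mimicking cursor placement away from transition edges.
#'
#' @param trace A [recording_trace()] filtered at the analysis bandwidth.
#' @param levels A [estimate_levels()] result (or a list with `closed_pA`,
#'   `open_pA`).
#' @param dead_time_s Events shorter than this are censored (merged); must
#'   be at least 2 sample intervals and shorter than the trace.
#' @return An `event_table`: data.frame with columns `state`, `t_start_s`,
#'   `duration_s`, `amplitude_pA`; trace metadata in `attr(, "meta")`.
#' @export
idealize_half_amplitude <- function(trace, levels,
                                    dead_time_s = default_dead_time(
                                      trace$meta$analysis_cutoff_Hz %||% 800
                                    )) {
  stopifnot(inherits(trace, "recording_trace"))
  dt <- trace$dt
  x <- trace$current_pA
  n <- length(x)
  if (dead_time_s >= n * dt) err_config("dead time exceeds trace duration")
  if (dead_time_s < 2 * dt) err_config("dead time must be >= 2 sample intervals")
  thr <- (levels$closed_pA + levels$open_pA) / 2
  open_side <- sign(levels$open_pA - levels$closed_pA)
  raw_open <- if (open_side >= 0) x > thr else x < thr

  r <- rle(raw_open)
  dead_n <- dead_time_s / dt
  st <- merge_short_runs(r$values, r$lengths, dead_n)

  lens <- st$lengths
  states <- st$values
  starts <- cumsum(c(0L, lens[-length(lens)]))

  # settle margin: one rise time of the analysis filter after each edge
  fc <- trace$meta$analysis_cutoff_Hz %||% 800
  margin <- ceiling(0.3321 / fc / dt)
  amps <- event_amplitudes(x, starts, lens, margin)

  out <- data.frame(
    state = ifelse(states, "open", "closed"),
    t_start_s = starts * dt,
    duration_s = lens * dt,
    amplitude_pA = amps
  )
  structure(out, meta = trace$meta, dead_time_s = dead_time_s,
            class = c("event_table", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sequential dead-time censoring of a run-length encoded state sequence:
# walk the runs; runs shorter than dead_n are absorbed into the current
# event without changing its state; equal-state neighbours coalesce.
# Leading short runs are absorbed into the first resolvable event.
merge_short_runs <- function(values, lengths, dead_n) {
  k <- length(values)
  if (k == 1L) return(list(values = values, lengths = lengths))
  first_long <- which(lengths >= dead_n)[1]
  if (is.na(first_long)) {
    # nothing resolvable: single event of the majority state
    tot <- sum(lengths)
    maj <- sum(lengths[values]) >= tot / 2
    return(list(values = maj, lengths = tot))
  }
  out_v <- values[first_long]
  out_l <- sum(lengths[seq_len(first_long)])
  i <- first_long + 1L
  while (i <= k) {
    if (lengths[i] < dead_n || values[i] == out_v[length(out_v)]) {
      out_l[length(out_l)] <- out_l[length(out_l)] + lengths[i]
    } else {
      out_v <- c(out_v, values[i])
      out_l <- c(out_l, lengths[i])
    }
    i <- i + 1L
  }
  list(values = out_v, lengths = out_l)
}

# Per-event mean amplitudes via cumulative sums, excluding `margin` samples
# after each event start and before each event end when the event has more
# than 3*margin samples (short events keep all their samples).
event_amplitudes <- function(x, starts, lens, margin) {
  cs <- c(0, cumsum(x))
  trim <- ifelse(lens > 3 * margin, margin, 0L)
  lo <- starts + trim          # 0-based index of first kept sample
  hi <- starts + lens - trim   # 0-based index past last kept sample
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Duration-weighted single-channel current amplitude
#'
#' `i = ` (duration-weighted mean amplitude of open events) minus
#' (duration-weighted mean amplitude of closed events). The sign of the
#' driving force is preserved and the estimate is invariant to a baseline
#' offset.
#'
#' @param events An `event_table` from [idealize_half_amplitude()].
#' @return Amplitude in pA. Throws `ionpore_no_amplitude` when there are no
#'   open events.
#' @export
single_channel_amplitude <- function(events) {
  op <- events$state == "open"
  if (!any(op)) err_signal("no open events in table", "ionpore_no_amplitude")
  wmean <- function(a, w) sum(a * w) / sum(w)
  wmean(events$amplitude_pA[op], events$duration_s[op]) -
    wmean(events$amplitude_pA[!op], events$duration_s[!op])
}

#' Open probability
#'
#' Fraction of the analyzed interval spent in the open state.
#'
#' @param events An `event_table`.
#' @return A number in \[0, 1\].
#' @export
open_probability <- function(events) {
  sum(events$duration_s[events$state == "open"]) / sum(events$duration_s)
}
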