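# Current-voltage analysis: assemble I/V points from idealized recordings,
# fit per-replicate lines i = G (V - E_rev), pool across replicates,
# correct for junction potentials, flag saturation, classify selectivity.

#' Assemble I/V points from idealized event tables
#'
#' One point per (voltage, replicate): the duration-weighted single-channel
#' amplitude from [single_channel_amplitude()]. The junction potential is
#' applied once, as a fixed offset on the voltage axis
#' (`corrected = command - junction`), so the fitted reversal potential is
#' junction-corrected while the slope (conductance) is untouched.
#'
#' @param event_tables List of `event_table` objects; each must carry
#'   `voltage_mV` in its metadata. Replicate labels are taken from metadata
#'   field `replicate` when present, else from the list names, else "r1".
#' @param junction_mV Junction potential in mV (one value per solution
#'   condition).
#' @return A data.frame of class `iv_points` with columns `voltage_mV`,
#'   `corrected_mV`, `amplitude_pA`, `replicate`, `n_events`.
#' @export
build_iv <- function(event_tables, junction_mV = 0) {
  rows <- lapply(seq_along(event_tables), function(i) {
    ev <- event_tables[[i]]
    meta <- attr(ev, "meta")
    if (is.null(meta$voltage_mV)) {
      err_input("event table lacks voltage_mV metadata")
    }
    rep_lab <- meta$replicate %||% names(event_tables)[i] %||% "r1"
    if (is.null(rep_lab) || !nzchar(rep_lab)) rep_lab <- "r1"
    data.frame(
      voltage_mV = meta$voltage_mV,
      corrected_mV = meta$voltage_mV - junction_mV,
      amplitude_pA = single_channel_amplitude(ev),
      replicate = rep_lab,
      n_events = sum(ev$state == "open")
    )
  })
  pts <- do.call(rbind, rows)
  dup <- duplicated(pts[, c("voltage_mV", "replicate")])
  if (any(dup)) {
    err_input("duplicate (voltage, replicate) combinations in input")
  }
  structure(pts, junction_mV = junction_mV,
            class = c("iv_points", "data.frame"))
}

fit_one_replicate <- function(v, i) {
  fit <- lm(i ~ v)
  slope <- unname(coef(fit)[2])     # pA/mV = nS
  icpt <- unname(coef(fit)[1])
  g_pS <- slope * 1000
  e_rev <- if (abs(slope) < 1e-15) NA_real_ else -icpt / slope
  list(g_pS = g_pS, e_rev_mV = e_rev)
}

#' Linear I/V fit for conductance and reversal potential
#'
#' Per replicate, ordinary least squares of amplitude on corrected voltage
#' over the points with `|corrected voltage| > exclude_mV` (the low-voltage
#' window where single-channel amplitudes cannot be measured reliably is
#' excluded). The slope is the single-channel conductance (pS); the
#' x-intercept is the reversal potential — for conditions where the window
#' around zero current is unmeasurable, E_rev is necessarily extrapolated
#' and the intercept of the fitted line formalizes that extrapolation.
#' Replicates are aggregated as mean and SD.
#'
#' @param points An `iv_points` data.frame from [build_iv()].
#' @param exclude_mV Exclusion half-window in mV (default 20).
#' @return An object of class `iv_fit` with per-replicate estimates and
#'   pooled `conductance_pS` / `e_rev_mV` (mean, sd, n).
#' @export
fit_iv_linear <- function(points, exclude_mV = 20) {
  keep <- abs(points$corrected_mV) > exclude_mV
  if (!any(keep)) {
    err_signal("all I/V points fall inside the exclusion window",
               "ionpore_insufficient_range")
  }
  pts <- points[keep, , drop = FALSE]
  reps <- split(pts, pts$replicate)
  per <- lapply(reps, function(d) {
    if (length(unique(d$corrected_mV)) < 2) {
      err_signal(sprintf(
        "replicate %s has < 2 distinct voltages outside the exclusion window",
        d$replicate[1]
      ), "ionpore_insufficient_range")
    }
    fit_one_replicate(d$corrected_mV, d$amplitude_pA)
  })
  g <- vapply(per, `[[`, numeric(1), "g_pS")
  e <- vapply(per, `[[`, numeric(1), "e_rev_mV")
  if (any(!is.finite(e))) {
    err_signal("zero slope: reversal potential undefined",
               "ionpore_erev_undefined")
  }
  n <- length(g)
  structure(list(
    replicates = data.frame(replicate = names(per), g_pS = unname(g),
                            e_rev_mV = unname(e)),
    conductance_pS = c(mean = mean(g), sd = if (n >= 2) sd(g) else NA_real_),
    e_rev_mV = c(mean = mean(e), sd = if (n >= 2) sd(e) else NA_real_),
    n = n,
    exclude_mV = exclude_mV,
    junction_mV = attr(points, "junction_mV") %||% 0
  ), class = "iv_fit")
}

#' @export
print.iv_fit <- function(x, ...) {
  cat(sprintf(
    "<iv_fit> G = %.3g +/- %.2g pS, E_rev = %.3g +/- %.2g mV (n = %d, |V| > %g mV)\n",
    x$conductance_pS["mean"], x$conductance_pS["sd"],
    x$e_rev_mV["mean"], x$e_rev_mV["sd"], x$n, x$exclude_mV
  ))
  invisible(x)
}

#' Detect current saturation on either limb of the I/V relation
#'
#' A reference line is fitted to the low-driving-force points
#' (`|V - E_rev| <= sat_boundary_mV`, outside the exclusion window, pooled
#' across replicates). For each sign of the driving force, the points beyond
#' the boundary are compared with the extrapolated line: a limb is flagged
#' saturating when the mean observed/extrapolated amplitude ratio falls
#' below `1 - deficit`.
#'
#' @param points An `iv_points` data.frame.
#' @param fit An [fit_iv_linear()] result (supplies E_rev and the exclusion
#'   window).
#' @param sat_boundary_mV Driving-force boundary separating the reference
#'   window from the assessed region (default 50 mV).
#' @param deficit Fractional deficit that triggers the flag (default 0.15).
#' @return A list of class `saturation_report`: per-limb mean ratios and
#'   flags (`NA` where a limb is not assessable).
#' @export
detect_saturation <- function(points, fit, sat_boundary_mV = 50,
                              deficit = 0.15) {
  e_rev <- unname(fit$e_rev_mV["mean"])
  outside_excl <- abs(points$corrected_mV) > fit$exclude_mV
  g <- unname(fit$conductance_pS["mean"])
  icpt <- -g * 1e-3 * e_rev
  # the reference window |V - E_rev| <= boundary depends on E_rev, which the
  # global fit may itself bias when one limb saturates; iterate window
  # selection and reference refit until the window is stable
  ref_prev <- rep(NA, nrow(points))
  for (iter in 1:10) {
    d <- points$corrected_mV - e_rev
    ref <- outside_excl & abs(d) <= sat_boundary_mV
    if (identical(ref, ref_prev)) break
    ref_prev <- ref
    if (sum(ref) < 2 || length(unique(points$corrected_mV[ref])) < 2) break
    ref_fit <- lm(points$amplitude_pA[ref] ~ points$corrected_mV[ref])
    icpt <- unname(coef(ref_fit)[1])
    g <- 1000 * unname(coef(ref_fit)[2])
    if (abs(g) > 1e-12) e_rev <- -1000 * icpt / g
  }
  d <- points$corrected_mV - e_rev
  far <- outside_excl & abs(d) > sat_boundary_mV
  if (!any(far)) {
    err_signal("no points beyond the saturation boundary: not assessable",
               "ionpore_not_assessable")
  }
  limb <- function(sgn) {
    sel <- far & sign(d) == sgn
    if (!any(sel)) return(c(ratio = NA_real_, flag = NA))
    pred <- icpt + g * points$corrected_mV[sel] * 1e-3
    ratio <- mean(points$amplitude_pA[sel] / pred)
    c(ratio = ratio, flag = ratio < (1 - deficit))
  }
  pos <- limb(+1); neg <- limb(-1)
  structure(list(
    positive = list(ratio = unname(pos["ratio"]),
                    saturating = as.logical(pos["flag"])),
    negative = list(ratio = unname(neg["ratio"]),
                    saturating = as.logical(neg["flag"])),
    reference_g_pS = g, sat_boundary_mV = sat_boundary_mV, deficit = deficit
  ), class = "saturation_report")
}

#' Classify ionic selectivity from the reversal potential
#'
#' Compares the measured reversal potential with the cation and anion
#' Nernst potentials: the pore is labelled by whichever equilibrium
#' potential it sits closer to. When `e_rev` lies within the Nernst
#' interval, the P_Cl/P_K permeability ratio from [pcl_pk_from_erev()] is
#' attached.
#'
#' @param e_rev Measured reversal potential, mV.
#' @param nernst_cation,nernst_anion Nernst potentials of the cation and
#'   anion, mV (must differ).
#' @param k_cis,k_trans Optional KCl concentrations for the GHK ratio.
#' @param rt_over_f Thermal voltage, mV.
#' @return A list with `label` ("cation-preferring", "anion-preferring" or
#'   "nonselective (tie)"), `proximity_ratio` (distance-to-cation /
#'   distance-to-anion), and `pcl_pk` (or NA).
#' @export
classify_selectivity <- function(e_rev, nernst_cation, nernst_anion,
                                 k_cis = NULL, k_trans = NULL,
                                 rt_over_f = thermal_voltage(22)) {
  if (nernst_cation == nernst_anion) {
    err_domain("cation and anion Nernst potentials must differ")
  }
  d_cat <- abs(e_rev - nernst_cation)
  d_an <- abs(e_rev - nernst_anion)
  label <- if (d_cat < d_an) {
    "cation-preferring"
  } else if (d_an < d_cat) {
    "anion-preferring"
  } else {
    "nonselective (tie)"
  }
  pcl_pk <- NA_real_
  if (!is.null(k_cis) && !is.null(k_trans)) {
    pcl_pk <- tryCatch(
      pcl_pk_from_erev(e_rev, k_cis, k_trans, rt_over_f),
      ionpore_domain_error = function(e) NA_real_
    )
  }
  list(label = label, proximity_ratio = d_cat / d_an, pcl_pk = pcl_pk)
}
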