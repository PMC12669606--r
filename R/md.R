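# Ion-permeation accounting for MD-style data: hysteresis-based detection
# of complete transmembrane crossings from ion z-trajectories, conversion
# of charge flux to conductance, species partitioning, a Poisson
# crossing-event generator, and pore hydration profiling.
#
# Direction convention: +1 = motion from the cis-equivalent side (below
# z_low) to the trans side (above z_high); positive voltage drives cations
# in the +1 direction.

#' Build an ion trajectory object
#'
#' @param z_nm Per-frame z positions (nm).
#' @param species Ion label.
#' @param z Signed valence.
#' @param dt_ps Frame interval in ps (> 0).
#' @param z_low,z_high Membrane slab bounds in nm (`z_low < z_high`).
#' @param box_z_nm Optional periodic box length along z, used to unwrap
#'   jumps larger than half the box.
#' @return An object of class `ion_trajectory`.
#' @export
ion_trajectory <- function(z_nm, species = "K", z = 1L, dt_ps = 10,
                           z_low = -2, z_high = 2, box_z_nm = NULL) {
  if (z_low >= z_high) err_config("z_low must be < z_high")
  if (dt_ps <= 0) err_config("frame interval must be > 0")
  structure(list(
    z_nm = as.numeric(z_nm), species = species, z = as.integer(z),
    dt_ps = dt_ps, z_low = z_low, z_high = z_high, box_z_nm = box_z_nm
  ), class = "ion_trajectory")
}

# Remove periodic-image jumps: any frame-to-frame step larger than box/2 is
# treated as a wrap and the following suffix is shifted by a box multiple.
unwrap_z <- function(z, box) {
  if (is.null(box)) return(z)
  d <- diff(z)
  shift <- -round(d / box)
  shift[abs(d) <= box / 2] <- 0
  z + c(0, cumsum(shift)) * box
}

#' Detect complete transmembrane crossing events
#'
#' Hysteresis rule on the two slab planes: an event is counted only when an
#' ion last seen below `z_low` is next seen above `z_high` (direction +1) or
#' vice versa (direction -1). Excursions into the slab that return to the
#' same side count zero. Periodic jumps are unwrapped first when a box
#' length is available.
#'
#' @param traj An [ion_trajectory()].
#' @param voltage_mV Applied voltage context stored with the events.
#' @return A `crossing_events` object (see [crossing_events()]).
#' @export
detect_crossings <- function(traj, voltage_mV = NA_real_) {
  stopifnot(inherits(traj, "ion_trajectory"))
  z <- unwrap_z(traj$z_nm, traj$box_z_nm)
  if (traj$z_high < min(z) || traj$z_low > max(z)) {
    err_config("slab bounds lie outside the trajectory range")
  }
  box <- traj$box_z_nm
  # Gap index: which inter-slab compartment the ion occupies. Without
  # periodicity there are two compartments (-1 below the slab, 0 above);
  # with a box of length L the slab repeats every L and gap k lies between
  # image k and image k+1. Moving from gap k-1 to gap k is one complete
  # traversal; frames inside a slab image carry no gap and are skipped, so
  # excursions that re-enter the same gap count zero (hysteresis).
  if (is.null(box)) {
    gap <- ifelse(z < traj$z_low, -1L, ifelse(z > traj$z_high, 0L, NA_integer_))
  } else {
    cell <- floor((z - traj$z_low) / box)
    inside <- (z - cell * box) <= traj$z_high
    gap <- ifelse(inside, NA_integer_, as.integer(floor((z - traj$z_high) / box)))
  }
  keep <- which(!is.na(gap))
  s <- gap[keep]
  t_ns <- (keep - 1L) * traj$dt_ps * 1e-3
  ev_time <- numeric(0); ev_dir <- integer(0)
  if (length(s) > 1) {
    ch <- which(diff(s) != 0L)
    for (j in ch) {
      steps <- s[j + 1L] - s[j]
      ev_time <- c(ev_time, rep(t_ns[j + 1L], abs(steps)))
      ev_dir <- c(ev_dir, rep(as.integer(sign(steps)), abs(steps)))
    }
  }
  crossing_events(
    data.frame(time_ns = ev_time,
               species = rep(traj$species, length(ev_dir)),
               valence = rep(traj$z, length(ev_dir)),
               direction = ev_dir),
    voltage_mV = voltage_mV,
    duration_ns = (length(traj$z_nm) - 1L) * traj$dt_ps * 1e-3
  )
}

#' Crossing event set
#'
#' Signed per-species transmembrane crossing events with their voltage and
#' duration context.
#'
#' @param events data.frame with columns `time_ns`, `species`, `valence`,
#'   `direction` (+1 cis to trans, -1 reverse).
#' @param voltage_mV Applied voltage (mV).
#' @param duration_ns Observation time (ns, > 0).
#' @return Object of class `crossing_events`.
#' @export
crossing_events <- function(events, voltage_mV, duration_ns) {
  if (duration_ns <= 0) err_domain("duration must be > 0")
  if (nrow(events) > 0 && any(abs(events$direction) != 1)) {
    err_domain("event directions must be +1 or -1")
  }
  structure(list(events = events, voltage_mV = voltage_mV,
                 duration_ns = duration_ns),
            class = "crossing_events")
}

#' @export
print.crossing_events <- function(x, ...) {
  cat(sprintf("<crossing_events> %d events over %g ns at %g mV\n",
              nrow(x$events), x$duration_ns, x$voltage_mV))
  invisible(x)
}

#' Conductance from transmembrane charge flux
#'
#' `G = (sum over events of z_i * e * direction_i) / (V * t)`, expressed in
#' pS. Anions moving against the field add constructively to the current
#' (their `z * direction` product is positive under the sign convention).
#'
#' @param x A `crossing_events` object.
#' @return Conductance in pS.
#' @export
conductance_from_crossings <- function(x) {
  stopifnot(inherits(x, "crossing_events"))
  if (is.na(x$voltage_mV) || x$voltage_mV == 0) {
    err_domain("conductance requires a non-zero applied voltage")
  }
  q <- sum(x$events$valence * x$events$direction) * phys_constants$e # C
  v <- x$voltage_mV * 1e-3
  t <- x$duration_ns * 1e-9
  1e12 * q / (v * t)
}

#' Per-species contribution to the pore current
#'
#' Default statistic: |charge flux| per species normalized to the summed
#' |charge flux| over species. Count fractions (unsigned event counts) are
#' reported alongside.
#'
#' @param x A `crossing_events` object with at least one event.
#' @return data.frame with columns `species`, `charge_fraction`,
#'   `count_fraction`; charge fractions sum to 1.
#' @export
species_current_fraction <- function(x) {
  stopifnot(inherits(x, "crossing_events"))
  ev <- x$events
  if (nrow(ev) == 0) {
    err_signal("no crossing events: fractions not assessable",
               "ionpore_not_assessable")
  }
  flux <- tapply(ev$valence * ev$direction, ev$species, sum)
  cnt <- tapply(rep(1, nrow(ev)), ev$species, sum)
  data.frame(
    species = names(flux),
    charge_fraction = as.numeric(abs(flux) / sum(abs(flux))),
    count_fraction = as.numeric(cnt / sum(cnt)),
    row.names = NULL
  )
}

#' Simulate Poisson crossing events at a target conductance
#'
#' Each species is an independent Poisson process with rate
#' `lambda_s = share_s * G * |V| / (|z_s| * e)`; event times are uniform on
#' the window given the counts; all events carry the current direction
#' implied by the sign of the voltage and the ion valence, so
#' [conductance_from_crossings()] is an unbiased estimator of `target_pS`.
#'
#' @param target_pS Target conductance in pS (>= 0).
#' @param voltage_mV Applied voltage (non-zero).
#' @param duration_ns Window length in ns.
#' @param species data.frame with columns `species`, `valence`, `share`
#'   (conductance shares, non-negative, summing to 1). Default: pure K+.
#' @param seed Integer seed (deterministic output).
#' @return A `crossing_events` object.
#' @export
simulate_crossing_events <- function(target_pS, voltage_mV, duration_ns,
                                     species = data.frame(
                                       species = "K", valence = 1L,
                                       share = 1
                                     ),
                                     seed = NULL) {
  if (target_pS < 0) err_domain("target conductance must be >= 0")
  if (voltage_mV == 0) err_domain("voltage must be non-zero")
  if (any(species$share < 0)) err_domain("species shares must be >= 0")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(species)), function(i) {
      sp <- species[i, ]
      # events per second carried by this species
      lam <- sp$share * (target_pS * 1e-12) * abs(voltage_mV * 1e-3) /
        (abs(sp$valence) * phys_constants$e)
      n <- rpois(1, lam * duration_ns * 1e-9)
      if (n == 0) return(NULL)
      data.frame(
        time_ns = sort(runif(n, 0, duration_ns)),
        species = sp$species,
        valence = as.integer(sp$valence),
        direction = as.integer(sign(voltage_mV) * sign(sp$valence))
      )
    })
    ev <- do.call(rbind, rows)
    if (is.null(ev)) {
      ev <- data.frame(time_ns = numeric(0), species = character(0),
                       valence = integer(0), direction = integer(0))
    }
    crossing_events(ev, voltage_mV, duration_ns)
  })
}

#' Pore hydration profile
#'
#' Mean (+/- SD over frames) water occupancy per z-bin across the membrane
#' slab, with a continuity flag that is TRUE when every bin has positive
#' mean occupancy (a continuously hydrated pore).
#'
#' @param frames List of numeric vectors: per-frame z positions (nm) of the
#'   water molecules inside the pore cylinder.
#' @param z_low,z_high Slab bounds (nm).
#' @param bin_nm Bin width (nm, > 0).
#' @return A list of class `hydration_profile`: data.frame `profile`
#'   (`z_mid_nm`, `mean_count`, `sd_count`) and `continuous` flag.
#' @export
hydration_profile <- function(frames, z_low, z_high, bin_nm = 0.1) {
  if (bin_nm <= 0) err_domain("bin width must be > 0")
  if (length(frames) == 0) err_input("empty frame set")
  breaks <- seq(z_low, z_high, by = bin_nm)
  if (breaks[length(breaks)] < z_high) breaks <- c(breaks, z_high)
  nb <- length(breaks) - 1L
  counts <- vapply(frames, function(z) {
    z <- z[z >= z_low & z <= z_high]
    tabulate(pmin(findInterval(z, breaks, rightmost.closed = TRUE), nb),
             nbins = nb)
  }, numeric(nb))
  counts <- matrix(counts, nrow = nb)
  prof <- data.frame(
    z_mid_nm = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_count = rowMeans(counts),
    sd_count = apply(counts, 1, sd)
  )
  structure(list(profile = prof, continuous = all(prof$mean_count > 0),
                 bin_nm = bin_nm),
            class = "hydration_profile")
}
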