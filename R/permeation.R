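# Selectivity-filter site assignment, permeation-event counting, and
# single-channel conductance.

#' Build a selectivity-filter site model
#'
#' Six site planes, one per SF residue, each the mean z of the four
#' subunits' backbone carbonyl O atoms (time-averaged by default, since
#' the SF is held near-rigid); the five intervals between consecutive
#' planes are the K+ sites S4 (innermost, lowest z) up to S0
#' (outermost).  Non-monotone average planes mean the structure is not
#' SF-like and raise an error.
#'
#' @param traj A `trajectory_set`.
#' @param sf_resids SF residue numbers, inner to outer (default 358:363).
#' @param frames Frames to average over (default all).
#' @param entry_margin Hysteresis margin (Angstrom) applied at the outer
#'   boundaries by [site_timeseries()] to suppress flicker.
#' @return An `sf_model`: `planes` (6 increasing z values), `sites`
#'   (names S4..S0, bottom to top), `entry_margin`.
#' @export
build_sf_model <- function(traj, sf_resids = 358:363, frames = NULL,
                           entry_margin = 2) {
  frames <- frames %||% seq_len(n_frames(traj))
  sus <- c("I", "II", "III", "IV")
  planes <- numeric(length(sf_resids))
  for (r in seq_along(sf_resids)) {
    idx <- integer(0)
    for (su in sus) {
      ch <- chains_for_subunit(traj, su)
      i <- select_atoms(traj, chain = ch, resid = sf_resids[r], name = "O")
      if (length(i) != 1)
        stopf("subunit %s residue %d: expected one backbone O, found %d",
              su, sf_resids[r], length(i))
      idx <- c(idx, i)
    }
    planes[r] <- mean(traj$xyz[frames, 3 * idx, drop = FALSE])
  }
  if (all(diff(planes) < 0)) planes <- rev(planes)
  if (any(diff(planes) <= 0))
    stopf("SF planes are not monotone in z (%s); structure is not SF-like",
          paste(sprintf("%.2f", planes), collapse = ", "))
  structure(list(planes = planes, sites = c("S4", "S3", "S2", "S1", "S0"),
                 entry_margin = entry_margin, sf_resids = sf_resids),
            class = "sf_model")
}

#' Per-frame SF site labels for ions
#'
#' Labels each ion `below`, `S4`..`S0`, or `above` from its z interval,
#' with hysteresis at the two outer planes: once inside the filter an
#' ion is only relabelled `below`/`above` after retreating
#' `entry_margin` beyond the outer plane, suppressing boundary flicker.
#'
#' @param traj A `trajectory_set`.
#' @param sf An `sf_model`.
#' @param ion_atoms Atom indices of the ions to track.
#' @return List of character vectors (one per ion, named by atom index).
#' @export
site_timeseries <- function(traj, sf, ion_atoms) {
  p <- sf$planes; m <- sf$entry_margin
  lab_inside <- function(z) {
    j <- findInterval(z, p, rightmost.closed = TRUE)
    j <- min(max(j, 1L), 5L)      # clamp to the nearest site while "inside"
    sf$sites[j]
  }
  out <- list()
  for (ia in ion_atoms) {
    z <- traj$xyz[, 3 * ia]
    lab <- character(length(z))
    region <- if (z[1] <= p[1]) "below" else if (z[1] >= p[6]) "above" else "inside"
    for (f in seq_along(z)) {
      region <- switch(region,
        below = if (z[f] > p[1]) "inside" else "below",
        above = if (z[f] < p[6]) "inside" else "above",
        inside = if (z[f] < p[1] - m) "below"
                 else if (z[f] > p[6] + m) "above" else "inside")
      lab[f] <- if (region == "inside") lab_inside(z[f]) else region
    }
    out[[as.character(ia)]] <- lab
  }
  out
}

#' Count complete permeation events
#'
#' An event is a maximal passage from `below` to `above` (direction +1)
#' or `above` to `below` (-1) that visits at least one SF site; partial
#' entries that retreat to the entry side are not events.  Net flux is
#' the signed sum.
#'
#' @param site_series List of per-ion label vectors from
#'   [site_timeseries()] (a single vector is also accepted).
#' @param times Frame times in ns (for the record duration).
#' @param voltage_mv Applied transmembrane voltage (mV), carried into
#'   the record for [conductance()].
#' @return A `permeation_record`: `events` data frame (`ion`,
#'   `entry_frame`, `exit_frame`, `direction`), `n_up`, `n_down`,
#'   `net_flux`, `total_events`, `duration_ns`, `voltage_mv`.
#' @export
count_permeations <- function(site_series, times = NULL, voltage_mv = NA) {
  if (is.character(site_series)) site_series <- list(site_series)
  events <- data.frame(ion = character(0), entry_frame = integer(0),
                       exit_frame = integer(0), direction = integer(0),
                       stringsAsFactors = FALSE)
  for (nm in seq_along(site_series)) {
    lab <- site_series[[nm]]
    ion_id <- names(site_series)[nm] %||% as.character(nm)
    if (is.null(ion_id) || !nzchar(ion_id)) ion_id <- as.character(nm)
    side <- NA_character_       # last outside region seen
    entry <- NA_integer_        # first inside frame of the current passage
    for (f in seq_along(lab)) {
      l <- lab[f]
      if (l %in% c("below", "above")) {
        if (!is.na(side) && !is.na(entry) && l != side) {
          events <- rbind(events, data.frame(
            ion = ion_id, entry_frame = entry, exit_frame = f,
            direction = if (side == "below") 1L else -1L,
            stringsAsFactors = FALSE))
        }
        side <- l
        entry <- NA_integer_
      } else {
        if (is.na(entry)) entry <- f
      }
    }
  }
  duration <- if (!is.null(times) && length(times) > 1)
    times[length(times)] - times[1] else NA_real_
  structure(list(events = events,
                 n_up = sum(events$direction == 1L),
                 n_down = sum(events$direction == -1L),
                 net_flux = sum(events$direction),
                 total_events = nrow(events),
                 duration_ns = duration, voltage_mv = voltage_mv),
            class = "permeation_record")
}

#' @export
print.permeation_record <- function(x, ...) {
  cat(sprintf("permeation_record: %d events (%d up, %d down), net flux %+d\n",
              x$total_events, x$n_up, x$n_down, x$net_flux))
  if (!is.na(x$duration_ns))
    cat(sprintf("  duration %.1f ns, voltage %s mV\n", x$duration_ns,
                format(x$voltage_mv)))
  invisible(x)
}

#' Single-channel conductance from a permeation record
#'
#' `g = net_flux * e / (duration * |V|)`, with the elementary charge
#' e = 1.602176634e-19 C, reported in pS.  Net flux (not total events)
#' is used so opposing crossings cancel, matching the physical current;
#' the total event count is available on the record.
#'
#' @param record A `permeation_record`, or NULL when giving the pieces
#'   directly.
#' @param net_flux Signed crossing count (overrides the record).
#' @param duration_ns Observation time in ns.
#' @param voltage_mv Applied voltage in mV.
#' @return Conductance in pS (signed by the flux direction).
#' @export
#' @examples
#' conductance(net_flux = 58, duration_ns = 5000, voltage_mv = 750)  # ~2.478
conductance <- function(record = NULL, net_flux = NULL, duration_ns = NULL,
                        voltage_mv = NULL) {
  if (!is.null(record)) {
    net_flux <- net_flux %||% record$net_flux
    duration_ns <- duration_ns %||% record$duration_ns
    voltage_mv <- voltage_mv %||% record$voltage_mv
  }
  if (is.null(duration_ns) || is.na(duration_ns) || duration_ns <= 0)
    stopf("duration must be positive")
  if (is.null(voltage_mv) || is.na(voltage_mv) || voltage_mv == 0)
    stopf("voltage must be nonzero")
  current_a <- net_flux * .ELEMENTARY_CHARGE / (duration_ns * 1e-9)
  g_s <- current_a / (abs(voltage_mv) * 1e-3)
  g_s * 1e12
}
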