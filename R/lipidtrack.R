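# Lateral lipid tracking: unwrapped XY paths, residue-contact
# itineraries, binding-site taxonomy (transient / transfer / activation)
# and transfer classification.

#' Shipped binding-site definitions
#'
#' The default site taxonomy for SK2: a transient site (R271, K278,
#' R286), an activation site (R299, R395, K396, K471) and the relay
#' residue R418 that transfers lipids between them.  Config-driven so
#' other SK isoforms can be re-labelled.
#'
#' @param transient,activation Character vectors of residue base labels.
#' @param transfer_residue Relay residue base label.
#' @return A `site_definitions` list.
#' @export
default_site_definitions <- function(transient = c("R271", "K278", "R286"),
                                     activation = c("R299", "R395", "K396", "K471"),
                                     transfer_residue = "R418") {
  both <- intersect(transient, activation)
  if (length(both))
    stopf("site residue sets must be disjoint (shared: %s)",
          paste(both, collapse = ", "))
  structure(list(transient = transient, activation = activation,
                 transfer_residue = transfer_residue),
            class = "site_definitions")
}

# "R271.III" -> "R271"
base_label <- function(label) sub("\\.[^.]*$", "", label)

#' Unwrapped lateral track of one lipid
#'
#' Headgroup-centroid XY path with periodic jumps removed by
#' minimum-image increment accumulation; the leaflet is assigned from
#' the mean headgroup z against the bilayer midplane (trajectory-mean,
#' not per frame, to avoid flicker).
#'
#' @param traj A `trajectory_set`.
#' @param lipid A `charge_group` for the lipid headgroup, or a lipid
#'   residue id (passed to [lipid_charge_group()]).
#' @param midplane_z Bilayer midplane (Angstrom); defaults to half the
#'   box height.
#' @return A `lipid_track`: `xy` (`n_frames x 2`, unwrapped, Angstrom),
#'   `leaflet` (`"upper"`/`"lower"`), `lipid` label.
#' @export
unwrap_xy <- function(traj, lipid, midplane_z = NULL) {
  if (!inherits(lipid, "charge_group")) lipid <- lipid_charge_group(traj, lipid)
  ctr <- charge_centers_all(traj, lipid)
  nf <- n_frames(traj)
  box_xy <- traj$box[, 1:2, drop = FALSE]
  xy <- matrix(NA_real_, nf, 2, dimnames = list(NULL, c("x", "y")))
  xy[1, ] <- ctr[1, 1:2]
  if (nf > 1) {
    raw <- diff(ctr[, 1:2, drop = FALSE])
    inc <- raw - box_xy[-1, , drop = FALSE] * round(raw / box_xy[-1, , drop = FALSE])
    if (any(abs(inc) > box_xy[-1, ] / 2))
      stopf("per-frame displacement exceeds half the box; sampling too sparse to unwrap")
    xy[-1, ] <- xy[rep(1, nf - 1), ] + apply(inc, 2, cumsum)
  }
  midplane_z <- midplane_z %||% mean(traj$box[, 3]) / 2
  leaflet <- if (mean(ctr[, 3]) < midplane_z) "lower" else "upper"
  structure(list(lipid = lipid$label, xy = xy, leaflet = leaflet,
                 times = traj$times), class = "lipid_track")
}

#' Residue-contact itinerary of one lipid
#'
#' Visits are the maximal contact runs (via [bridge_events()]) of the
#' lipid against each candidate residue under the centre-of-charge
#' tracking rule, merged into one chronological list.  Simultaneous
#' contacts are allowed; ties on `first_frame` are broken by residue
#' label.
#'
#' @param traj A `trajectory_set`.
#' @param lipid Acidic `charge_group` for the lipid headgroup.
#' @param residues Named list of basic `charge_group`s.
#' @param cutoff Tracking cutoff in Angstrom (paper protocol: 5.5).
#' @param min_dwell Minimum visit length in frames (a brush-contact
#'   filter; default 1 counts every contact run).
#' @return A `lipid_itinerary`: data frame `visits` with `residue`,
#'   `first_frame`, `last_frame`.
#' @export
build_itinerary <- function(traj, lipid, residues, cutoff = 5.5, min_dwell = 1) {
  if (!length(residues)) stopf("residue list is empty")
  series <- scan_partner_residues(traj, lipid, residues, cutoff, mode = "center")
  vis <- list()
  for (lab in names(series)) {
    ev <- bridge_events(series[[lab]], min_dwell = min_dwell)
    if (nrow(ev))
      vis[[lab]] <- data.frame(residue = lab, first_frame = ev$formed_frame,
                               last_frame = ev$broken_frame,
                               stringsAsFactors = FALSE)
  }
  visits <- if (length(vis)) do.call(rbind, vis) else
    data.frame(residue = character(0), first_frame = integer(0),
               last_frame = integer(0))
  visits <- visits[order(visits$first_frame, visits$residue), , drop = FALSE]
  rownames(visits) <- NULL
  structure(list(lipid = lipid$label, visits = visits, cutoff = cutoff),
            class = "lipid_itinerary")
}

#' Classify site-to-site transfers in an itinerary
#'
#' Emits a transfer whenever the lipid's site label changes between
#' consecutive site-assigned visits; if the intervening visit(s) include
#' the relay residue, `via_residue` is set.  Residues belonging to no
#' site (and not the relay) are collected under the `unassigned`
#' attribute rather than raising an error.
#'
#' @param itin A `lipid_itinerary` (or its `visits` data frame).
#' @param sites A `site_definitions` list.
#' @return Data frame with `from_site`, `to_site`, `via_residue` (NA if
#'   direct) and `frame` (first frame of the arriving visit), with
#'   attribute `unassigned`.
#' @export
classify_transfers <- function(itin, sites = default_site_definitions()) {
  visits <- if (is.data.frame(itin)) itin else itin$visits
  site_of <- function(lab) {
    b <- base_label(lab)
    if (b %in% sites$transient) "transient"
    else if (b %in% sites$activation) "activation"
    else if (b %in% sites$transfer_residue) "transfer"
    else NA_character_
  }
  out <- data.frame(from_site = character(0), to_site = character(0),
                    via_residue = character(0), frame = integer(0),
                    stringsAsFactors = FALSE)
  unassigned <- character(0)
  cur_site <- NA_character_
  via <- NA_character_
  for (i in seq_len(nrow(visits))) {
    s <- site_of(visits$residue[i])
    if (is.na(s)) {
      unassigned <- union(unassigned, visits$residue[i])
      next
    }
    if (s == "transfer") {
      via <- visits$residue[i]
      next
    }
    if (!is.na(cur_site) && s != cur_site) {
      out <- rbind(out, data.frame(from_site = cur_site, to_site = s,
                                   via_residue = via,
                                   frame = visits$first_frame[i],
                                   stringsAsFactors = FALSE))
    }
    via <- NA_character_   # relay counts only between consecutive site visits
    cur_site <- s
  }
  attr(out, "unassigned") <- unassigned
  out
}

#' Per-residue lipid occupancy
#'
#' Fraction of frames each residue is contacted by at least one lipid,
#' the mean visit dwell, and visit counts.  Contact totals are
#' conserved: summing per-lipid visit lengths recovers the total contact
#' frames counted with multiplicity.
#'
#' @param traj A `trajectory_set`.
#' @param lipids List of acidic lipid `charge_group`s.
#' @param residues Named list of basic residue `charge_group`s.
#' @param cutoff Tracking cutoff in Angstrom.
#' @return Data frame with `residue`, `fraction`, `mean_dwell`,
#'   `n_visits`, `contact_frames` (with multiplicity).
#' @export
occupancy_map <- function(traj, lipids, residues, cutoff = 5.5) {
  if (!length(lipids)) stopf("need at least one lipid")
  nf <- n_frames(traj)
  out <- data.frame(residue = names(residues), fraction = 0,
                    mean_dwell = NA_real_, n_visits = 0L,
                    contact_frames = 0L, stringsAsFactors = FALSE)
  for (r in seq_along(residues)) {
    any_contact <- rep(FALSE, nf)
    dwells <- integer(0)
    total <- 0L
    for (lp in lipids) {
      cs <- contact_timeseries(traj, residues[[r]], lp, cutoff, mode = "center")
      any_contact <- any_contact | cs$states
      ev <- bridge_events(cs)
      dwells <- c(dwells, ev$broken_frame - ev$formed_frame + 1L)
      total <- total + sum(cs$states)
    }
    out$fraction[r] <- mean(any_contact)
    out$mean_dwell[r] <- if (length(dwells)) mean(dwells) else NA_real_
    out$n_visits[r] <- length(dwells)
    out$contact_frames[r] <- total
  }
  out
}
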