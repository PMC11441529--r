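# Salt-bridge detection between charged groups: centre-of-charge
# tracking (5.5 A protocol) and minimum heavy-atom N...O criterion
# (3.6 A time-series rule), plus event extraction.

# Charged heavy atoms per residue type, the groups whose centroid is the
# "centre of charge".
.CHARGED_ATOMS <- list(
  ARG = list(atoms = c("NE", "NH1", "NH2"), polarity = "basic"),
  LYS = list(atoms = "NZ", polarity = "basic"),
  GLU = list(atoms = c("OE1", "OE2"), polarity = "acidic"),
  ASP = list(atoms = c("OD1", "OD2"), polarity = "acidic"))

#' Define a charged group
#'
#' @param traj A `trajectory_set` (used to validate the indices).
#' @param label Group label, e.g. `"R395.III"` or `"PIP#2"`.
#' @param atom_indices 1-based atom indices of the charged heavy atoms.
#' @param polarity `"basic"` or `"acidic"` (lipid phosphate groups are
#'   acidic).
#' @param center_rule `"centroid"` (centre of the charged atoms) or
#'   `"single_atom"` (first index).
#' @return A `charge_group`.
#' @export
charge_group <- function(traj, label, atom_indices, polarity,
                         center_rule = c("centroid", "single_atom")) {
  center_rule <- match.arg(center_rule)
  atom_indices <- as.integer(atom_indices)
  if (!length(atom_indices)) stopf("charge group '%s' has no atoms", label)
  if (any(atom_indices < 1 | atom_indices > n_atoms(traj)))
    stopf("charge group '%s': atom index out of range", label)
  key <- unique(paste(traj$atoms$chain[atom_indices],
                      traj$atoms$resid[atom_indices]))
  if (length(key) > 1)
    stopf("charge group '%s' spans several residues (%s)", label,
          paste(key, collapse = "; "))
  polarity <- match.arg(polarity, c("basic", "acidic"))
  structure(list(label = label, atom_indices = atom_indices,
                 polarity = polarity, center_rule = center_rule),
            class = "charge_group")
}

#' Charge group for a protein residue
#'
#' Picks the charged heavy atoms by residue type (Arg guanidinium N,
#' Lys NZ, Glu/Asp carboxylate O) and infers the polarity.
#'
#' @param traj A `trajectory_set`.
#' @param chain Chain id, or `subunit` label instead.
#' @param resid Author residue number.
#' @param subunit Subunit label looked up in the subunit map.
#' @return A `charge_group` labelled `"<X><resid>.<subunit>"`.
#' @export
residue_charge_group <- function(traj, resid, chain = NULL, subunit = NULL) {
  if (is.null(chain)) {
    if (is.null(subunit)) stopf("give either chain or subunit")
    chain <- chains_for_subunit(traj, subunit)
    if (length(chain) != 1)
      stopf("subunit '%s' maps to %d chains", subunit, length(chain))
  }
  idx_all <- select_atoms(traj, chain = chain, resid = resid)
  if (!length(idx_all)) stopf("no atoms for residue %d in chain %s", resid, chain)
  resname <- traj$atoms$resname[idx_all[1]]
  spec <- .CHARGED_ATOMS[[resname]]
  if (is.null(spec)) stopf("no charged-atom rule for residue type '%s'", resname)
  idx <- idx_all[traj$atoms$name[idx_all] %in% spec$atoms]
  missing <- setdiff(spec$atoms, traj$atoms$name[idx])
  if (length(missing))
    stopf("residue %s%d (%s) lacks charged atom(s): %s", resname, resid, chain,
          paste(missing, collapse = ", "))
  su <- unname(traj$subunit_map[chain])
  code <- c(ARG = "R", LYS = "K", GLU = "E", ASP = "D")[resname]
  charge_group(traj, sprintf("%s%d.%s", code, resid, su), idx, spec$polarity)
}

#' Charge group for a PIP2-like lipid headgroup
#'
#' The phosphate-bonded charged oxygen atoms of one lipid; the default
#' centre rule is the whole-headgroup centroid (the tracking protocol).
#'
#' @param traj A `trajectory_set`.
#' @param lipid_id Lipid residue number within the lipid chain.
#' @param resname Lipid residue name.
#' @return An acidic `charge_group` labelled `"PIP#<id>"`.
#' @export
lipid_charge_group <- function(traj, lipid_id, resname = "PIP") {
  chains <- chains_for_subunit(traj, "lipid")
  idx <- select_atoms(traj, chain = chains, resid = lipid_id,
                      resname = resname, elem = "O")
  if (!length(idx)) stopf("no headgroup O atoms for lipid %d", lipid_id)
  charge_group(traj, sprintf("PIP#%d", lipid_id), idx, "acidic")
}

#' Centre of charge of a group in one frame
#'
#' Centroid of the group's charged heavy atoms (or the single designated
#' atom under the `single_atom` rule).
#'
#' @param traj A `trajectory_set`.
#' @param group A `charge_group`.
#' @param frame 1-based frame index.
#' @return Length-3 coordinate vector (Angstrom).
#' @export
charge_center <- function(traj, group, frame) {
  idx <- group$atom_indices
  if (group$center_rule == "single_atom") idx <- idx[1]
  colMeans(atom_coords(traj, frame, idx))
}

# Per-frame centres of a group across all frames (n_frames x 3).
charge_centers_all <- function(traj, group) {
  idx <- group$atom_indices
  if (group$center_rule == "single_atom") idx <- idx[1]
  x <- traj$xyz[, 3 * idx - 2, drop = FALSE]
  y <- traj$xyz[, 3 * idx - 1, drop = FALSE]
  z <- traj$xyz[, 3 * idx, drop = FALSE]
  cbind(rowMeans(x), rowMeans(y), rowMeans(z))
}

#' Per-frame contact state of a pair of charged groups
#'
#' `mode = "center"` is the lipid-tracking protocol: minimum-image
#' distance between the centres of charge (paper cutoff 5.5 A).
#' `mode = "heavy_atom_min"` is the salt-bridge criterion: the minimum
#' N...O heavy-atom distance (paper cutoff 3.6 A).  Groups must have
#' opposite polarity.
#'
#' @param traj A `trajectory_set`.
#' @param a,b `charge_group`s of opposite polarity.
#' @param cutoff Distance cutoff in Angstrom.
#' @param mode Distance rule, see above.
#' @return A `contact_series`: per-frame logical `states`, per-frame
#'   `min_distance` (Angstrom), the pair labels, cutoff and mode.
#' @export
contact_timeseries <- function(traj, a, b, cutoff,
                               mode = c("center", "heavy_atom_min")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (a$polarity == b$polarity)
    stopf("groups '%s' and '%s' have the same polarity (%s)",
          a$label, b$label, a$polarity)
  nf <- n_frames(traj)
  if (mode == "center") {
    d <- min_image_distance(charge_centers_all(traj, a),
                            charge_centers_all(traj, b), traj$box)
  } else {
    d <- rep(Inf, nf)
    for (ia in a$atom_indices) {
      pa <- traj$xyz[, xyz_cols(ia), drop = FALSE]
      for (ib in b$atom_indices) {
        pb <- traj$xyz[, xyz_cols(ib), drop = FALSE]
        d <- pmin(d, min_image_distance(pa, pb, traj$box))
      }
    }
  }
  structure(list(pair = c(a$label, b$label), cutoff = cutoff, mode = mode,
                 states = d <= cutoff, min_distance = d, times = traj$times),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact_series %s : %s (%s, cutoff %.2f A): %d/%d frames formed\n",
              x$pair[1], x$pair[2], x$mode, x$cutoff,
              sum(x$states), length(x$states)))
  invisible(x)
}

#' Formation/breaking events of a contact series
#'
#' Maximal runs of formed frames.  False gaps shorter than `min_dwell`
#' are merged first (optional smoothing), then runs shorter than
#' `min_dwell` are dropped.  With the default `min_dwell = 1` the events
#' are exactly the maximal true runs.
#'
#' @param series A `contact_series` (or plain logical vector).
#' @param min_dwell Minimum run length in frames (>= 1).
#' @return Data frame with `formed_frame` and `broken_frame` (1-based,
#'   inclusive), ordered by `formed_frame`.
#' @export
bridge_events <- function(series, min_dwell = 1) {
  if (min_dwell < 1) stopf("min_dwell must be >= 1")
  states <- if (inherits(series, "contact_series")) series$states else series
  if (min_dwell > 1 && any(states)) {
    r <- rle(states)
    gap <- !r$values & r$lengths < min_dwell
    gap[c(1, length(r$values))] <- FALSE   # leading/trailing gaps stay
    r$values[gap] <- TRUE
    states <- inverse.rle(r)
  }
  ev <- runs_to_events(states)
  ev[ev$broken_frame - ev$formed_frame + 1 >= min_dwell, , drop = FALSE]
}

#' Contact series between one lipid and many candidate residues
#'
#' @param traj A `trajectory_set`.
#' @param lipid An acidic `charge_group` (lipid headgroup).
#' @param candidates List of basic `charge_group`s.
#' @param cutoff Cutoff in Angstrom.
#' @param mode Distance rule, as in [contact_timeseries()].
#' @return Named list of `contact_series`, one per candidate.
#' @export
scan_partner_residues <- function(traj, lipid, candidates, cutoff = 5.5,
                                  mode = "center") {
  if (!length(candidates)) stopf("candidate list is empty")
  out <- lapply(candidates, function(g)
    contact_timeseries(traj, g, lipid, cutoff, mode))
  names(out) <- vapply(candidates, function(g) g$label, "")
  out
}

#' Bridge formed-fraction split by lipid-bound state
#'
#' The disruption test: how often a protein-protein salt bridge is
#' formed while the basic partner is lipid-bound versus unbound.
#'
#' @param bridge A `contact_series` for the protein-protein bridge.
#' @param bound_flags Per-frame logical: is the basic partner
#'   lipid-bound?
#' @return List with `fraction_bound`, `fraction_unbound`, `n_bound`,
#'   `n_unbound`.
#' @export
formed_fraction_by_state <- function(bridge, bound_flags) {
  states <- if (inherits(bridge, "contact_series")) bridge$states else bridge
  if (length(states) != length(bound_flags))
    stopf("frame counts differ: %d vs %d", length(states), length(bound_flags))
  list(fraction_bound = if (any(bound_flags)) mean(states[bound_flags]) else NA_real_,
       fraction_unbound = if (any(!bound_flags)) mean(states[!bound_flags]) else NA_real_,
       n_bound = sum(bound_flags), n_unbound = sum(!bound_flags))
}
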