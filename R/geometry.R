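# Pore-radius profiling (HOLE-style spherical probe), V390 gate-distance
# series with geometric averaging, selectivity-filter carbonyl distances
# and the bridge-versus-gate correlation summary.

# Probe radii at a batch of XY centres in the slice at height z:
# for each centre, the distance to the nearest vdW surface.
probe_radii_at <- function(xy, z, coords, vdw) {
  xy <- rbind(xy)
  dx <- outer(xy[, 1], coords[, 1], "-")
  dy <- outer(xy[, 2], coords[, 2], "-")
  dz2 <- (z - coords[, 3])^2
  d <- sqrt(dx * dx + dy * dy + rep(dz2, each = nrow(xy))) -
    rep(vdw, each = nrow(xy))
  dim(d) <- dim(dx)
  apply(d, 1, min)
}

# Deterministic compass (pattern) search in the XY plane at fixed z,
# polishing a start point; robust for the piecewise-smooth min-distance
# objective.  Each iteration evaluates the 8 compass moves as a batch.
compass_polish <- function(start_xy, z, coords, vdw, cap = Inf,
                           center0 = start_xy, search_radius = Inf,
                           step = 0.4, tol = 0.002) {
  moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  cur <- start_xy
  best <- min(probe_radii_at(cur, z, coords, vdw), cap)
  while (step > tol && best < cap) {
    # the objective cap and the search-radius bound keep the probe from
    # wandering out of an open (non-pore) region indefinitely
    cand <- sweep(moves * step, 2, cur, "+")
    ok <- sqrt(rowSums(sweep(cand, 2, center0)^2)) <= search_radius
    if (!any(ok)) { step <- step / 2; next }
    cand <- cand[ok, , drop = FALSE]
    v <- pmin(probe_radii_at(cand, z, coords, vdw), cap)
    i <- which.max(v)
    if (v[i] > best + 1e-12) { cur <- cand[i, ]; best <- v[i] }
    else step <- step / 2
  }
  list(xy = cur, radius = best)
}

#' HOLE-style pore-radius profile along z
#'
#' At each z slice the pore radius is the largest sphere centred in that
#' plane that touches no atom's van der Waals surface:
#' `max over c of min over atoms (|c - atom| - vdw)`.  The maximisation
#' uses the previous slice's centre plus random restarts, each polished
#' by a deterministic compass search; results are deterministic for a
#' fixed seed.  Slices with no atoms within the search shell report a
#' capped sentinel radius with a warning.
#'
#' @param traj A `trajectory_set`.
#' @param frame Frame to profile.
#' @param z_range Length-2 z interval (Angstrom) along the pore axis
#'   (the z axis by convention).
#' @param dz Slice spacing (Angstrom).
#' @param n_restarts Random restarts per slice.
#' @param seed Seed for the restarts.
#' @param atom_indices Atoms forming the pore wall; defaults to the
#'   chains mapped to subunits I-IV.
#' @param max_radius Sentinel cap for empty slices (Angstrom).
#' @param start_xy Initial centre guess; defaults to the XY box centre.
#' @param search_radius Each slice's centre search is confined to this
#'   disk (Angstrom) around the previous slice's centre, which keeps the
#'   probe threaded through the pore instead of escaping through wall
#'   gaps or into the bulk.
#' @return A `pore_profile`: data frame with `z`, `radius`, `x`, `y`.
#' @export
pore_profile <- function(traj, frame = 1, z_range, dz = 0.5, n_restarts = 32,
                         seed = 1, atom_indices = NULL, max_radius = 15,
                         start_xy = NULL, search_radius = 6) {
  if (dz <= 0) stopf("dz must be positive")
  if (is.null(atom_indices))
    atom_indices <- select_atoms(traj, subunit = c("I", "II", "III", "IV"))
  if (!length(atom_indices)) stopf("no pore-wall atoms selected")
  crd <- atom_coords(traj, frame, atom_indices)
  vdw <- traj$atoms$vdw[atom_indices]
  zs <- seq(z_range[1], z_range[2], by = dz)
  start_xy <- start_xy %||% (traj$box[frame, 1:2] / 2)
  res <- with_seed(seed, {
    out <- data.frame(z = zs, radius = NA_real_, x = NA_real_, y = NA_real_)
    prev <- start_xy
    for (i in seq_along(zs)) {
      z <- zs[i]
      shell <- abs(crd[, 3] - z) < max_radius + max(vdw)
      if (!any(shell)) {
        warning(sprintf("no atoms near slice z = %.2f; radius capped at %.1f A",
                        z, max_radius))
        out$radius[i] <- max_radius
        out$x[i] <- prev[1]; out$y[i] <- prev[2]
        next
      }
      ccrd <- crd[shell, , drop = FALSE]; cvdw <- vdw[shell]
      # coarse deterministic grid around the previous centre, plus the
      # seeded random restarts; polish only the most promising starts,
      # all confined to a search disk around the previous centre
      grid <- as.matrix(expand.grid(x = seq(-5, 5, by = 1),
                                    y = seq(-5, 5, by = 1)))
      starts <- rbind(prev,
                      sweep(grid, 2, prev, "+"),
                      matrix(rep(prev, n_restarts), ncol = 2, byrow = TRUE) +
                        matrix(stats::runif(2 * n_restarts, -search_radius,
                                            search_radius), ncol = 2))
      inb <- sqrt(rowSums(sweep(starts, 2, prev)^2)) <= search_radius
      starts <- starts[inb, , drop = FALSE]
      v0 <- probe_radii_at(starts, z, ccrd, cvdw)
      top <- order(v0, decreasing = TRUE)[seq_len(min(6, nrow(starts)))]
      best <- NULL
      for (s in top) {
        cand <- compass_polish(starts[s, ], z, ccrd, cvdw, cap = max_radius,
                               center0 = prev, search_radius = search_radius)
        if (is.null(best) || cand$radius > best$radius) best <- cand
        if (best$radius >= max_radius) break
      }
      out$radius[i] <- min(best$radius, max_radius)
      out$x[i] <- best$xy[1]; out$y[i] <- best$xy[2]
      prev <- best$xy
    }
    out
  })
  res$radius <- pmax(res$radius, 0)
  class(res) <- c("pore_profile", "data.frame")
  res
}

#' Across-subunit gate-distance series at V390
#'
#' Distances between the gate atoms of opposite subunits (I-III and
#' II-IV, fixed by the subunit map, never inferred from geometry) per
#' frame, plus their geometric mean `sqrt(d_I_III * d_II_IV)`, the
#' summary used for asymmetric gate openings.  `atom_rule` selects the
#' backbone CA or the side-chain CG atom.
#'
#' @param traj A `trajectory_set`.
#' @param resid Gate residue number (default 390).
#' @param atom_rule `"CG"` (side-chain diameter rule) or `"CA"`
#'   (backbone rule).
#' @return A `gate_series` data frame: `frame`, `time_ns`, `d_I_III`,
#'   `d_II_IV`, `geometric_mean` (Angstrom).
#' @export
gate_distances <- function(traj, resid = 390, atom_rule = c("CG", "CA")) {
  atom_rule <- match.arg(atom_rule)
  idx <- integer(4)
  for (k in 1:4) {
    su <- c("I", "II", "III", "IV")[k]
    ch <- chains_for_subunit(traj, su)
    i <- select_atoms(traj, chain = ch, resid = resid, name = atom_rule)
    if (length(i) != 1)
      stopf("subunit %s: expected one %s atom at residue %d, found %d",
            su, atom_rule, resid, length(i))
    idx[k] <- i
  }
  p <- lapply(idx, function(i) traj$xyz[, xyz_cols(i), drop = FALSE])
  d13 <- sqrt(rowSums((p[[1]] - p[[3]])^2))
  d24 <- sqrt(rowSums((p[[2]] - p[[4]])^2))
  out <- data.frame(frame = seq_len(n_frames(traj)), time_ns = traj$times,
                    d_I_III = d13, d_II_IV = d24,
                    geometric_mean = sqrt(d13 * d24))
  attr(out, "atom_rule") <- atom_rule
  class(out) <- c("gate_series", "data.frame")
  out
}

#' Cross-subunit carbonyl-oxygen distances in the selectivity filter
#'
#' For each SF residue, the backbone O-O distances of the two opposite
#' subunit pairs (I-III, II-IV) and their mean, in one frame.
#'
#' @param traj A `trajectory_set`.
#' @param frame Frame index.
#' @param sf_resids Residue numbers of the filter (default 358:363).
#' @return Data frame with `resid`, `d_I_III`, `d_II_IV`, `mean`
#'   (Angstrom).
#' @export
sf_carbonyl_distances <- function(traj, frame = 1, sf_resids = 358:363) {
  sus <- c("I", "II", "III", "IV")
  out <- data.frame(resid = sf_resids, d_I_III = NA_real_, d_II_IV = NA_real_,
                    mean = NA_real_)
  for (r in seq_along(sf_resids)) {
    crd <- matrix(NA_real_, 4, 3)
    for (k in 1:4) {
      ch <- chains_for_subunit(traj, sus[k])
      i <- select_atoms(traj, chain = ch, resid = sf_resids[r], name = "O")
      if (length(i) != 1)
        stopf("subunit %s residue %d: expected one backbone O, found %d",
              sus[k], sf_resids[r], length(i))
      crd[k, ] <- atom_coords(traj, frame, i)
    }
    d13 <- sqrt(sum((crd[1, ] - crd[3, ])^2))
    d24 <- sqrt(sum((crd[2, ] - crd[4, ])^2))
    out$d_I_III[r] <- d13; out$d_II_IV[r] <- d24; out$mean[r] <- (d13 + d24) / 2
  }
  out
}

#' Bridge formed-fraction binned by gate diameter
#'
#' Frames are binned by the geometric-mean gate distance; the per-bin
#' formed fraction of the bridge is reported together with a
#' monotone-trend statistic (Spearman correlation of bin centres against
#' fractions).  A constant fraction profile has trend 0 by definition; a
#' single occupied bin leaves the trend undefined (NA with a note).
#'
#' @param gate A `gate_series`.
#' @param bridge A `contact_series` (same frame count).
#' @param n_bins Number of equal-width bins (>= 2).
#' @return List with `bins` (data frame: `center`, `fraction`, `n`) and
#'   `trend` (Spearman rho, 0 for flat profiles, NA if undefined).
#' @export
bridge_vs_gate <- function(gate, bridge, n_bins = 6) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  states <- if (inherits(bridge, "contact_series")) bridge$states else bridge
  g <- gate$geometric_mean
  if (length(g) != length(states))
    stopf("frame counts differ: %d vs %d", length(g), length(states))
  rng <- range(g)
  if (diff(rng) == 0) {
    bins <- data.frame(center = rng[1], fraction = mean(states),
                       n = length(states))
    return(list(bins = bins, trend = NA_real_,
                note = "constant gate distance; trend undefined"))
  }
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(g, brk, include.lowest = TRUE, labels = FALSE)
  centers <- (brk[-1] + brk[-length(brk)]) / 2
  occ <- sort(unique(bin))
  frac <- vapply(occ, function(b) mean(states[bin == b]), 0)
  bins <- data.frame(center = centers[occ], fraction = frac,
                     n = as.integer(table(factor(bin, levels = occ))))
  trend <- if (nrow(bins) < 2) NA_real_
    else if (stats::sd(bins$fraction) == 0) 0
    else suppressWarnings(stats::cor(bins$center, bins$fraction,
                                     method = "spearman"))
  list(bins = bins, trend = trend)
}
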