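# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set, plus lipid-bound stratification with the
# 4 A N...O rule.

#' Deterministic golden-spiral points on the unit sphere
#'
#' @param n Number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley per-atom solvent-accessible surface area
#'
#' Each atom's sphere of radius `vdw + probe_radius` is sampled with a
#' deterministic golden-spiral point set; the accessible fraction (test
#' points outside every neighbour's expanded sphere) scales the full
#' sphere area `4 pi (r + rp)^2`.  Results are bit-reproducible: no
#' random numbers are involved.  Coincident duplicate atoms are computed
#' normally (they occlude each other).
#'
#' @param traj A `trajectory_set`.
#' @param frame Frame index.
#' @param atom_indices Atoms whose SASA is wanted (default: all
#'   occluders).
#' @param occluder_indices Atoms that block solvent (default: every atom
#'   except those on chains mapped to `ion` or `solvent`, i.e. protein,
#'   CaM and lipid heavy atoms jointly).
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom (>= 16).
#' @return Numeric vector of per-atom areas (Angstrom^2), named by atom
#'   index.
#' @export
shrake_rupley <- function(traj, frame = 1, atom_indices = NULL,
                          occluder_indices = NULL, probe_radius = 1.4,
                          n_points = 960) {
  if (n_points < 16) stopf("n_points must be >= 16")
  if (is.null(occluder_indices)) {
    lab <- unname(traj$subunit_map[traj$atoms$chain])
    occluder_indices <- which(!(lab %in% c("ion", "solvent")))
  }
  if (is.null(atom_indices)) atom_indices <- occluder_indices
  sph <- golden_spiral_points(n_points)
  occ_crd <- atom_coords(traj, frame, occluder_indices)
  occ_r <- traj$atoms$vdw[occluder_indices] + probe_radius
  out <- numeric(length(atom_indices))
  for (k in seq_along(atom_indices)) {
    i <- atom_indices[k]
    ci <- as.vector(atom_coords(traj, frame, i))
    ri <- traj$atoms$vdw[i] + probe_radius
    d2 <- rowSums(sweep(occ_crd, 2, ci)^2)
    nb <- which(d2 < (ri + occ_r)^2 & !(occluder_indices == i & d2 < 1e-12))
    pts <- sweep(sph * ri, 2, ci, "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dd <- sweep(pts, 2, occ_crd[j, ])
      acc <- acc & rowSums(dd * dd) >= occ_r[j]^2
      if (!any(acc)) break
    }
    out[k] <- 4 * pi * ri * ri * mean(acc)
  }
  names(out) <- atom_indices
  out
}

#' Per-residue SASA in one frame
#'
#' @inheritParams shrake_rupley
#' @param chain,resid Residue address.
#' @return Total residue SASA in Angstrom^2.
#' @export
residue_sasa <- function(traj, frame, chain, resid, occluder_indices = NULL,
                         probe_radius = 1.4, n_points = 960) {
  idx <- select_atoms(traj, chain = chain, resid = resid)
  if (!length(idx)) stopf("no atoms for residue %d in chain %s", resid, chain)
  sum(shrake_rupley(traj, frame, atom_indices = idx,
                    occluder_indices = occluder_indices,
                    probe_radius = probe_radius, n_points = n_points))
}

#' Lipid-bound flags for a basic residue
#'
#' A residue counts as bound in a frame when the minimum distance
#' between any phosphate-bonded charged O of any lipid headgroup and any
#' charged side-chain N of the residue is below `cutoff` (paper rule:
#' 4 A).
#'
#' @param traj A `trajectory_set`.
#' @param residue Basic `charge_group` (must contain side-chain N
#'   atoms).
#' @param lipids List of acidic lipid `charge_group`s (headgroup O
#'   atoms).
#' @param cutoff Bound/unbound threshold in Angstrom.
#' @return Per-frame logical vector.
#' @export
bound_flags <- function(traj, residue, lipids, cutoff = 4.0) {
  n_idx <- residue$atom_indices[traj$atoms$elem[residue$atom_indices] == "N"]
  if (!length(n_idx))
    stopf("residue group '%s' has no side-chain N atoms", residue$label)
  nf <- n_frames(traj)
  d <- rep(Inf, nf)
  for (lp in lipids) {
    o_idx <- lp$atom_indices[traj$atoms$elem[lp$atom_indices] == "O"]
    for (i in n_idx) {
      pi_ <- traj$xyz[, xyz_cols(i), drop = FALSE]
      for (j in o_idx) {
        pj <- traj$xyz[, xyz_cols(j), drop = FALSE]
        d <- pmin(d, min_image_distance(pi_, pj, traj$box))
      }
    }
  }
  d < cutoff
}

#' Per-frame SASA series for one residue with bound flags
#'
#' @param traj A `trajectory_set`.
#' @param residue Basic `charge_group` identifying the residue.
#' @param lipids List of lipid `charge_group`s (for the bound flags).
#' @param frames Frames to evaluate (default all).
#' @param bound_cutoff The 4 A N...O rule threshold.
#' @inheritParams shrake_rupley
#' @return A `sasa_series` data frame: `frame`, `sasa_A2`, `bound`.
#' @export
sasa_series <- function(traj, residue, lipids = list(), frames = NULL,
                        bound_cutoff = 4.0, occluder_indices = NULL,
                        probe_radius = 1.4, n_points = 960) {
  frames <- frames %||% seq_len(n_frames(traj))
  idx <- residue$atom_indices
  a <- traj$atoms[idx[1], ]
  res_idx <- select_atoms(traj, chain = a$chain, resid = a$resid)
  sasa <- vapply(frames, function(f)
    sum(shrake_rupley(traj, f, atom_indices = res_idx,
                      occluder_indices = occluder_indices,
                      probe_radius = probe_radius, n_points = n_points)), 0)
  bound <- if (length(lipids))
    bound_flags(traj, residue, lipids, bound_cutoff)[frames]
  else rep(FALSE, length(frames))
  out <- data.frame(frame = frames, sasa_A2 = sasa, bound = bound)
  attr(out, "residue") <- residue$label
  attr(out, "probe_radius") <- probe_radius
  attr(out, "n_points") <- n_points
  class(out) <- c("sasa_series", "data.frame")
  out
}

#' Bound/unbound SASA summary
#'
#' Means and SDs of the SASA in the lipid-bound and unbound strata, and
#' the variance ratio `sd_bound^2 / sd_unbound^2`; a reduction below 1
#' is the variance-reduction signature of a lipid-pinned side chain.  An
#' empty stratum is reported with its count and NA statistics.
#'
#' @param sasa A `sasa_series`, or a numeric vector plus `bound`.
#' @param bound Logical stratum flags (when `sasa` is a plain vector).
#' @return A `sasa_summary` list: `mean_bound`, `sd_bound`,
#'   `mean_unbound`, `sd_unbound`, `n_bound`, `n_unbound`,
#'   `variance_ratio`.
#' @export
stratify_sasa <- function(sasa, bound = NULL) {
  if (inherits(sasa, "sasa_series")) { bound <- sasa$bound; v <- sasa$sasa_A2 }
  else v <- as.numeric(sasa)
  if (length(v) != length(bound)) stopf("sasa and bound lengths differ")
  st <- function(x) if (length(x)) c(mean(x), stats::sd(x)) else c(NA_real_, NA_real_)
  b <- st(v[bound]); u <- st(v[!bound])
  structure(list(mean_bound = b[1], sd_bound = b[2],
                 mean_unbound = u[1], sd_unbound = u[2],
                 n_bound = sum(bound), n_unbound = sum(!bound),
                 variance_ratio = b[2]^2 / u[2]^2),
            class = "sasa_summary")
}

#' @export
print.sasa_summary <- function(x, ...) {
  cat(sprintf("SASA bound:   %7.2f +/- %.2f A^2 (n=%d)\n",
              x$mean_bound, x$sd_bound, x$n_bound))
  cat(sprintf("SASA unbound: %7.2f +/- %.2f A^2 (n=%d)\n",
              x$mean_unbound, x$sd_unbound, x$n_unbound))
  cat(sprintf("variance ratio (bound/unbound): %.3f\n", x$variance_ratio))
  invisible(x)
}
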