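# Bridge-conditioned pose clustering: frames split by a named salt
# bridge, then k-medoids (PAM) on a superposition-corrected RMSD matrix
# of a selection, yielding medoid frames as representative poses.

#' Partition frames by bridge state
#'
#' @param bridge A `contact_series` (or logical vector).
#' @return List with `formed_frames` and `absent_frames` (1-based frame
#'   indices; together they cover every frame exactly once).
#' @export
stratify_frames <- function(bridge) {
  states <- if (inherits(bridge, "contact_series")) bridge$states else bridge
  list(formed_frames = which(states), absent_frames = which(!states))
}

# Pairwise selection-RMSD matrix after fitting every frame onto the
# first requested frame on `fit_indices`.
pose_rmsd_matrix <- function(traj, frames, sel_idx, fit_idx) {
  ref_fit <- atom_coords(traj, frames[1], fit_idx)
  sel <- lapply(frames, function(f) {
    sp <- superpose_rmsd(atom_coords(traj, f, fit_idx), ref_fit, fit = TRUE)
    atom_coords(traj, f, sel_idx) %*% sp$rotation +
      matrix(sp$translation, length(sel_idx), 3, byrow = TRUE)
  })
  n <- length(frames)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sel[[i]] - sel[[j]]
    m[i, j] <- m[j, i] <- sqrt(mean(rowSums(d * d)))
  }
  m
}

#' Cluster poses within a frame stratum
#'
#' Frames are first superposed on `fit_indices` (default: the four
#' channel subunits), then a pairwise RMSD matrix of `selection` is
#' clustered with k-medoids (PAM).  With `k = NULL`, k is chosen by a
#' silhouette scan over 2..5 (falling back to 1 when every silhouette is
#' non-positive).  Medoid frames are the representative poses.  Cluster
#' ids are arbitrary labels; compare partitions, not ids.
#'
#' @param traj A `trajectory_set`.
#' @param frames Frame indices of one stratum (length >= k).
#' @param selection Atom indices whose pose is clustered.
#' @param k Number of clusters, or NULL for the silhouette scan.
#' @param seed Accepted for interface stability; PAM's BUILD/SWAP search
#'   is deterministic and draws no random numbers.
#' @param fit_indices Atoms used for the rigid-body fit.
#' @return A `pose_clustering`: `frames`, `assignments`,
#'   `medoid_frames`, `k`, `mean_within_rmsd`, `mean_between_rmsd`,
#'   `silhouette` (mean, NA for k = 1).
#' @export
cluster_poses <- function(traj, frames, selection, k = NULL, seed = NULL,
                          fit_indices = NULL) {
  if (!length(frames)) stopf("no frames to cluster")
  if (!is.null(k) && (k < 1 || k > length(frames)))
    stopf("k must be between 1 and the number of frames (%d)", length(frames))
  fit_indices <- fit_indices %||%
    select_atoms(traj, subunit = c("I", "II", "III", "IV"))
  m <- pose_rmsd_matrix(traj, frames, selection, fit_indices)
  dmat <- stats::as.dist(m)
  pick_k <- function() {
    ks <- 2:min(5, length(frames) - 1)
    if (!length(ks) || length(frames) < 3) return(1L)
    sil <- vapply(ks, function(kk) {
      fit <- cluster::pam(dmat, kk, diss = TRUE)
      mean(cluster::silhouette(fit$clustering, dmat)[, "sil_width"])
    }, 0)
    if (all(sil <= 0)) 1L else ks[which.max(sil)]
  }
  if (is.null(k)) k <- pick_k()
  if (k == 1) {
    assignments <- rep(1L, length(frames))
    med <- which.min(colSums(m))
    medoid_frames <- frames[med]
    silh <- NA_real_
  } else if (k == length(frames)) {
    assignments <- seq_along(frames)   # singleton clusters
    medoid_frames <- frames
    silh <- NA_real_
  } else {
    fit <- cluster::pam(dmat, k, diss = TRUE)
    assignments <- as.integer(fit$clustering)
    medoid_frames <- frames[fit$id.med]
    silh <- if (k > 1) mean(cluster::silhouette(assignments, dmat)[, "sil_width"])
            else NA_real_
  }
  same <- outer(assignments, assignments, "==")
  off <- upper.tri(m)
  within <- m[off & same]
  between <- m[off & !same]
  structure(list(frames = frames, assignments = assignments,
                 medoid_frames = medoid_frames, k = k,
                 mean_within_rmsd = if (length(within)) mean(within) else 0,
                 mean_between_rmsd = if (length(between)) mean(between) else NA_real_,
                 silhouette = silh,
                 objective = sum(vapply(seq_along(frames), function(i)
                   min(m[i, match(medoid_frames, frames)]), 0))),
            class = "pose_clustering")
}

#' @export
print.pose_clustering <- function(x, ...) {
  cat(sprintf("pose_clustering: %d frames in %d cluster(s); sizes %s\n",
              length(x$frames), x$k,
              paste(table(x$assignments), collapse = ", ")))
  cat(sprintf("  medoid frames: %s; within %.3f A, between %s A\n",
              paste(x$medoid_frames, collapse = ", "), x$mean_within_rmsd,
              format(x$mean_between_rmsd, digits = 4)))
  invisible(x)
}

#' Circular summary of a side-chain dihedral per cluster
#'
#' Torsion angles (degrees) of one atom quadruple across the clustered
#' frames, summarised per cluster by circular mean and circular SD, to
#' expose rotamer shifts between poses (e.g. the two arginine rotamer
#' clusters seen when the lipid bridge forms).
#'
#' @param traj A `trajectory_set`.
#' @param clustering A `pose_clustering`.
#' @param atom_quad Four atom indices defining the dihedral.
#' @return Data frame with `cluster`, `n`, `circ_mean_deg`,
#'   `circ_sd_deg`.
#' @export
dihedral_summary <- function(traj, clustering, atom_quad) {
  if (length(atom_quad) != 4) stopf("a dihedral needs exactly 4 atoms")
  ang <- vapply(clustering$frames, function(f) {
    crd <- atom_coords(traj, f, atom_quad)
    bio3d::torsion.xyz(as.vector(t(crd)), atm.inc = 4)
  }, 0)
  out <- data.frame(cluster = sort(unique(clustering$assignments)),
                    n = 0L, circ_mean_deg = NA_real_, circ_sd_deg = NA_real_)
  for (r in seq_len(nrow(out))) {
    a <- ang[clustering$assignments == out$cluster[r]] * pi / 180
    out$n[r] <- length(a)
    s <- mean(sin(a)); c <- mean(cos(a))
    out$circ_mean_deg[r] <- atan2(s, c) * 180 / pi
    rbar <- sqrt(s^2 + c^2)
    out$circ_sd_deg[r] <- sqrt(pmax(0, -2 * log(rbar))) * 180 / pi
  }
  out
}
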