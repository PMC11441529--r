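# The trajectory container: a labelled structure plus frames of
# coordinates with per-frame orthorhombic box and time stamps.

#' Construct a trajectory set
#'
#' The central container of the package: an atom table, an `n_frames x
#' 3*n_atoms` coordinate matrix (columns x1,y1,z1,x2,...; bio3d "xyz"
#' layout), per-frame orthorhombic box lengths, time stamps in ns, and a
#' chain-to-subunit map.
#'
#' @param atoms Data frame with columns `name`, `resname`, `resid`
#'   (author residue number), `chain`, `elem`, `vdw` (Angstrom).  Row
#'   order is atom order; atoms are addressed by 1-based row index.
#' @param xyz Numeric matrix, one row per frame, `3 * nrow(atoms)`
#'   columns, coordinates in Angstrom.
#' @param box Numeric matrix `n_frames x 3` of box lengths (Lx, Ly, Lz)
#'   in Angstrom, or a length-3 vector recycled to all frames.
#' @param times Numeric vector of frame times in ns, strictly
#'   increasing.  Defaults to `0:(n_frames-1)`.
#' @param subunit_map Named character vector mapping each chain id to a
#'   label such as `"I"`..`"IV"`, `"CaM-I"`..`"CaM-IV"`, `"lipid"`,
#'   `"ion"`, `"solvent"`.  Must cover every chain present.
#'
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(atoms, xyz, box, times = NULL, subunit_map = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "resname", "resid", "chain", "elem", "vdw")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0))
    stopf("all vdW radii must be positive")
  xyz <- rbind(xyz)  # tolerate a single frame given as a vector
  if (ncol(xyz) != 3L * nrow(atoms))
    stopf("coordinate matrix has %d columns; expected %d (3 per atom)",
          ncol(xyz), 3L * nrow(atoms))
  nf <- nrow(xyz)
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (nrow(box) != nf) stopf("box must have one row per frame")
  if (any(box <= 0)) stopf("box lengths must be positive")
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stopf("times must have one entry per frame")
  if (nf > 1 && any(diff(times) <= 0))
    stopf("frame times must be strictly increasing")
  chains <- unique(atoms$chain)
  if (is.null(subunit_map)) {
    subunit_map <- stats::setNames(chains, chains)
  } else {
    uncov <- setdiff(chains, names(subunit_map))
    if (length(uncov))
      stopf("subunit_map does not cover chain(s): %s", paste(uncov, collapse = ", "))
  }
  structure(list(atoms = atoms, xyz = xyz, box = box,
                 times = as.numeric(times), subunit_map = subunit_map),
            class = "trajectory_set")
}

#' Number of frames / atoms in a trajectory set
#' @param traj A `trajectory_set`.
#' @return Integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj A `trajectory_set`.
#' @param frame 1-based frame index.
#' @return Numeric matrix with columns x, y, z (Angstrom).
#' @export
get_frame <- function(traj, frame) {
  if (frame < 1 || frame > n_frames(traj))
    stopf("frame %d out of range 1..%d", frame, n_frames(traj))
  matrix(traj$xyz[frame, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atom indices by attribute
#'
#' All given filters are ANDed; `subunit` filters on the chain-to-subunit
#' map rather than the raw chain id.
#'
#' @param traj A `trajectory_set`.
#' @param chain,resid,resname,name,elem,subunit Optional vectors of
#'   admissible values.
#' @return Integer vector of 1-based atom indices, in structure order.
#' @export
select_atoms <- function(traj, chain = NULL, resid = NULL, resname = NULL,
                         name = NULL, elem = NULL, subunit = NULL) {
  a <- traj$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(elem)) keep <- keep & a$elem %in% elem
  if (!is.null(subunit))
    keep <- keep & unname(traj$subunit_map[a$chain]) %in% subunit
  which(keep)
}

# Chains carrying a given subunit label ("I".."IV", "lipid", ...).
chains_for_subunit <- function(traj, label) {
  names(traj$subunit_map)[traj$subunit_map == label]
}

# xyz column indices for a set of atom indices.
xyz_cols <- function(idx) as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))

# Coordinates of a set of atoms in one frame (k x 3).
atom_coords <- function(traj, frame, idx) {
  matrix(traj$xyz[frame, xyz_cols(idx)], ncol = 3, byrow = TRUE)
}

#' Append frames from one trajectory set to another
#'
#' @param traj A `trajectory_set`.
#' @param xyz Coordinate matrix to append (same column count).
#' @param box Box rows for the new frames.
#' @param times Times (ns) for the new frames.
#' @return The extended `trajectory_set`.
#' @export
append_frames <- function(traj, xyz, box, times) {
  trajectory_set(traj$atoms, rbind(traj$xyz, xyz), rbind(traj$box, box),
                 c(traj$times, times), traj$subunit_map)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d atoms, %d frame(s), box %s A\n",
              n_atoms(x), n_frames(x),
              paste(sprintf("%.1f", x$box[1, ]), collapse = " x ")))
  labs <- table(unname(x$subunit_map[x$atoms$chain]))
  cat("  atoms per subunit label: ",
      paste(sprintf("%s=%d", names(labs), labs), collapse = ", "), "\n", sep = "")
  invisible(x)
}
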