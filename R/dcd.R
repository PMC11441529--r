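# DCD trajectory I/O.  Reading goes through bio3d::read.dcd; writing is
# done here (CHARMM layout with per-frame orthorhombic unit cell), since
# no installed R package writes DCD.  XTC is not supported and raises an
# explicit unsupported-format error.

# 1 AKMA time unit in ps (CHARMM convention for the DCD delta field).
.AKMA_PS <- 0.04888821

# Minimal DCD header parse: atom count, frame count, timestep, cell flag.
# Used for validation and to recover frame times that bio3d discards.
read_dcd_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  len <- readBin(con, "integer", 1, endian = "little")
  end <- "little"
  if (len != 84) {
    end <- "big"
    seek(con, 0)
    len <- readBin(con, "integer", 1, endian = end)
    if (len != 84) stopf("%s does not look like a DCD file", path)
  }
  tag <- readChar(con, 4)
  if (tag != "CORD") stopf("%s: unexpected DCD block tag '%s'", path, tag)
  icntrl_raw <- readBin(con, "raw", 80)
  ints <- readBin(icntrl_raw, "integer", 20, size = 4, endian = end)
  delta <- readBin(icntrl_raw[37:40], "numeric", 1, size = 4, endian = end)
  list(nframes = ints[1], istart = ints[2], nsavc = ints[3],
       delta_akma = delta, has_cell = ints[11] == 1L, version = ints[20],
       endian = end)
}

#' Write a trajectory set as a DCD file
#'
#' CHARMM-style DCD: single-precision coordinates plus a per-frame
#' orthorhombic unit-cell record.  The frame interval is stored in the
#' header (AKMA units), so [read_trajectory()] can recover time stamps;
#' unequal frame spacing is flattened to the mean interval with a
#' warning.
#'
#' @param traj A `trajectory_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj)
  na <- n_atoms(traj)
  dt_ns <- if (nf > 1) diff(traj$times) else 1
  if (nf > 2 && diff(range(dt_ns)) > 1e-9 * max(dt_ns))
    warning("unequal frame spacing; DCD header stores the mean interval")
  delta_akma <- mean(dt_ns) * 1000 / .AKMA_PS
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: length marker, payload, length marker.
    raw_payload <- writer
    writeBin(length(raw_payload), con, size = 4, endian = "little")
    writeBin(raw_payload, con)
    writeBin(length(raw_payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 0L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- 1L; icntrl[20] <- 24L
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl[1:9], raw(), size = 4, endian = "little"),
           writeBin(as.numeric(delta_akma), raw(), size = 4, endian = "little"),
           writeBin(icntrl[11:20], raw(), size = 4, endian = "little"))
  rec(hdr)
  title <- sprintf("%-80s", "written by sktraj")
  rec(c(writeBin(1L, raw(), size = 4, endian = "little"),
        charToRaw(title)))
  rec(writeBin(as.integer(na), raw(), size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    b <- traj$box[f, ]
    # XTLABC order: (a, cos(gamma), b, cos(beta), cos(alpha), c).
    rec(writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), raw(),
                 size = 8, endian = "little"))
    fr <- get_frame(traj, f)
    for (dim in 1:3)
      rec(writeBin(as.numeric(fr[, dim]), raw(), size = 4, endian = "little"))
  }
  invisible(path)
}

#' Read a coordinate trajectory onto a structure
#'
#' Replaces the placeholder frame of a freshly read structure with the
#' trajectory's frames, in file order, with per-frame box lengths.  Only
#' DCD input is supported; XTC raises an unsupported-format error.
#'
#' @param traj A `trajectory_set` carrying the structure (atom count must
#'   match the trajectory).
#' @param path DCD file.
#' @param dt Frame interval in ns.  Defaults to the interval recorded in
#'   the DCD header.
#' @return A `trajectory_set` whose frames are the trajectory frames.
#' @export
read_trajectory <- function(traj, path, dt = NULL) {
  if (grepl("\\.xtc$", path, ignore.case = TRUE))
    stopf("XTC trajectories are not supported; convert to DCD")
  hdr <- read_dcd_header(path)
  if (hdr$nframes < 1) stopf("%s contains no frames", path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (ncol(xyz) != 3L * n_atoms(traj))
    stopf("atom-count mismatch: trajectory has %d atoms, structure has %d",
          ncol(xyz) / 3, n_atoms(traj))
  if (hdr$has_cell) {
    cell <- bio3d::read.dcd(path, verbose = FALSE, cell = TRUE)
    if (any(abs(cell[, 4:6] - 90) > 1e-3))
      stopf("triclinic cells are not supported; only orthorhombic boxes")
    box <- cell[, 1:3, drop = FALSE]
  } else {
    box <- traj$box[rep(1, nrow(xyz)), , drop = FALSE]
  }
  if (is.null(dt)) dt <- hdr$delta_akma * hdr$nsavc * .AKMA_PS / 1000
  if (!is.finite(dt) || dt <= 0) dt <- 1
  times <- (seq_len(nrow(xyz)) - 1L) * dt
  trajectory_set(traj$atoms, unclass(xyz), box, times, traj$subunit_map)
}
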