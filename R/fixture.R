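# Writing and re-reading generated fixtures: PDB + DCD + a JSON
# ground-truth sidecar, so the full file round trip (including periodic
# wrapping) is exercised.

#' Write a generated trajectory and its ground truth to disk
#'
#' Produces `structure.pdb` (frame 1), `traj.dcd` (all frames) and
#' `ground_truth.json` in `dir`.  Coordinates are wrapped into the
#' periodic box on writing (the in-memory generator output is unwrapped),
#' so downstream unwrapping code is exercised on re-read.
#'
#' @param traj A `trajectory_set` from [synth_generate()].
#' @param truth The matching ground-truth list.
#' @param dir Output directory (created if needed).
#' @param wrap Wrap coordinates into the box on writing?
#' @return Character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(traj, truth, dir, wrap = TRUE) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopf("cannot create directory %s", dir)
  out <- traj
  if (wrap) {
    for (f in seq_len(n_frames(traj))) {
      crd <- wrap_coords(get_frame(traj, f), matrix(traj$box[f, ], n_atoms(traj),
                                                    3, byrow = TRUE))
      out$xyz[f, ] <- as.vector(t(crd))
    }
  }
  pdb <- file.path(dir, "structure.pdb")
  dcd <- file.path(dir, "traj.dcd")
  gt <- file.path(dir, "ground_truth.json")
  write_structure(out, pdb, frame = 1)
  write_dcd(out, dcd)
  side <- truth
  side$subunit_map <- as.list(out$subunit_map)
  side$lipid_paths <- lapply(truth$lipid_paths, function(m)
    list(x = m[, 1], y = m[, 2]))
  jsonlite::write_json(side, gt, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pdb = pdb, dcd = dcd, truth = gt))
}

#' Read a fixture directory back
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `traj` (structure + trajectory frames) and `truth`.
#' @export
read_fixture <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  sm <- unlist(gt$subunit_map)
  structure_only <- read_structure(file.path(dir, "structure.pdb"),
                                   subunit_map = sm)
  traj <- read_trajectory(structure_only, file.path(dir, "traj.dcd"))
  truth <- gt
  truth$subunit_map <- NULL
  if (!is.null(truth$lipid_paths))
    truth$lipid_paths <- lapply(truth$lipid_paths, function(p)
      cbind(x = p$x, y = p$y))
  if (is.data.frame(truth$itineraries)) truth$itineraries <- list(truth$itineraries)
  list(traj = traj, truth = truth)
}
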