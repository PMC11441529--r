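# PDB structure I/O (via bio3d) with vdW radius assignment and
# orthorhombic-box handling.

# Parse the CRYST1 record of a PDB file; NULL when absent.
# Errors on triclinic cells: only orthorhombic boxes are supported.
parse_cryst1 <- function(path) {
  lines <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  ln <- lines[[1]]
  abc <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24), substr(ln, 25, 33)))
  ang <- as.numeric(c(substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54)))
  if (any(is.na(abc))) stopf("malformed CRYST1 record: %s", ln)
  if (any(abs(ang - 90) > 1e-3))
    stopf("triclinic cells are not supported (CRYST1 angles %s); only orthorhombic boxes",
          paste(ang, collapse = "/"))
  abc
}

# Derive an element symbol from a PDB atom name when the element column
# is blank: strip digits, take the leading alphabetic part, prefer
# two-letter matches from the radius table (CL, NA, ...), else first letter.
guess_element <- function(name, table_names) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% table_names & nchar(nm) >= 2 &
           !(substr(nm, 1, 1) %in% c("C", "N", "O", "H", "P", "S") &
               nchar(name) <= 4 & !(two %in% c("CL", "NA", "MG", "ZN", "FE", "BR"))),
         two, substr(nm, 1, 1))
}

#' Read a PDB structure as a single-frame trajectory set
#'
#' Atoms are kept in file order.  Van der Waals radii are assigned per
#' element from [bondi_radii()] (overridable); an atom whose element is
#' not in the table is an error, never a silent default.  The box comes
#' from the CRYST1 record unless overridden by `box`; triclinic cells are
#' rejected.
#'
#' @param path PDB file.
#' @param subunit_map Named character vector chain -> subunit label (see
#'   [trajectory_set()]).  Defaults to identity labels.
#' @param box Optional length-3 box override (Angstrom), used when the
#'   file has no CRYST1 record.
#' @param vdw_table Named radius table, element -> Angstrom.
#' @param time Time stamp (ns) of the single frame.
#' @return A `trajectory_set` with one frame.
#' @export
read_structure <- function(path, subunit_map = NULL, box = NULL,
                           vdw_table = bondi_radii(), time = 0) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stopf("PDB parse error in %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  elem[blank] <- guess_element(at$elety[blank], names(vdw_table))
  unknown <- !(elem %in% names(vdw_table))
  if (any(unknown)) {
    i <- which(unknown)[1]
    stopf("unknown element '%s' for atom %d (%s %s%s); extend vdw_table",
          elem[i], i, at$elety[i], at$resid[i], at$resno[i])
  }
  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(name = trimws(at$elety), resname = trimws(at$resid),
                      resid = at$resno, chain = chain, elem = elem,
                      vdw = unname(vdw_table[elem]),
                      stringsAsFactors = FALSE)
  file_box <- parse_cryst1(path)
  box <- box %||% file_box
  if (is.null(box))
    stopf("%s has no CRYST1 record; supply box = c(Lx, Ly, Lz)", path)
  xyz <- matrix(as.numeric(pdb$xyz), nrow = 1)
  trajectory_set(atoms, xyz, box, times = time, subunit_map = subunit_map)
}

#' Write one frame of a trajectory set as a PDB file
#'
#' Emits a CRYST1 record for the frame's orthorhombic box, then the atom
#' records in structure order (coordinates at PDB precision, 1e-3 A).
#'
#' @param traj A `trajectory_set`.
#' @param path Output file.
#' @param frame 1-based frame to write.
#' @return `path`, invisibly.
#' @export
write_structure <- function(traj, path, frame = 1) {
  a <- traj$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz[frame, ],
                   resno = a$resid, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = ifelse(a$chain == " ", "", a$chain),
                   elesy = a$elem)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   traj$box[frame, 1], traj$box[frame, 2], traj$box[frame, 3],
                   90, 90, 90)
  writeLines(c(cryst, readLines(path, warn = FALSE)), path)
  invisible(path)
}
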