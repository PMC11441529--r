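# Lateral lipid tracking, itineraries, transfers, occupancy.

# Minimal lipid-bearing trajectory: one PIP headgroup (P + 4 O) whose
# centroid follows `path` (n x 2), at fixed z.
lipid_path_traj <- function(path, box = c(100, 100, 100), z = 30) {
  off <- rbind(c(0, 0, 0), c(0.6, 0, 0), c(-0.6, 0, 0), c(0, 0.6, 0),
               c(0, -0.6, 0))
  frames <- lapply(seq_len(nrow(path)), function(f)
    sweep(off, 2, c(path[f, 1], path[f, 2], z), "+"))
  vdw <- bondi_radii()
  atoms <- data.frame(name = c("P1", "O1", "O2", "O3", "O4"),
                      resname = "PIP", resid = 1, chain = "L",
                      elem = c("P", "O", "O", "O", "O"),
                      vdw = unname(vdw[c("P", "O", "O", "O", "O")]))
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  trajectory_set(atoms, xyz, box, subunit_map = c(L = "lipid"))
}

test_that("unwrap_xy removes periodic jumps and assigns the leaflet", {
  # stationary lipid
  tr0 <- lipid_path_traj(cbind(rep(50, 5), rep(40, 5)))
  trk0 <- unwrap_xy(tr0, 1)
  expect_equal(max(abs(diff(trk0$xy))), 0)
  expect_equal(trk0$leaflet, "lower")
  # boundary crossing: raw x 99 -> 1 unwraps to 99 -> 101
  tr <- lipid_path_traj(cbind(c(99, 1), c(50, 50)))
  trk <- unwrap_xy(tr, 1)
  expect_equal(unname(trk$xy[, "x"]), c(99, 101))
  # upper-leaflet assignment
  trU <- lipid_path_traj(cbind(rep(50, 3), rep(50, 3)), z = 80)
  expect_equal(unwrap_xy(trU, 1)$leaflet, "upper")
})

test_that("unwrapped generator paths match the programmed truth through the file round trip", {
  g <- fix_canonical()
  d <- withr::local_tempdir()
  write_fixture(g$traj, g$truth, d)     # wraps coordinates on write
  rt <- read_fixture(d)
  trk <- unwrap_xy(rt$traj, 1)
  want <- g$truth$lipid_paths[[1]]
  # increments match the programmed walk (coordinates only to DCD precision)
  expect_equal(diff(trk$xy[, 1]), diff(want[, 1]), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(diff(trk$xy[, 2]), diff(want[, 2]), tolerance = 1e-4,
               ignore_attr = TRUE)
  # re-wrapping the unwrapped path reproduces the raw stored coordinates
  lip <- lipid_charge_group(rt$traj, 1)
  raw <- charge_centers_all <- vapply(seq_len(n_frames(rt$traj)), function(f)
    charge_center(rt$traj, lip, f)[1:2], numeric(2))
  box_xy <- rt$traj$box[1, 1:2]
  rewrapped <- trk$xy - rep(box_xy, each = nrow(trk$xy)) *
    floor(trk$xy / rep(box_xy, each = nrow(trk$xy)))
  expect_equal(rewrapped[, 1], raw[1, ], tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(rewrapped[, 2], raw[2, ], tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("itineraries recover the programmed residue order exactly", {
  g <- fix_canonical()
  lip <- lipid_charge_group(g$traj, 1)
  residues <- list()
  for (base in c("R271", "K278", "R286", "R418", "R299")) {
    resid <- c(R271 = 271, K278 = 278, R286 = 286, R418 = 418, R299 = 299)[[base]]
    for (su in c("I", "II", "III", "IV"))
      residues[[paste0(base, ".", su)]] <-
        residue_charge_group(g$traj, resid, subunit = su)
  }
  it <- build_itinerary(g$traj, lip, residues, cutoff = 5.5)
  expect_equal(it$visits$residue, g$truth$itineraries[[1]]$residue)
  expect_equal(it$visits$first_frame, g$truth$itineraries[[1]]$first_frame)
  expect_equal(it$visits$last_frame, g$truth$itineraries[[1]]$last_frame)
})

test_that("empty itineraries and simultaneous-contact tie-breaks", {
  g <- fix_disruption()
  lip <- lipid_charge_group(g$traj, 1)
  never <- list(`R271.II` = residue_charge_group(g$traj, 271, subunit = "II"))
  it <- build_itinerary(g$traj, lip, never)
  expect_equal(nrow(it$visits), 0)
  # two residues contacted from frame 1: ties broken by label
  crd <- rbind(c(50, 50, 30), c(52, 50, 30))   # both within 5.5 of the lipid
  prot <- make_traj(list(crd, crd, crd), names = c("NZ", "NZ"),
                    elem = "N", resids = c(1, 2), resname = "LYS",
                    chain = "A", subunit_map = c(A = "I"))
  # graft a lipid onto the same trajectory
  liptr <- lipid_path_traj(cbind(rep(51, 3), rep(50, 3)))
  atoms <- rbind(prot$atoms, liptr$atoms)
  xyz <- cbind(prot$xyz, liptr$xyz)
  tr <- trajectory_set(atoms, xyz, c(100, 100, 100),
                       subunit_map = c(A = "I", L = "lipid"))
  lip2 <- lipid_charge_group(tr, 1)
  res <- list(B2 = charge_group(tr, "B2", 2, "basic"),
              A1 = charge_group(tr, "A1", 1, "basic"))
  it2 <- build_itinerary(tr, lip2, res)
  expect_equal(it2$visits$first_frame, c(1, 1))
  expect_equal(it2$visits$residue, c("A1", "B2"))  # label order on ties
})

test_that("transfers are classified with and without the relay residue", {
  sites <- default_site_definitions()
  mk <- function(residues) {
    n <- length(residues)
    list(visits = data.frame(residue = residues,
                             first_frame = seq(1, by = 10, length.out = n),
                             last_frame = seq(5, by = 10, length.out = n)))
  }
  expect_equal(nrow(classify_transfers(mk(c("R271.I", "K278.I", "R286.I")),
                                       sites)), 0)
  tr1 <- classify_transfers(mk(c("R286.I", "R418.I", "R299.I")), sites)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$from_site, "transient")
  expect_equal(tr1$to_site, "activation")
  expect_equal(tr1$via_residue, "R418.I")
  tr2 <- classify_transfers(mk(c("R286.I", "R299.I")), sites)
  expect_equal(tr2$via_residue, NA_character_)
  # unknown residues are reported, not fatal
  tr3 <- classify_transfers(mk(c("R286.I", "K116.I", "R299.I")), sites)
  expect_equal(attr(tr3, "unassigned"), "K116.I")
  expect_equal(nrow(tr3), 1)
})

test_that("the canonical fixture yields exactly one transient->activation transfer via R418", {
  g <- fix_canonical()
  lip <- lipid_charge_group(g$traj, 1)
  residues <- list()
  for (base in c("R271", "K278", "R286", "R418", "R299")) {
    resid <- c(R271 = 271, K278 = 278, R286 = 286, R418 = 418, R299 = 299)[[base]]
    residues[[paste0(base, ".I")]] <-
      residue_charge_group(g$traj, resid, subunit = "I")
  }
  it <- build_itinerary(g$traj, lip, residues)
  tr <- classify_transfers(it)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$from_site, "transient")
  expect_equal(tr$to_site, "activation")
  expect_equal(tr$via_residue, "R418.I")
})

test_that("occupancy fractions and dwell bookkeeping are conserved", {
  g <- fix_disruption()
  lip <- lipid_charge_group(g$traj, 1)
  res <- list(`R395.III` = residue_charge_group(g$traj, 395, subunit = "III"),
              `R271.II` = residue_charge_group(g$traj, 271, subunit = "II"))
  occ <- occupancy_map(g$traj, list(lip), res)
  expect_equal(occ$fraction[occ$residue == "R271.II"], 0)
  truth_frames <- sum(!is.na(g$truth$bound_residue[[1]]) &
                        g$truth$bound_residue[[1]] == "R395.III")
  expect_equal(occ$contact_frames[occ$residue == "R395.III"], truth_frames)
  expect_equal(occ$fraction[occ$residue == "R395.III"],
               truth_frames / n_frames(g$traj))
  # two lipids covering disjoint halves union to full occupancy
  nf <- 20
  mkpath <- function(on) cbind(ifelse(on, 50, 10), rep(50, nf))
  l1 <- lipid_path_traj(mkpath(seq_len(nf) <= 10))
  l2 <- lipid_path_traj(mkpath(seq_len(nf) > 10))
  l2$atoms$resid <- 2
  res_atom <- make_traj(lapply(seq_len(nf), function(f) rbind(c(50, 50, 30))),
                        names = "NZ", elem = "N", resids = 9, resname = "LYS",
                        chain = "A", subunit_map = c(A = "I"))
  atoms <- rbind(res_atom$atoms, l1$atoms, l2$atoms)
  xyz <- cbind(res_atom$xyz, l1$xyz, l2$xyz)
  tr <- trajectory_set(atoms, xyz, c(100, 100, 100),
                       subunit_map = c(A = "I", L = "lipid"))
  lips <- list(lipid_charge_group(tr, 1), lipid_charge_group(tr, 2))
  occ2 <- occupancy_map(tr, lips,
                        list(K9 = charge_group(tr, "K9", 1, "basic")))
  expect_equal(occ2$fraction, 1.0)
})
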