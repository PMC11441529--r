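# SF site model, site labelling, permeation counting, conductance.

# Minimal SF: 6 residues x 4 subunits of backbone O at given plane
# heights, plus ions whose z follows given per-frame values.
sf_ion_traj <- function(planes, ion_z, ring_radius = 1.4) {
  nf <- if (is.matrix(ion_z)) nrow(ion_z) else length(ion_z)
  ion_z <- rbind(ion_z)
  if (nrow(ion_z) == 1) ion_z <- t(ion_z)   # single ion given as vector
  n_ions <- ncol(ion_z)
  vdw <- bondi_radii()
  rows <- list(); base <- list()
  for (k in 1:4) {
    th <- (k - 1) * pi / 2
    for (j in seq_along(planes)) {
      rows[[length(rows) + 1]] <- data.frame(
        name = "O", resname = "GLY", resid = 357 + j,
        chain = c("A", "B", "C", "D")[k], elem = "O", vdw = vdw[["O"]])
      base[[length(base) + 1]] <- c(50 + ring_radius * cos(th),
                                    50 + ring_radius * sin(th), planes[j])
    }
  }
  for (i in seq_len(n_ions)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = "K", resname = "K", resid = i, chain = "N", elem = "K",
      vdw = vdw[["K"]])
    base[[length(base) + 1]] <- c(50, 50, 0)
  }
  atoms <- do.call(rbind, rows)
  tmpl <- do.call(rbind, base)
  xyz <- matrix(NA_real_, nf, 3 * nrow(atoms))
  for (f in seq_len(nf)) {
    crd <- tmpl
    for (i in seq_len(n_ions))
      crd[24 + i, 3] <- ion_z[f, i]
    xyz[f, ] <- as.vector(t(crd))
  }
  trajectory_set(atoms, xyz, c(100, 100, 120),
                 subunit_map = c(A = "I", B = "II", C = "III", D = "IV",
                                 N = "ion"))
}

test_that("build_sf_model derives ordered planes and five sites", {
  tr <- sf_ion_traj(planes = c(0, 3, 6, 9, 12, 15) + 40, ion_z = 50)
  sf <- build_sf_model(tr)
  expect_equal(sf$planes, c(0, 3, 6, 9, 12, 15) + 40)
  expect_equal(sf$sites, c("S4", "S3", "S2", "S1", "S0"))
  expect_equal(diff(sf$planes), rep(3, 5))
  # a swapped pair of planes is not SF-like
  tr_bad <- sf_ion_traj(planes = c(0, 6, 3, 9, 12, 15) + 40, ion_z = 50)
  expect_error(build_sf_model(tr_bad), "monotone")
  # generator planes match the programmed stack
  g <- fix_canonical()
  sfg <- build_sf_model(g$traj)
  expect_equal(sfg$planes, g$truth$sf_planes, tolerance = 1e-6)
})

test_that("site labels follow z with hysteresis at the outer boundaries", {
  planes <- c(40, 43, 46, 49, 52, 55)
  # fixed mid-S2 ion
  tr <- sf_ion_traj(planes, ion_z = rep(47.5, 8))
  sf <- build_sf_model(tr)
  ion <- select_atoms(tr, subunit = "ion")
  expect_true(all(site_timeseries(tr, sf, ion)[[1]] == "S2"))
  # linear ramp traverses all labels in order
  trr <- sf_ion_traj(planes, ion_z = seq(30, 65, length.out = 71))
  labs <- site_timeseries(trr, build_sf_model(trr),
                          select_atoms(trr, subunit = "ion"))[[1]]
  expect_equal(rle(labs)$values,
               c("below", "S4", "S3", "S2", "S1", "S0", "above"))
  # flicker around the lower plane does not toggle below/inside
  z <- c(35, 41, 39.5, 41, 39.5, 41, 35)   # margin 2: 39.5 > 40 - 2
  trf <- sf_ion_traj(planes, ion_z = z)
  labf <- site_timeseries(trf, build_sf_model(trf),
                          select_atoms(trf, subunit = "ion"))[[1]]
  expect_equal(labf, c("below", "S4", "S4", "S4", "S4", "S4", "below"))
})

test_that("permeation counting: retreats, cancellation, generator truth", {
  planes <- c(40, 43, 46, 49, 52, 55)
  # partial entry that retreats is not an event
  tr1 <- sf_ion_traj(planes, ion_z = c(30, 42, 47, 42, 30))
  rec1 <- count_permeations(site_timeseries(tr1, build_sf_model(tr1),
                                            select_atoms(tr1, subunit = "ion")))
  expect_equal(rec1$total_events, 0)
  # one up and one down by different ions: net zero
  up <- seq(30, 65, length.out = 12); down <- rev(up)
  tr2 <- sf_ion_traj(planes, ion_z = cbind(up, down))
  rec2 <- count_permeations(site_timeseries(tr2, build_sf_model(tr2),
                                            select_atoms(tr2, subunit = "ion")))
  expect_equal(rec2$total_events, 2)
  expect_equal(rec2$net_flux, 0)
  expect_equal(rec2$n_up, 1)
  # generator crossings recovered exactly
  g <- fix_crossings(n_cross = 12)
  sf <- build_sf_model(g$traj)
  ions <- select_atoms(g$traj, subunit = "ion")
  rec <- count_permeations(site_timeseries(g$traj, sf, ions),
                           times = g$traj$times, voltage_mv = 750)
  expect_equal(rec$n_up, 12)
  expect_equal(rec$n_down, 0)
  expect_equal(rec$net_flux, 12)
})

test_that("event counts equal the pattern-matching oracle on random site walks", {
  set.seed(77)
  sites <- c("below", "S4", "S3", "S2", "S1", "S0", "above")
  for (rep in 1:300) {
    # random walk over the ordered site ladder
    pos <- cumsum(c(sample(1:7, 1), sample(c(-1, 1), 60, replace = TRUE)))
    pos <- pmin(pmax(pos, 1), 7)
    lab <- sites[pos]
    rec <- count_permeations(lab)
    want <- oracle_permeation_counts(lab)
    expect_equal(rec$n_up, unname(want["up"]))
    expect_equal(rec$n_down, unname(want["down"]))
  }
})

test_that("event counting is invariant to mild subsampling", {
  g <- fix_crossings(n_cross = 6, n_frames = 240)
  sf <- build_sf_model(g$traj)
  ions <- select_atoms(g$traj, subunit = "ion")
  full <- count_permeations(site_timeseries(g$traj, sf, ions))$n_up
  sub <- g$traj
  keep <- seq(1, n_frames(g$traj), by = 2)
  sub$xyz <- sub$xyz[keep, , drop = FALSE]
  sub$box <- sub$box[keep, , drop = FALSE]
  sub$times <- sub$times[keep]
  subbed <- count_permeations(site_timeseries(sub, build_sf_model(sub), ions))$n_up
  expect_equal(subbed, full)
})

test_that("conductance follows g = N e / (T V) with linear scalings", {
  expect_equal(conductance(net_flux = 0, duration_ns = 1000, voltage_mv = 750), 0)
  g58 <- conductance(net_flux = 58, duration_ns = 5000, voltage_mv = 750)
  expect_equal(g58, 58 * 1.602176634e-19 / (5e-6 * 0.75) * 1e12)
  expect_equal(g58, 2.478, tolerance = 1e-3)
  expect_equal(conductance(net_flux = 58, duration_ns = 10000, voltage_mv = 750),
               g58 / 2)
  expect_equal(conductance(net_flux = 116, duration_ns = 5000, voltage_mv = 750),
               g58 * 2)
  expect_error(conductance(net_flux = 5, duration_ns = 0, voltage_mv = 750),
               "duration")
  expect_error(conductance(net_flux = 5, duration_ns = 10, voltage_mv = 0),
               "voltage")
})
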