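# Pore profiling, gate distances, SF carbonyl distances,
# bridge-versus-gate binning.

ring_coords <- function(n, ring_radius, z, center = c(50, 50)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + ring_radius * cos(th), center[2] + ring_radius * sin(th), z)
}

test_that("pore radius matches closed forms on atom rings", {
  tr <- make_traj(ring_coords(8, 6, 50), subunit_map = c(A = "I"))
  pp <- pore_profile(tr, 1, z_range = c(50, 50), dz = 1, seed = 2)
  expect_equal(pp$radius, 6 - 1.7, tolerance = 1e-3)
  # stacked rings: the 3 A ring is the constriction; a tight search
  # radius threads the sparse 8-atom cage without slipping between rings
  crd <- rbind(ring_coords(8, 6, 46), ring_coords(8, 3, 54))
  tr2 <- make_traj(crd, subunit_map = c(A = "I"))
  pp2 <- pore_profile(tr2, 1, z_range = c(46, 54), dz = 2, seed = 2,
                      search_radius = 2)
  expect_equal(min(pp2$radius), 3 - 1.7, tolerance = 1e-3)
  expect_equal(pp2$z[which.min(pp2$radius)], 54)
})

test_that("pore radii agree with the 0.1 A grid-search oracle on a random pore", {
  tr <- fix_random_pore(200)
  crd <- get_frame(tr, 1)
  vdw <- tr$atoms$vdw
  zs <- seq(44, 56, by = 2)
  pp <- pore_profile(tr, 1, z_range = range(zs), dz = 2, seed = 9)
  expect_equal(pp$z, zs)
  for (i in seq_along(zs)) {
    want <- oracle_grid_pore_radius(zs[i], crd, vdw, c(50, 50))
    expect_lt(abs(pp$radius[i] - want), 0.05)
    # the profiler's radius is a maximum: no tested centre beats it by
    # more than the polish tolerance
    expect_gte(pp$radius[i], want - 0.05)
  }
  # deterministic for a fixed seed
  pp2 <- pore_profile(tr, 1, z_range = range(zs), dz = 2, seed = 9)
  expect_identical(pp$radius, pp2$radius)
})

# Four gate atoms at given positions, replicated over frames.
gate_traj <- function(pts_by_frame, name = "CG") {
  if (!is.list(pts_by_frame)) pts_by_frame <- list(pts_by_frame)
  vdw <- bondi_radii()
  atoms <- data.frame(name = name, resname = "VAL", resid = 390,
                      chain = c("A", "B", "C", "D"), elem = "C",
                      vdw = vdw[["C"]])
  xyz <- do.call(rbind, lapply(pts_by_frame, function(f) as.vector(t(f))))
  trajectory_set(atoms, xyz, c(100, 100, 100),
                 subunit_map = c(A = "I", B = "II", C = "III", D = "IV"))
}

test_that("gate distances follow the square and rectangle closed forms", {
  s <- 9.9
  sq <- rbind(c(0, 0, 0), c(s, 0, 0), c(s, s, 0), c(0, s, 0))
  gs <- gate_distances(gate_traj(sq), 390, "CG")
  expect_equal(gs$d_I_III, s * sqrt(2))
  expect_equal(gs$d_II_IV, s * sqrt(2))
  expect_equal(gs$geometric_mean, s * sqrt(2))
  expect_equal(gs$geometric_mean, 14.0, tolerance = 1e-3)
  # rectangle with diagonals 12 and 16
  rect <- rbind(c(-6, 0, 0), c(0, 8, 0), c(6, 0, 0), c(0, -8, 0))
  gr <- gate_distances(gate_traj(rect), 390, "CG")
  expect_equal(gr$d_I_III, 12)
  expect_equal(gr$d_II_IV, 16)
  expect_equal(gr$geometric_mean, sqrt(192))
  # AM-GM: geometric mean never exceeds the arithmetic mean
  expect_lte(gr$geometric_mean, (gr$d_I_III + gr$d_II_IV) / 2)
  # missing CG atoms are reported with the subunit
  expect_error(gate_distances(gate_traj(sq, name = "CA"), 390, "CG"),
               "subunit I")
})

test_that("gate series recovers the programmed schedule and satisfies AM-GM", {
  g <- fix_canonical()
  gs <- gate_distances(g$traj, 390, "CG")
  expect_true(all(abs(gs$geometric_mean - g$truth$gate_series) <= 0.01))
  expect_true(all(gs$geometric_mean <= (gs$d_I_III + gs$d_II_IV) / 2 + 1e-12))
  # CA rule reads the backbone ring (offset ring in the generator)
  gsa <- gate_distances(g$traj, 390, "CA")
  expect_true(all(gsa$geometric_mean > gs$geometric_mean))
})

test_that("SF carbonyl distances: square closed form, rotation invariance, degeneracy", {
  mk_sf <- function(rot = diag(3), side = 3.0) {
    pts <- rbind(c(side / 2, side / 2, 0), c(-side / 2, side / 2, 0),
                 c(-side / 2, -side / 2, 0), c(side / 2, -side / 2, 0))
    pts <- pts[c(1, 2, 3, 4), ] %*% t(rot)
    pts <- sweep(pts, 2, c(50, 50, 50), "+")
    vdw <- bondi_radii()
    atoms <- data.frame(name = "O", resname = "SER", resid = 358,
                        chain = c("A", "B", "C", "D"), elem = "O",
                        vdw = vdw[["O"]])
    trajectory_set(atoms, matrix(as.vector(t(pts)), 1), c(100, 100, 100),
                   subunit_map = c(A = "I", B = "II", C = "III", D = "IV"))
  }
  d <- sf_carbonyl_distances(mk_sf(), frame = 1, sf_resids = 358)
  expect_equal(d$d_I_III, 3 * sqrt(2), tolerance = 1e-12)
  expect_equal(d$mean, 3 * sqrt(2), tolerance = 1e-12)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  d2 <- sf_carbonyl_distances(mk_sf(rot), frame = 1, sf_resids = 358)
  expect_equal(d2$d_I_III, d$d_I_III, tolerance = 1e-9)
  d0 <- sf_carbonyl_distances(mk_sf(side = 0), frame = 1, sf_resids = 358)
  expect_equal(d0$d_I_III, 0)
  # generator SF rings match the programmed opposite-pair distance
  g <- fix_canonical()
  dg <- sf_carbonyl_distances(g$traj, frame = 1)
  expect_equal(dg$d_I_III, g$truth$sf_oo_distance, tolerance = 1e-9)
})

test_that("bridge_vs_gate bins and trend statistics", {
  g <- fix_canonical()
  gate <- gate_distances(g$traj, 390, "CG")
  # always-formed bridge: flat profile, trend defined as 0
  always <- rep(TRUE, n_frames(g$traj))
  bg <- bridge_vs_gate(gate, always, n_bins = 5)
  expect_true(all(bg$bins$fraction == 1))
  expect_equal(bg$trend, 0)
  # programmed anti-correlation (bridge true iff gate < 10): step profile
  bridge <- g$truth$bridge_states[[1]]
  bg2 <- bridge_vs_gate(gate, bridge, n_bins = 2)
  expect_equal(bg2$bins$fraction, c(1, 0))
  expect_equal(bg2$trend, -1)
  # constant gate: single occupied bin, trend undefined
  cfgc <- synth_config(n_frames = 12, gate_distance_schedule = 14, seed = 2)
  gc_ <- synth_generate(cfgc)
  gatec <- gate_distances(gc_$traj, 390, "CG")
  bgc <- bridge_vs_gate(gatec, rep(TRUE, 12), n_bins = 4)
  expect_true(is.na(bgc$trend))
  expect_error(bridge_vs_gate(gate, always, n_bins = 1), "n_bins")
})
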