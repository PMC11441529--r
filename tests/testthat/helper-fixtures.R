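# Fixture builders shared across test files.  Generated fixtures are
# memoised so each is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Minimal hand-built trajectory: one chain of carbon atoms with given
# per-frame coordinates.
make_traj <- function(frames, box = c(100, 100, 100), elem = "C",
                      chain = "A", names = NULL, resids = NULL,
                      resname = "UNK", subunit_map = NULL, times = NULL) {
  if (!is.list(frames)) frames <- list(frames)
  n <- nrow(frames[[1]])
  vdw <- bondi_radii()
  atoms <- data.frame(name = names %||% rep("C", n),
                      resname = resname,
                      resid = resids %||% seq_len(n),
                      chain = chain, elem = elem,
                      vdw = unname(vdw[elem]), stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f))))
  trajectory_set(atoms, xyz, box, times = times, subunit_map = subunit_map)
}

# Canonical lipid-itinerary fixture: one lipid walking the full
# transient -> transfer -> activation route while the gate opens and
# the bridge anti-correlates with the gate.
fix_canonical <- function() cached("canonical", function() {
  cfg <- synth_config(
    n_frames = 160, lipid_count = 1,
    lipid_waypoints = list(data.frame(
      residue = c("R271", "K278", "R286", "R418", "R299"), dwell = 25)),
    crossing_schedule = data.frame(ion = c(1, 2), start = c(10, 60),
                                   end = c(40, 100), direction = c(1, 1)),
    gate_distance_schedule = seq(6, 14, length.out = 160),
    bridge_gate_threshold = 10, seed = 11)
  c(list(cfg = cfg), synth_generate(cfg))
})

# Bridge-disruption fixture: the lipid parks at R395 of subunit III,
# breaking that inter-subunit bridge while bound.
fix_disruption <- function() cached("disruption", function() {
  cfg <- synth_config(
    n_frames = 120, lipid_count = 1,
    lipid_waypoints = list(data.frame(residue = c("K396", "R395.III", "K471"),
                                      dwell = c(20, 50, 20))),
    gate_distance_schedule = 14, bridge_gate_threshold = Inf, seed = 23)
  c(list(cfg = cfg), synth_generate(cfg))
})

# Many-crossing permeation fixture (no lipids, no jitter).
fix_crossings <- function(n_cross = 12, n_frames = 200) {
  starts <- round(seq(5, n_frames - 25, length.out = n_cross))
  cfg <- synth_config(
    n_frames = n_frames, lipid_count = 0, residue_jitter = 0,
    crossing_schedule = data.frame(ion = seq_len(n_cross), start = starts,
                                   end = starts + 20, direction = 1),
    seed = 5)
  c(list(cfg = cfg), synth_generate(cfg))
}

# Random artificial pore: atoms scattered on a noisy cylinder.
fix_random_pore <- function(n_atoms = 200, seed = 42) {
  set.seed(seed)
  th <- stats::runif(n_atoms, 0, 2 * pi)
  r <- 7 + stats::rnorm(n_atoms, 0, 0.8)
  z <- stats::runif(n_atoms, 40, 60)
  crd <- cbind(50 + r * cos(th), 50 + r * sin(th), z)
  make_traj(crd, box = c(100, 100, 100), subunit_map = c(A = "I"))
}
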