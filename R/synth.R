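# Synthetic trajectory generator: an idealised four-fold pseudo-symmetric
# channel in a membrane with programmable ground truth for lipid
# itineraries, salt-bridge events, gate distances and ion crossings.
#
# Geometry (all Angstrom, membrane normal along z, box centre cz):
#   * intracellular gate: V390 CA/CG atoms on four-fold rings at
#     z = mz - 15, CG ring diameter driven per frame by the schedule;
#   * selectivity filter: one backbone O per subunit for each of the six
#     SF residues (S358..D363), on small rings stacked 3 A apart above
#     the membrane midplane;
#   * basic anchors: R271, K278, R286, R418, R299, R395, K396, K471 (and
#     CaM K116) at distinct angles on a wide ring in the lower leaflet,
#     spaced so neighbouring charge centres are ~14 A apart;
#   * bridge partner E398 (of the preceding subunit) sits 2.8 A from the
#     R395 centre when the inter-subunit salt bridge is formed and 7 A
#     when broken;
#   * PIP2-like lipids: a phosphate P plus four charged O atoms, moving
#     laterally in the lower leaflet either along programmed waypoint
#     itineraries or as reflected random walks with sticky capture;
#   * K+ ions: scheduled linear transits through the SF stack, the rest
#     diffusing in bulk far from the pore.

.ROMAN <- c("I", "II", "III", "IV")
.SUBUNIT_CHAINS <- c("A", "B", "C", "D")
.CAM_CHAINS <- c("E", "F", "G", "H")

# Basic-residue anchors: angular offsets (degrees) within each subunit
# sector.  11.25 deg spacing on a 70 A ring keeps centres ~13.7 A apart.
.ANCHOR_OFFSET <- c(R271 = -40, K278 = -28.75, R286 = -17.5, R418 = -6.25,
                    R299 = 5, R395 = 16.25, K396 = 27.5, K471 = 38.75)
.ANCHOR_RESID <- c(R271 = 271, K278 = 278, R286 = 286, R418 = 418,
                   R299 = 299, R395 = 395, K396 = 396, K471 = 471)
.ARG_ANCHORS <- c("R271", "R286", "R418", "R299", "R395")
.SF_RESNAMES <- c("SER", "ILE", "GLY", "TYR", "GLY", "ASP")

#' Configuration for the synthetic trajectory generator
#'
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame interval in ns.
#' @param box Orthorhombic box lengths (Angstrom).
#' @param gate_distance_schedule Per-frame target CG-ring diameter of the
#'   V390 gate (Angstrom); a scalar is recycled.  Default 14.
#' @param lipid_count Number of PIP2-like lipids.
#' @param lipid_diffusion Lateral diffusion coefficient (Angstrom^2/ns)
#'   for free lipids.
#' @param sticky_residues Data frame with columns `residue` (label such
#'   as `"R271"` or `"R271.II"`), `capture_radius` (Angstrom) and
#'   `mean_dwell` (frames): free lipids entering the capture radius park
#'   at the residue with a geometric (memoryless) dwell.
#' @param lipid_waypoints List (one element per lipid) of data frames
#'   with columns `residue` and `dwell` (frames): deterministic
#'   itineraries visited in order, one or more travel frames between
#'   visits.  Lipids without an entry follow the random walk.
#' @param crossing_schedule Data frame with columns `ion` (1-based id),
#'   `start`, `end` (frames) and `direction` (+1 up / -1 down): complete
#'   selectivity-filter transits realised as linear z ramps.
#' @param ion_count Total K+ ions; defaults to scheduled ions plus four
#'   bulk ions.
#' @param bridge_gate_threshold Gate diameter (Angstrom) below which the
#'   four R395:E398 inter-subunit bridges are formed (default `Inf`:
#'   always formed).  A lipid parked at an R395 breaks that subunit's
#'   bridge regardless.
#' @param bridge_schedule Optional explicit per-frame logical overriding
#'   the gate rule (before the lipid override).
#' @param residue_jitter Thermal jitter (sd, Angstrom) on basic-residue
#'   side-chain N atoms while lipid-unbound.
#' @param bound_jitter_factor Multiplier on the jitter while a lipid is
#'   parked at the residue (models the reduced rotamer variability of a
#'   lipid-pinned side chain).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_frames = 500, dt = 1, box = c(170, 170, 120),
                         gate_distance_schedule = 14,
                         lipid_count = 0, lipid_diffusion = 1,
                         sticky_residues = NULL, lipid_waypoints = NULL,
                         crossing_schedule = NULL, ion_count = NULL,
                         bridge_gate_threshold = Inf, bridge_schedule = NULL,
                         residue_jitter = 0.35, bound_jitter_factor = 0.2,
                         seed = 1) {
  if (n_frames < 1) stopf("n_frames must be >= 1")
  if (dt <= 0) stopf("dt must be positive")
  if (length(box) != 3 || any(box <= 0)) stopf("box must be 3 positive lengths")
  sched <- rep_len(as.numeric(gate_distance_schedule), n_frames)
  if (any(sched <= 0)) stopf("gate distances must be positive")
  if (!is.null(bridge_schedule)) {
    bridge_schedule <- rep_len(as.logical(bridge_schedule), n_frames)
  }
  if (!is.null(crossing_schedule)) {
    cs <- as.data.frame(crossing_schedule)
    req <- c("ion", "start", "end", "direction")
    if (!all(req %in% names(cs))) stopf("crossing_schedule needs columns %s",
                                        paste(req, collapse = ", "))
    if (any(cs$start >= cs$end)) stopf("crossing start must precede end")
    if (any(cs$start < 1 | cs$end > n_frames))
      stopf("crossing intervals must lie within 1..n_frames")
    if (!all(cs$direction %in% c(-1, 1))) stopf("direction must be +1 or -1")
    for (id in unique(cs$ion)) {
      iv <- cs[cs$ion == id, ]
      iv <- iv[order(iv$start), ]
      if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
        stopf("overlapping crossings scheduled for ion %d", id)
    }
    crossing_schedule <- cs
  }
  if (!is.null(sticky_residues)) {
    sr <- as.data.frame(sticky_residues)
    if (!"capture_radius" %in% names(sr)) sr$capture_radius <- 5.5
    if (!"mean_dwell" %in% names(sr)) sr$mean_dwell <- 30
    if (any(sr$mean_dwell < 1)) stopf("mean_dwell must be >= 1 frame")
    sticky_residues <- sr
  }
  if (is.null(ion_count))
    ion_count <- (if (is.null(crossing_schedule)) 0 else max(crossing_schedule$ion)) + 4
  structure(list(
    n_frames = as.integer(n_frames), dt = dt, box = as.numeric(box),
    gate_distance_schedule = sched, lipid_count = as.integer(lipid_count),
    lipid_diffusion = lipid_diffusion, sticky_residues = sticky_residues,
    lipid_waypoints = lipid_waypoints, crossing_schedule = crossing_schedule,
    ion_count = as.integer(ion_count),
    bridge_gate_threshold = bridge_gate_threshold,
    bridge_schedule = bridge_schedule,
    residue_jitter = residue_jitter,
    bound_jitter_factor = bound_jitter_factor,
    seed = as.integer(seed),
    # internal geometry (documented above)
    anchor_radius = 70, travel_radius = 90, dwell_offset = 2,
    sf_ring_radius = 1.4, cam_radius = 82),
    class = "synth_config")
}

# Parse "R271" / "R271.III" -> list(base, subunit index).
parse_residue_label <- function(label) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  base <- parts[1]
  su <- if (length(parts) > 1) match(parts[2], .ROMAN) else 1L
  if (!(base %in% c(names(.ANCHOR_OFFSET), "K116")) || is.na(su))
    stopf("unknown residue label '%s'", label)
  list(base = base, subunit = su)
}

full_label <- function(base, subunit) paste0(base, ".", .ROMAN[subunit])

# Charge-centre anchor (x, y) of a basic residue instance.
anchor_xy <- function(cfg, base, subunit) {
  ctr <- cfg$box[1:2] / 2
  if (base == "K116") {
    th <- ((subunit - 1) * 90 + 45) * pi / 180
    return(ctr + cfg$cam_radius * c(cos(th), sin(th)))
  }
  th <- ((subunit - 1) * 90 + .ANCHOR_OFFSET[[base]]) * pi / 180
  ctr + cfg$anchor_radius * c(cos(th), sin(th))
}

# Lipid parking spot: 2 A radially outward of the charge centre.
dwell_xy <- function(cfg, base, subunit) {
  a <- anchor_xy(cfg, base, subunit)
  ctr <- cfg$box[1:2] / 2
  u <- (a - ctr) / sqrt(sum((a - ctr)^2))
  a + cfg$dwell_offset * u
}

# Membrane/pore reference levels.
synth_levels <- function(cfg) {
  mz <- cfg$box[3] / 2
  list(mz = mz, gate_z = mz - 15, leaflet_z = mz - 17,
       sf_z = mz + 6 + 3 * (0:5))
}

#' Generate a synthetic trajectory with ground truth
#'
#' Deterministic for a fixed seed: identical configs give bitwise
#' identical coordinates.
#'
#' @param config A [synth_config()].
#' @return List with `traj` (a `trajectory_set`) and `truth`, the
#'   realised ground truth: `itineraries` (per-lipid data frames of
#'   residue / first_frame / last_frame), `lipid_paths` (per-lipid
#'   unwrapped XY), `bound_residue` (per-lipid per-frame label or NA),
#'   `crossings`, `gate_series`, `bridge_states` and `bridge_events`
#'   (per R395:E398 pair), `sf_planes` and `sf_oo_distance`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, synth_generate_impl(config))
}

synth_generate_impl <- function(cfg) {
  nf <- cfg$n_frames
  lv <- synth_levels(cfg)
  ctr <- cfg$box[1:2] / 2

  ## ---- atom table and static template ----
  rows <- list(); pos <- list()
  add_atom <- function(name, resname, resid, chain, elem, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = chain,
      elem = elem, stringsAsFactors = FALSE)
    pos[[length(pos) + 1]] <<- xyz
  }
  tri <- function(center, r = 0.8) {
    # three points with centroid exactly at `center`
    th <- c(90, 210, 330) * pi / 180
    lapply(th, function(t) center + c(r * cos(t), r * sin(t), 0))
  }
  for (k in 1:4) {
    ch <- .SUBUNIT_CHAINS[k]
    thk <- (k - 1) * pi / 2
    u <- c(cos(thk), sin(thk))
    # V390 gate atoms (ring radii set per frame; template uses frame 1)
    r_cg <- cfg$gate_distance_schedule[1] / 2
    add_atom("CA", "VAL", 390, ch, "C", c(ctr + (r_cg + 1.5) * u, lv$gate_z))
    add_atom("CG", "VAL", 390, ch, "C", c(ctr + r_cg * u, lv$gate_z))
    # SF backbone O stack
    for (j in 1:6)
      add_atom("O", .SF_RESNAMES[j], 357 + j, ch, "O",
               c(ctr + cfg$sf_ring_radius * u, lv$sf_z[j]))
    # basic anchors
    for (base in names(.ANCHOR_OFFSET)) {
      a <- c(anchor_xy(cfg, base, k), lv$leaflet_z)
      resid <- .ANCHOR_RESID[[base]]
      if (base %in% .ARG_ANCHORS) {
        nm <- c("NE", "NH1", "NH2")
        p <- tri(a)
        for (i in 1:3) add_atom(nm[i], "ARG", resid, ch, "N", p[[i]])
      } else {
        add_atom("NZ", "LYS", resid, ch, "N", a)
      }
    }
    # E398 of this subunit sits near R395 of the *next* subunit
    nxt <- k %% 4 + 1
    e_ctr <- e398_center(cfg, nxt, formed = TRUE)
    add_atom("OE1", "GLU", 398, ch, "O", e_ctr + c(0, 0, 0.6))
    add_atom("OE2", "GLU", 398, ch, "O", e_ctr - c(0, 0, 0.6))
  }
  for (k in 1:4)
    add_atom("NZ", "LYS", 116, .CAM_CHAINS[k], "N",
             c(anchor_xy(cfg, "K116", k), lv$leaflet_z))
  lipid_atom_start <- length(rows) + 1L
  if (cfg$lipid_count > 0) {
    off <- rbind(c(0, 0, 0.8), c(0.75, 0, -0.4), c(-0.37, 0.65, -0.4),
                 c(-0.37, -0.65, -0.4))
    for (l in seq_len(cfg$lipid_count)) {
      add_atom("P1", "PIP", l, "L", "P", c(0, 0, lv$leaflet_z))
      for (i in 1:4)
        add_atom(paste0("O", i), "PIP", l, "L", "O",
                 c(off[i, 1:2], lv$leaflet_z + off[i, 3]))
    }
  }
  ion_atom_start <- length(rows) + 1L
  for (i in seq_len(cfg$ion_count))
    add_atom("K", "K", i, "N", "K", c(0, 0, 0))
  atoms <- do.call(rbind, rows)
  template <- do.call(rbind, pos)
  subunit_map <- c(stats::setNames(.ROMAN, .SUBUNIT_CHAINS),
                   stats::setNames(paste0("CaM-", .ROMAN), .CAM_CHAINS),
                   L = "lipid", N = "ion")

  ## ---- lipid motion + bound bookkeeping ----
  lip <- synth_lipids(cfg, nf)

  ## ---- bridge states ----
  geo <- sqrt(cfg$gate_distance_schedule *
                cfg$gate_distance_schedule)  # CG diagonals are equal by symmetry
  base_state <- if (!is.null(cfg$bridge_schedule)) cfg$bridge_schedule
                else geo < cfg$bridge_gate_threshold
  bridge_states <- list()
  for (k in 1:4) {
    bound_here <- rep(FALSE, nf)
    for (l in seq_len(cfg$lipid_count))
      bound_here <- bound_here | (!is.na(lip$bound[[l]]) &
                                    lip$bound[[l]] == full_label("R395", k))
    prv <- (k + 2) %% 4 + 1
    bridge_states[[sprintf("R395.%s:E398.%s", .ROMAN[k], .ROMAN[prv])]] <-
      base_state & !bound_here
  }

  ## ---- ion z paths ----
  ion <- synth_ions(cfg, nf, lv)

  ## ---- jitter bookkeeping ----
  # indices of jittered side-chain N atoms per residue instance
  jitter_idx <- list()
  key <- paste(atoms$chain, atoms$resid, sep = ":")
  for (k in 1:4) for (base in names(.ANCHOR_OFFSET)) {
    lab <- full_label(base, k)
    jitter_idx[[lab]] <- which(atoms$chain == .SUBUNIT_CHAINS[k] &
                                 atoms$resid == .ANCHOR_RESID[[base]] &
                                 atoms$elem == "N")
  }
  for (k in 1:4)
    jitter_idx[[paste0("K116.", .ROMAN[k])]] <-
      which(atoms$chain == .CAM_CHAINS[k] & atoms$resid == 116)
  bound_at <- function(lab, f) {
    for (l in seq_len(cfg$lipid_count))
      if (!is.na(lip$bound[[l]][f]) && lip$bound[[l]][f] == lab) return(TRUE)
    FALSE
  }

  ## ---- per-frame assembly ----
  cg_idx <- which(atoms$resid == 390 & atoms$name == "CG")
  ca_idx <- which(atoms$resid == 390 & atoms$name == "CA")
  e398_idx <- lapply(1:4, function(k) {   # E398 near R395 of subunit k
    prv <- (k + 2) %% 4 + 1
    which(atoms$chain == .SUBUNIT_CHAINS[prv] & atoms$resid == 398)
  })
  xyz <- matrix(0, nf, 3L * nrow(atoms))
  for (f in seq_len(nf)) {
    crd <- template
    r_cg <- cfg$gate_distance_schedule[f] / 2
    for (k in 1:4) {
      u <- c(cos((k - 1) * pi / 2), sin((k - 1) * pi / 2))
      crd[cg_idx[k], 1:2] <- ctr + r_cg * u
      crd[ca_idx[k], 1:2] <- ctr + (r_cg + 1.5) * u
      st <- bridge_states[[k]][f]
      ec <- e398_center(cfg, k, formed = st)
      crd[e398_idx[[k]], ] <- rbind(ec + c(0, 0, 0.6), ec - c(0, 0, 0.6))
    }
    # thermal jitter on basic side chains, damped while lipid-bound
    if (cfg$residue_jitter > 0) {
      for (lab in names(jitter_idx)) {
        idx <- jitter_idx[[lab]]
        sdv <- cfg$residue_jitter *
          (if (bound_at(lab, f)) cfg$bound_jitter_factor else 1)
        crd[idx, ] <- crd[idx, ] + matrix(stats::rnorm(3 * length(idx), 0, sdv),
                                          ncol = 3)
      }
    }
    # lipids
    for (l in seq_len(cfg$lipid_count)) {
      i0 <- lipid_atom_start + 5L * (l - 1L)
      shift <- c(lip$path[[l]][f, ], 0)
      crd[i0:(i0 + 4L), ] <- sweep(template[i0:(i0 + 4L), , drop = FALSE] ,
                                   2, shift, "+")
    }
    # ions
    for (i in seq_len(cfg$ion_count)) {
      crd[ion_atom_start + i - 1L, ] <- ion$pos[[i]][f, ]
    }
    xyz[f, ] <- as.vector(t(crd))
  }

  vdw <- bondi_radii()
  atoms$vdw <- unname(vdw[atoms$elem])
  traj <- trajectory_set(atoms, xyz, cfg$box, times = (seq_len(nf) - 1) * cfg$dt,
                         subunit_map = subunit_map)
  truth <- list(
    itineraries = lip$itineraries,
    lipid_paths = lip$path,
    bound_residue = lip$bound,
    crossings = ion$crossings,
    gate_series = cfg$gate_distance_schedule,
    bridge_states = bridge_states,
    bridge_events = lapply(bridge_states, runs_to_events),
    sf_planes = lv$sf_z,
    sf_oo_distance = rep(2 * cfg$sf_ring_radius, 6))
  list(traj = traj, truth = truth)
}

# E398 charge-group centre near R395 of subunit k.
e398_center <- function(cfg, k, formed) {
  a <- anchor_xy(cfg, "R395", k)
  ctr <- cfg$box[1:2] / 2
  u <- (a - ctr) / sqrt(sum((a - ctr)^2))
  tang <- c(-u[2], u[1])
  d <- if (formed) 2.8 else 7.0
  lvz <- synth_levels(cfg)$leaflet_z
  c(a + d * tang, lvz)
}

# Maximal TRUE runs of a logical vector as (formed_frame, broken_frame),
# 1-based inclusive.
runs_to_events <- function(states) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(formed_frame = starts[keep], broken_frame = ends[keep])
}

# Lipid paths, bound labels and itineraries.
synth_lipids <- function(cfg, nf) {
  path <- list(); bound <- list(); itins <- list()
  all_anchor_labels <- c(
    as.vector(outer(names(.ANCHOR_OFFSET), .ROMAN, full_label)),
    as.vector(outer("K116", .ROMAN, full_label)))
  for (l in seq_len(cfg$lipid_count)) {
    wp <- if (!is.null(cfg$lipid_waypoints) && l <= length(cfg$lipid_waypoints))
      cfg$lipid_waypoints[[l]] else NULL
    if (!is.null(wp)) {
      res <- synth_lipid_waypoints(cfg, nf, as.data.frame(wp), l)
    } else {
      res <- synth_lipid_walk(cfg, nf, l)
    }
    path[[l]] <- res$path; bound[[l]] <- res$bound
    itins[[l]] <- bound_to_itinerary(res$bound)
  }
  list(path = path, bound = bound, itineraries = itins)
}

# Visits = maximal runs of a non-NA bound label.
bound_to_itinerary <- function(bound) {
  r <- rle(ifelse(is.na(bound), "", bound))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  data.frame(residue = r$values[keep], first_frame = starts[keep],
             last_frame = ends[keep], stringsAsFactors = FALSE)
}

# Deterministic waypoint itinerary: start on the travel ring at the first
# waypoint's bearing, then for each waypoint one or more travel frames
# along the travel ring (<= 40 degrees per frame, keeping steps well
# under half the box) followed by `dwell` frames parked at the residue.
synth_lipid_waypoints <- function(cfg, nf, wp, l) {
  ctr <- cfg$box[1:2] / 2
  labs <- character(nrow(wp))
  angs <- numeric(nrow(wp)); dw <- matrix(0, nrow(wp), 2)
  for (i in seq_len(nrow(wp))) {
    pl <- parse_residue_label(wp$residue[i])
    labs[i] <- full_label(pl$base, pl$subunit)
    dw[i, ] <- dwell_xy_any(cfg, pl$base, pl$subunit)
    a <- anchor_xy(cfg, pl$base, pl$subunit) - ctr
    angs[i] <- atan2(a[2], a[1])
  }
  path <- matrix(NA_real_, nf, 2)
  bound <- rep(NA_character_, nf)
  travel_pt <- function(ang) ctr + cfg$travel_radius * c(cos(ang), sin(ang))
  path[1, ] <- travel_pt(angs[1])
  f <- 2L
  prev_ang <- angs[1]
  for (i in seq_len(nrow(wp))) {
    dint <- (angs[i] - prev_ang + pi) %% (2 * pi) - pi  # shortest arc
    nseg <- max(1L, ceiling(abs(dint) / (40 * pi / 180)))
    for (s in seq_len(nseg)) {
      if (f > nf) break
      path[f, ] <- travel_pt(prev_ang + dint * s / nseg)
      f <- f + 1L
    }
    dwell <- as.integer(wp$dwell[i])
    for (s in seq_len(dwell)) {
      if (f > nf) break
      path[f, ] <- dw[i, ]
      bound[f] <- labs[i]
      f <- f + 1L
    }
    prev_ang <- angs[i]
    if (f > nf) break
  }
  if (f <= nf) {            # park at the last waypoint for the remainder
    for (s in f:nf) { path[s, ] <- dw[nrow(wp), ]; bound[s] <- labs[nrow(wp)] }
  }
  list(path = path, bound = bound)
}

dwell_xy_any <- function(cfg, base, subunit) dwell_xy(cfg, base, subunit)

# Reflected 2D random walk with sticky capture.
synth_lipid_walk <- function(cfg, nf, l) {
  ctr <- cfg$box[1:2] / 2
  margin <- 5
  path <- matrix(NA_real_, nf, 2)
  bound <- rep(NA_character_, nf)
  sticky <- cfg$sticky_residues
  stick_pts <- NULL
  if (!is.null(sticky)) {
    pts <- list()
    for (i in seq_len(nrow(sticky))) {
      pl <- parse_residue_label(sticky$residue[i])
      expand <- if (grepl(".", sticky$residue[i], fixed = TRUE)) pl$subunit else 1:4
      for (k in expand)
        pts[[length(pts) + 1]] <- list(
          label = full_label(pl$base, k),
          anchor = anchor_xy(cfg, pl$base, k),
          dwell_pos = dwell_xy(cfg, pl$base, k),
          radius = sticky$capture_radius[i],
          mean_dwell = sticky$mean_dwell[i])
    }
    stick_pts <- pts
  }
  sdstep <- sqrt(2 * cfg$lipid_diffusion * cfg$dt)
  # start on the travel ring at a lipid-specific bearing
  th0 <- 2 * pi * (l - 0.5) / max(1, cfg$lipid_count)
  cur <- ctr + cfg$travel_radius * c(cos(th0), sin(th0))
  cur <- pmin(pmax(cur, margin), cfg$box[1:2] - margin)
  dwell_left <- 0L; cur_label <- NA_character_; cur_stick <- NULL
  for (f in seq_len(nf)) {
    if (dwell_left > 0L) {
      path[f, ] <- cur; bound[f] <- cur_label
      dwell_left <- dwell_left - 1L
      if (dwell_left == 0L) {
        # escape just outside the capture radius, radially outward
        u <- (cur_stick$dwell_pos - ctr) /
          sqrt(sum((cur_stick$dwell_pos - ctr)^2))
        cur <- cur_stick$anchor + (cur_stick$radius + 2) * u
        cur_label <- NA_character_
      }
      next
    }
    if (f > 1) {
      cur <- cur + stats::rnorm(2, 0, sdstep)
      cur <- pmin(pmax(cur, margin), cfg$box[1:2] - margin)  # reflect walls
    }
    captured <- FALSE
    if (!is.null(stick_pts)) {
      for (sp in stick_pts) {
        if (sqrt(sum((cur - sp$anchor)^2)) <= sp$radius) {
          dwell <- 1L + stats::rgeom(1, 1 / sp$mean_dwell)
          cur <- sp$dwell_pos; cur_label <- sp$label; cur_stick <- sp
          path[f, ] <- cur; bound[f] <- cur_label
          dwell_left <- dwell - 1L
          if (dwell_left == 0L) {
            u <- (sp$dwell_pos - ctr) / sqrt(sum((sp$dwell_pos - ctr)^2))
            cur <- sp$anchor + (sp$radius + 2) * u
            cur_label <- NA_character_
          }
          captured <- TRUE
          break
        }
      }
    }
    if (!captured) { path[f, ] <- cur; bound[f] <- NA_character_ }
  }
  list(path = path, bound = bound)
}

# Ion z paths and realised crossings.
synth_ions <- function(cfg, nf, lv) {
  ctr <- cfg$box[1:2] / 2
  z_below <- lv$sf_z[1] - 10; z_above <- lv$sf_z[6] + 10
  pos <- list()
  cs <- cfg$crossing_schedule
  scheduled <- if (is.null(cs)) integer(0) else unique(cs$ion)
  for (i in seq_len(cfg$ion_count)) {
    p <- matrix(NA_real_, nf, 3)
    if (i %in% scheduled) {
      iv <- cs[cs$ion == i, ]; iv <- iv[order(iv$start), ]
      z <- rep(NA_real_, nf)
      first_dir <- iv$direction[1]
      z[] <- if (first_dir > 0) z_below else z_above
      for (r in seq_len(nrow(iv))) {
        s <- iv$start[r]; e <- iv$end[r]; d <- iv$direction[r]
        z0 <- if (d > 0) z_below else z_above
        z1 <- if (d > 0) z_above else z_below
        z[s:e] <- z0 + (seq(s, e) - s) / (e - s) * (z1 - z0)
        if (e < nf) z[(e + 1):nf] <- z1
      }
      # a lateral offset of 0 keeps scheduled ions on the pore axis
      p[, 1] <- ctr[1]; p[, 2] <- ctr[2]; p[, 3] <- z
    } else {
      # bulk ion: clamped 3D walk kept below the filter (intracellular
      # bulk never threads the SF)
      th <- 2 * pi * i / max(1, cfg$ion_count)
      cur <- c(ctr + 55 * c(cos(th), sin(th)), lv$mz - 35)
      zmax <- lv$sf_z[1] - 12
      for (f in seq_len(nf)) {
        if (f > 1) {
          cur <- cur + stats::rnorm(3, 0, 1)
          cur <- pmin(pmax(cur, 5), c(cfg$box[1:2] - 5, zmax))
        }
        p[f, ] <- cur
      }
    }
    pos[[i]] <- p
  }
  crossings <- if (is.null(cs)) {
    data.frame(ion = integer(0), entry_frame = integer(0),
               exit_frame = integer(0), direction = integer(0))
  } else {
    data.frame(ion = cs$ion, entry_frame = cs$start, exit_frame = cs$end,
               direction = cs$direction)[order(cs$ion, cs$start), ]
  }
  list(pos = pos, crossings = crossings)
}
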