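# Pipeline orchestration: a validated plain-text (YAML) configuration
# holding the named analysis constants, staged execution with isolated
# failures, a machine-readable manifest, and a text report that copies
# stage outputs without recomputing them.

#' Analysis configuration
#'
#' Collects every named constant of the analysis battery: the 5.5 A
#' centre-of-charge tracking cutoff, the 3.6 A salt-bridge cutoff, the
#' 4 A SASA bound/unbound rule, the 750 mV permeation voltage, the gate
#' residue (V390), the primary inter-subunit bridge (R395:E398), the SF
#' residues (358-363) and the binding-site taxonomy.  All fields are
#' plain values so the config round-trips through YAML unchanged.
#'
#' @param structure,trajectory,out_dir Paths (structure PDB, DCD
#'   trajectory, output directory).
#' @param subunit_map Named chain -> label map.
#' @param tracking_cutoff,bridge_cutoff,sasa_bound_cutoff Cutoffs (A).
#' @param voltage_mv Applied voltage for the conductance estimate.
#' @param gate_resid,gate_rule Gate residue and atom rule.
#' @param sf_resids Selectivity-filter residue numbers.
#' @param bridge Primary bridge: list with `basic_resid`,
#'   `basic_subunit`, `acidic_resid`, `acidic_subunit`.
#' @param sites Site taxonomy (see [default_site_definitions()]).
#' @param site_resids Named label -> residue-number map for the site
#'   residues.
#' @param lipid_resname Lipid residue name.
#' @param sasa_residues Residue labels (e.g. `"R395.III"`) for the SASA
#'   stage.
#' @param sasa_n_points Test points per atom in the SASA stage.
#' @param pore_dz,pore_restarts Pore-profile parameters.
#' @param cluster_k Cluster count (NULL = silhouette scan).
#' @param cluster_max_frames Frame cap per stratum (even subsampling).
#' @param seed Seed for the seeded stages (pore restarts).
#' @return A validated `analysis_config` list.
#' @export
analysis_config <- function(structure, trajectory, out_dir,
                            subunit_map = NULL,
                            tracking_cutoff = 5.5, bridge_cutoff = 3.6,
                            sasa_bound_cutoff = 4.0, voltage_mv = 750,
                            gate_resid = 390, gate_rule = "CG",
                            sf_resids = 358:363,
                            bridge = list(basic_resid = 395, basic_subunit = "III",
                                          acidic_resid = 398, acidic_subunit = "II"),
                            sites = NULL, site_resids = NULL,
                            lipid_resname = "PIP",
                            sasa_residues = c("R395.III"),
                            sasa_n_points = 240,
                            pore_dz = 1.0, pore_restarts = 16,
                            cluster_k = NULL, cluster_max_frames = 40,
                            seed = 1) {
  sites <- sites %||% unclass(default_site_definitions())
  site_resids <- site_resids %||%
    list(R271 = 271, K278 = 278, R286 = 286, R299 = 299, R395 = 395,
         K396 = 396, R418 = 418, K471 = 471)
  cfg <- list(paths = list(structure = structure, trajectory = trajectory,
                           out_dir = out_dir),
              subunit_map = as.list(subunit_map),
              cutoffs = list(tracking = tracking_cutoff, bridge = bridge_cutoff,
                             sasa_bound = sasa_bound_cutoff),
              voltage_mv = voltage_mv,
              gate = list(resid = gate_resid, rule = gate_rule),
              sf_resids = as.integer(sf_resids),
              bridge = bridge, sites = sites, site_resids = site_resids,
              lipid_resname = lipid_resname,
              sasa = list(residues = as.list(sasa_residues),
                          n_points = sasa_n_points),
              pore = list(dz = pore_dz, n_restarts = pore_restarts),
              cluster = list(k = cluster_k, max_frames = cluster_max_frames),
              seed = seed)
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

validate_config <- function(cfg) {
  cuts <- unlist(cfg$cutoffs)
  if (any(cuts <= 0)) stopf("config: all cutoffs must be positive")
  if (is.null(cfg$paths$structure) || is.null(cfg$paths$trajectory) ||
      is.null(cfg$paths$out_dir))
    stopf("config: paths$structure, paths$trajectory and paths$out_dir are required")
  if (!cfg$gate$rule %in% c("CA", "CG")) stopf("config: gate rule must be CA or CG")
  invisible(TRUE)
}

#' Load / save an analysis configuration (YAML)
#'
#' The config round-trips: load(save(x)) is identical to x.
#'
#' @param path YAML file.
#' @return An `analysis_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # canonical shapes: length-1 sequences come back as scalars
  cfg$sasa$residues <- as.list(unlist(cfg$sasa$residues))
  cfg$sf_resids <- as.integer(unlist(cfg$sf_resids))
  validate_config(cfg)
  class(cfg) <- "analysis_config"
  cfg
}

#' @rdname load_config
#' @param cfg An `analysis_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# "R395.III" -> list(resid, subunit); subunit defaults to I.
label_address <- function(label, site_resids) {
  parts <- strsplit(label, ".", fixed = TRUE)[[1]]
  base <- parts[1]
  resid <- site_resids[[base]] %||% suppressWarnings(as.integer(sub("^[A-Za-z]+", "", base)))
  if (is.null(resid) || is.na(resid)) stopf("cannot parse residue label '%s'", label)
  list(base = base, resid = as.integer(resid),
       subunit = if (length(parts) > 1) parts[2] else "I")
}

#' Run the full analysis pipeline
#'
#' Executes salt-bridge detection, lipid tracking, gate/pore geometry,
#' permeation counting, SASA stratification and pose clustering in
#' order.  Referenced residues are validated against the structure
#' before any compute; a stage failure is logged and isolated so later
#' independent stages still run.  Deterministic outputs are bit-identical
#' across reruns with the same config.
#'
#' @param cfg An `analysis_config` or path to a YAML config.
#' @return A `run_manifest` (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  out_dir <- cfg$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sm <- if (length(cfg$subunit_map)) unlist(cfg$subunit_map) else NULL
  traj <- read_trajectory(read_structure(cfg$paths$structure, subunit_map = sm),
                          cfg$paths$trajectory)

  # validate referenced residues before any compute
  for (lab in c(unlist(cfg$sites$transient), unlist(cfg$sites$activation),
                cfg$sites$transfer_residue)) {
    ad <- label_address(lab, cfg$site_resids)
    if (!length(select_atoms(traj, resid = ad$resid)))
      stopf("config validation: residue %s (%d) not present in structure",
            lab, ad$resid)
  }
  for (r in c(cfg$gate$resid, cfg$sf_resids, cfg$bridge$basic_resid,
              cfg$bridge$acidic_resid))
    if (!length(select_atoms(traj, resid = r)))
      stopf("config validation: residue %d not present in structure", r)

  manifest <- list(tool = "sktraj", version = as.character(utils::packageVersion("sktraj")),
                   seed = cfg$seed, stages = list())
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(status = "ok", files = fun(), error = NULL),
                    error = function(e) list(status = "error", files = character(0),
                                             error = conditionMessage(e)))
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    manifest$stages[[name]] <<- res
  }
  shared <- new.env()

  stage("saltbridge", function() {
    sus <- c("I", "II", "III", "IV")
    files <- character(0)
    rows <- list(); evrows <- list()
    for (k in 1:4) {
      prv <- (k + 2) %% 4 + 1
      gb <- residue_charge_group(traj, cfg$bridge$basic_resid, subunit = sus[k])
      ga <- residue_charge_group(traj, cfg$bridge$acidic_resid, subunit = sus[prv])
      cs <- contact_timeseries(traj, gb, ga, cfg$cutoffs$bridge, "heavy_atom_min")
      pair <- paste(gb$label, ga$label, sep = ":")
      rows[[pair]] <- data.frame(frame = seq_along(cs$states),
                                 time_ns = cs$times, pair = pair,
                                 min_distance_A = cs$min_distance,
                                 formed = cs$states)
      ev <- bridge_events(cs)
      if (nrow(ev)) evrows[[pair]] <- cbind(pair = pair, ev)
      if (sus[k] == cfg$bridge$basic_subunit) shared$bridge_series <- cs
    }
    f1 <- file.path(out_dir, "saltbridge_timeseries.tsv")
    write_tsv(do.call(rbind, rows), f1)
    f2 <- file.path(out_dir, "saltbridge_events.tsv")
    write_tsv(if (length(evrows)) do.call(rbind, evrows) else
      data.frame(pair = character(0), formed_frame = integer(0),
                 broken_frame = integer(0)), f2)
    c(f1, f2)
  })

  stage("lipidtrack", function() {
    lip_chains <- chains_for_subunit(traj, "lipid")
    lipid_ids <- if (length(lip_chains))
      sort(unique(traj$atoms$resid[traj$atoms$chain %in% lip_chains &
                                     traj$atoms$resname == cfg$lipid_resname]))
    else integer(0)
    if (!length(lipid_ids)) stopf("no lipids in structure")
    site_labels <- c(unlist(cfg$sites$transient), unlist(cfg$sites$activation),
                     cfg$sites$transfer_residue)
    residues <- list()
    for (lab in site_labels) for (su in c("I", "II", "III", "IV")) {
      ad <- label_address(lab, cfg$site_resids)
      residues[[paste0(lab, ".", su)]] <-
        residue_charge_group(traj, ad$resid, subunit = su)
    }
    lipids <- lapply(lipid_ids, function(id)
      lipid_charge_group(traj, id, cfg$lipid_resname))
    files <- character(0)
    itrows <- list(); trrows <- list(); pathrows <- list()
    for (i in seq_along(lipids)) {
      trk <- unwrap_xy(traj, lipids[[i]])
      pathrows[[i]] <- data.frame(lipid = lipids[[i]]$label,
                                  frame = seq_len(n_frames(traj)),
                                  x_A = trk$xy[, 1], y_A = trk$xy[, 2],
                                  leaflet = trk$leaflet)
      itin <- build_itinerary(traj, lipids[[i]], residues,
                              cutoff = cfg$cutoffs$tracking)
      if (nrow(itin$visits))
        itrows[[i]] <- cbind(lipid = lipids[[i]]$label, itin$visits)
      tr <- classify_transfers(itin, sites = cfg$sites)
      if (nrow(tr)) trrows[[i]] <- cbind(lipid = lipids[[i]]$label, tr)
    }
    f <- character(3)
    f[1] <- write_tsv(do.call(rbind, pathrows),
                      file.path(out_dir, "lipid_paths.tsv"))
    f[2] <- write_tsv(if (length(itrows)) do.call(rbind, itrows) else
      data.frame(lipid = character(0), residue = character(0),
                 first_frame = integer(0), last_frame = integer(0)),
      file.path(out_dir, "lipid_itineraries.tsv"))
    f[3] <- write_tsv(if (length(trrows)) do.call(rbind, trrows) else
      data.frame(lipid = character(0), from_site = character(0),
                 to_site = character(0), via_residue = character(0),
                 frame = integer(0)),
      file.path(out_dir, "lipid_transfers.tsv"))
    occ <- occupancy_map(traj, lipids, residues, cutoff = cfg$cutoffs$tracking)
    f[4] <- write_tsv(occ, file.path(out_dir, "lipid_occupancy.tsv"))
    f
  })

  stage("geometry", function() {
    gate <- gate_distances(traj, cfg$gate$resid, cfg$gate$rule)
    shared$gate <- gate
    f <- write_tsv(as.data.frame(gate), file.path(out_dir, "gate_distances.tsv"))
    if (!is.null(shared$bridge_series)) {
      bg <- bridge_vs_gate(gate, shared$bridge_series)
      f <- c(f, write_tsv(cbind(bg$bins, trend = bg$trend),
                          file.path(out_dir, "bridge_vs_gate.tsv")))
    }
    pidx <- select_atoms(traj, subunit = c("I", "II", "III", "IV"))
    zr <- range(atom_coords(traj, 1, pidx)[, 3])
    pp <- pore_profile(traj, frame = 1, z_range = zr, dz = cfg$pore$dz,
                       n_restarts = cfg$pore$n_restarts, seed = cfg$seed)
    f <- c(f, write_tsv(data.frame(z_A = pp$z, radius_A = pp$radius,
                                   x_A = pp$x, y_A = pp$y),
                        file.path(out_dir, "pore_profile.tsv")))
    sf <- sf_carbonyl_distances(traj, frame = 1, sf_resids = cfg$sf_resids)
    c(f, write_tsv(sf, file.path(out_dir, "sf_carbonyl_distances.tsv")))
  })

  stage("permeation", function() {
    sf <- build_sf_model(traj, cfg$sf_resids)
    ion_atoms <- select_atoms(traj, subunit = "ion")
    if (!length(ion_atoms)) stopf("no ions in structure")
    ss <- site_timeseries(traj, sf, ion_atoms)
    rec <- count_permeations(ss, times = traj$times,
                             voltage_mv = cfg$voltage_mv)
    g <- tryCatch(conductance(rec), error = function(e) NA_real_)
    f <- character(0)
    lab <- do.call(rbind, lapply(names(ss), function(nm)
      data.frame(ion_atom = nm, frame = seq_along(ss[[nm]]), site = ss[[nm]])))
    f[1] <- write_tsv(lab, file.path(out_dir, "ion_sites.tsv"))
    f[2] <- write_tsv(rec$events, file.path(out_dir, "permeation_events.tsv"))
    f[3] <- write_tsv(data.frame(n_up = rec$n_up, n_down = rec$n_down,
                                 net_flux = rec$net_flux,
                                 total_events = rec$total_events,
                                 duration_ns = rec$duration_ns,
                                 voltage_mv = rec$voltage_mv,
                                 conductance_pS = g),
                      file.path(out_dir, "permeation_summary.tsv"))
    f
  })

  stage("sasa", function() {
    lip_chains <- chains_for_subunit(traj, "lipid")
    lipid_ids <- if (length(lip_chains))
      sort(unique(traj$atoms$resid[traj$atoms$chain %in% lip_chains &
                                     traj$atoms$resname == cfg$lipid_resname]))
    else integer(0)
    lipids <- lapply(lipid_ids, function(id)
      lipid_charge_group(traj, id, cfg$lipid_resname))
    rows <- list(); sums <- list()
    for (lab in unlist(cfg$sasa$residues)) {
      ad <- label_address(lab, cfg$site_resids)
      grp <- residue_charge_group(traj, ad$resid, subunit = ad$subunit)
      ss <- sasa_series(traj, grp, lipids,
                        bound_cutoff = cfg$cutoffs$sasa_bound,
                        n_points = cfg$sasa$n_points)
      rows[[lab]] <- cbind(residue = grp$label, as.data.frame(ss))
      st <- stratify_sasa(ss)
      sums[[lab]] <- data.frame(residue = grp$label,
                                mean_bound = st$mean_bound, sd_bound = st$sd_bound,
                                mean_unbound = st$mean_unbound,
                                sd_unbound = st$sd_unbound,
                                n_bound = st$n_bound, n_unbound = st$n_unbound,
                                variance_ratio = st$variance_ratio)
    }
    f <- character(2)
    f[1] <- write_tsv(do.call(rbind, rows), file.path(out_dir, "sasa_series.tsv"))
    f[2] <- write_tsv(do.call(rbind, sums), file.path(out_dir, "sasa_summary.tsv"))
    f
  })

  stage("cluster", function() {
    if (is.null(shared$bridge_series)) stopf("salt-bridge stage did not run")
    strata <- stratify_frames(shared$bridge_series)
    sel <- select_atoms(traj, resid = cfg$bridge$basic_resid,
                        chain = chains_for_subunit(traj, cfg$bridge$basic_subunit))
    rows <- list(); files <- character(0)
    for (nm in c("formed_frames", "absent_frames")) {
      fr <- strata[[nm]]
      if (length(fr) < 2) next
      if (length(fr) > cfg$cluster$max_frames)
        fr <- fr[round(seq(1, length(fr), length.out = cfg$cluster$max_frames))]
      pc <- cluster_poses(traj, fr, sel, k = cfg$cluster$k, seed = cfg$seed)
      rows[[nm]] <- data.frame(stratum = sub("_frames", "", nm), frame = pc$frames,
                               cluster = pc$assignments,
                               medoid = pc$frames %in% pc$medoid_frames)
      for (mf in pc$medoid_frames) {
        p <- file.path(out_dir, sprintf("medoid_%s_frame%04d.pdb",
                                        sub("_frames", "", nm), mf))
        write_structure(traj, p, frame = mf)
        files <- c(files, p)
      }
    }
    if (!length(rows)) stopf("too few frames in every stratum")
    f <- write_tsv(do.call(rbind, rows), file.path(out_dir, "pose_clusters.tsv"))
    c(f, files)
  })

  manifest$stages <- manifest$stages
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$path <- mf
  class(manifest) <- "run_manifest"
  manifest
}

#' Assemble a text report from a pipeline run
#'
#' Copies numbers from the stage output files (single source of truth;
#' nothing is recomputed).  Stages without outputs are marked "not
#' run".
#'
#' @param manifest A `run_manifest` from [run_pipeline()], or the output
#'   directory containing `manifest.json`.
#' @param path Output file (default `report.txt` next to the manifest).
#' @return The report path, invisibly.
#' @export
report_pipeline <- function(manifest, path = NULL) {
  if (is.character(manifest)) {
    dir <- manifest
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
  } else dir <- dirname(manifest$path)
  path <- path %||% file.path(dir, "report.txt")
  ln <- c(sprintf("sktraj analysis report (tool %s, config %s)",
                  manifest$version, manifest$config_hash), "")
  sec <- function(title, stage, body) {
    st <- manifest$stages[[stage]]
    ln <<- c(ln, paste0("== ", title, " =="))
    if (is.null(st) || !identical(st$status, "ok")) {
      ln <<- c(ln, paste0("  not run",
                          if (!is.null(st$error)) paste0(" (", st$error, ")")), "")
    } else {
      ln <<- c(ln, body(), "")
    }
  }
  sec("Salt bridges", "saltbridge", function() {
    d <- read_tsv(file.path(dir, "saltbridge_timeseries.tsv"))
    vapply(split(d, d$pair), function(x)
      sprintf("  %s: formed fraction %.3f", x$pair[1], mean(x$formed)), "")
  })
  sec("Lipid itineraries and transfers", "lipidtrack", function() {
    it <- read_tsv(file.path(dir, "lipid_itineraries.tsv"))
    tr <- read_tsv(file.path(dir, "lipid_transfers.tsv"))
    c(sprintf("  %d visits across %d lipid(s)", nrow(it),
              length(unique(it$lipid))),
      if (nrow(tr)) sprintf("  transfer: %s %s -> %s via %s at frame %d",
                            tr$lipid, tr$from_site, tr$to_site,
                            ifelse(is.na(tr$via_residue), "-", tr$via_residue),
                            tr$frame)
      else "  no site-to-site transfers")
  })
  sec("Gate geometry", "geometry", function() {
    g <- read_tsv(file.path(dir, "gate_distances.tsv"))
    p <- read_tsv(file.path(dir, "pore_profile.tsv"))
    c(sprintf("  gate d(I-III) %.2f +/- %.2f A, d(II-IV) %.2f +/- %.2f A",
              mean(g$d_I_III), stats::sd(g$d_I_III),
              mean(g$d_II_IV), stats::sd(g$d_II_IV)),
      sprintf("  geometric mean %.2f +/- %.2f A",
              mean(g$geometric_mean), stats::sd(g$geometric_mean)),
      sprintf("  pore minimum radius %.2f A at z = %.1f A",
              min(p$radius_A), p$z_A[which.min(p$radius_A)]))
  })
  sec("Permeation and conductance", "permeation", function() {
    s <- read_tsv(file.path(dir, "permeation_summary.tsv"))
    sprintf("  %d up / %d down crossings, net %+d; conductance %.3f pS at %s mV",
            s$n_up, s$n_down, s$net_flux, s$conductance_pS,
            format(s$voltage_mv))
  })
  sec("SASA by lipid-bound state", "sasa", function() {
    s <- read_tsv(file.path(dir, "sasa_summary.tsv"))
    sprintf("  %s: bound %.1f +/- %.2f A^2 (n=%d), unbound %.1f +/- %.2f A^2 (n=%d)",
            s$residue, s$mean_bound, s$sd_bound, s$n_bound,
            s$mean_unbound, s$sd_unbound, s$n_unbound)
  })
  sec("Pose clusters", "cluster", function() {
    d <- read_tsv(file.path(dir, "pose_clusters.tsv"))
    vapply(split(d, d$stratum), function(x)
      sprintf("  %s: %d frames, %d cluster(s), medoid frame(s) %s",
              x$stratum[1], nrow(x), length(unique(x$cluster)),
              paste(x$frame[x$medoid], collapse = ", ")), "")
  })
  writeLines(ln, path)
  invisible(path)
}
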