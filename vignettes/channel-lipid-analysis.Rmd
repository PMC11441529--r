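---
title: "Analysing lipid-dependent gating of SK channels from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing lipid-dependent gating of SK channels from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sktraj)
```

## The scientific problem

Small-conductance Ca^2+^-activated K^+^ (SK) channels are homotetramers
gated by intracellular Ca^2+^ through constitutively bound calmodulin
(CaM).  The anionic inner-leaflet lipid PIP2 is a co-factor of
activation: its headgroup phosphates form salt bridges with basic
residues on the channel's cytoplasmic face, and occupancy of a specific
"activation" site near the pore-lining S6 helices correlates with
disruption of an inter-subunit R395:E398 salt bridge and widening of the
hydrophobic gate at V390.

`sktraj` implements the trajectory-analysis battery with which this
mechanism is quantified from all-atom MD simulations of an SK2--CaM
tetramer in a membrane:

1. **Salt-bridge tracking.**  Charged groups (Arg guanidinium N, Lys
   NZ, Glu/Asp carboxylate O, lipid phosphate O) are reduced to centres
   of charge.  Two distance rules coexist because they answer different
   questions: the *tracking* rule (centre-of-charge distance, cutoff
   5.5 Å) defines when a laterally diffusing lipid is "at" a residue,
   while the *bridge* rule (minimum heavy-atom N···O distance, cutoff
   3.6 Å) defines a formed salt bridge in time-series plots.  A third
   rule (N···O < 4 Å) defines the bound/unbound stratification used by
   the SASA analysis.  All three are named constants in the analysis
   configuration, never literals in code.
2. **Lipid itineraries.**  Each lipid's headgroup is unwrapped in the
   membrane plane (minimum-image increment accumulation) and its
   maximal contact runs against candidate residues become an ordered
   itinerary of visits.  Visits are classified against a configurable
   site taxonomy — transient site {R271, K278, R286}, activation site
   {R299, R395, K396, K471}, relay residue R418 — and a *transfer* is
   emitted when consecutive site-assigned visits change site, with the
   relay recorded when it mediated the change.
3. **Gate geometry.**  Across-subunit distances at V390 (backbone CA or
   side-chain CG rule) for the fixed opposite pairs I–III and II–IV,
   summarised per frame by the geometric mean `sqrt(d13 * d24)`, which
   under-weights asymmetric openings (by AM–GM it never exceeds the
   arithmetic mean).  Pair assignment always comes from the
   chain-to-subunit map, never from geometry.
4. **Pore profiling.**  A HOLE-style spherical-probe profile: at each z
   slice the radius is `max over centres of (min over atoms of
   |c - atom| - vdw)`, maximised by a coarse grid plus seeded random
   restarts, each polished by a deterministic compass search.
5. **Permeation and conductance.**  The six SF residues' backbone
   carbonyl planes define the five K^+^ sites S0–S4; an ion's
   per-frame site label feeds a state machine that counts complete
   below→above (or reverse) passages.  Conductance is
   `g = net_flux × e / (duration × |V|)`.
6. **SASA.**  Shrake–Rupley areas from a deterministic golden-spiral
   point set, stratified by the 4 Å lipid-bound rule, with the
   bound/unbound variance ratio as the summary of side-chain pinning.
7. **Pose clustering.**  Frames stratified by a named bridge's state
   are clustered with k-medoids (PAM) on a superposition-corrected
   selection-RMSD matrix; medoid frames are the representative poses,
   and circular statistics of side-chain dihedrals per cluster expose
   rotamer shifts.

## Conventions

Coordinates are in Å, times in ns, voltages in mV, areas in Å².
Frames are indexed from 1, the R convention, and all reported frame
intervals are inclusive.  Boxes are orthorhombic; triclinic input is
rejected explicitly.  The membrane normal is z.  Van der Waals radii
follow Bondi's compilation (with K^+^ at 2.75 Å), overridable at read
time; unknown elements are an error, never a default.

## Tunable parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| tracking cutoff | 5.5 | Å | lipid-at-residue rule (centre of charge) |
| bridge cutoff | 3.6 | Å | salt-bridge formed rule (min N···O) |
| SASA bound cutoff | 4.0 | Å | bound/unbound stratification rule |
| probe radius | 1.4 | Å | water probe for SASA |
| n_points | 960 | – | golden-spiral points per atom |
| entry margin | 2 | Å | SF hysteresis against boundary flicker |
| voltage | 750 | mV | applied field for the conductance estimate |
| pore dz | 0.5 | Å | slice spacing |
| n_restarts | 32 | – | random restarts per pore slice |
| search radius | 6 | Å | per-slice pore-centre search disk |
| min_dwell | 1 | frame | minimum visit length (brush-contact filter) |

Two parameters deserve comment.  The *entry margin* exists because an
ion sitting near the outermost carbonyl plane would otherwise flicker
between "below" and "S4" and fragment one passage into many; with
hysteresis an ion only re-acquires an outside label after retreating a
margin beyond the outer plane.  The *search radius* keeps the pore
probe threaded through the pore: the slice objective grows without
bound outside the protein, so the per-slice maximisation is confined to
a disk around the previous slice's centre (and the objective is capped
at the sentinel radius), which is also what makes profiles of open,
shallow, or sparse structures terminate deterministically.

## The synthetic-data generator

No deposited multi-microsecond trajectory is small enough to test
against routinely, so every analysis stage is validated against a
generator whose output has *programmable ground truth*
(`synth_config()` / `synth_generate()`).  It emulates exactly the
features the analyses touch and nothing else:

* four pseudo-symmetric subunits carrying minimal pseudo-residues —
  V390 CA/CG rings whose diameter follows a per-frame schedule, a
  six-plane SF carbonyl stack 3 Å apart, basic anchors (R271, K278,
  R286, R418, R299, R395, K396, K471, and CaM K116) at distinct
  bearings on a wide ring in the lower leaflet, spaced ≈14 Å so the
  5.5 Å tracking rule can never confuse neighbours;
* an E398 carboxylate that sits 2.8 Å from its partner R395 while the
  inter-subunit bridge is formed and 7 Å when broken.  Bridge state is
  driven by an explicit schedule or by a gate-diameter threshold
  (reproducing the bridge/gate anti-correlation as a constructed
  property), and is broken outright while a lipid is parked at that
  R395 — the disruption mechanism as ground truth;
* lipids with a 5-atom phosphate headgroup moving laterally in the
  lower leaflet, either along deterministic waypoint itineraries
  (travel frames on an outer ring, dwell frames parked 2 Å from the
  residue's charge centre) or as reflected random walks with sticky
  capture and geometric (memoryless) dwell;
* K^+^ ions executing scheduled linear transits through the SF stack,
  with bulk ions clamped below the filter so they can never generate
  spurious crossings;
* thermal jitter on basic side-chain N atoms that is damped while
  lipid-bound, which produces the bound-state SASA variance reduction
  as an emergent property of the fixture rather than an asserted
  number.

One global seed drives every stochastic draw, so identical configs are
bitwise reproducible.  Periodic wrapping is applied only when fixtures
are written to PDB/DCD, which is what exercises the unwrapping code on
re-read.

What the generator deliberately does **not** emulate: physical force
fields, water, realistic side-chain sterics, correlated protein
motions, or multi-ion knock-on in the filter.  Passing the recovery
suites therefore shows that the *analyses* are correct (they measure
what they claim to measure, at the stated tolerances), not that any
biological conclusion about real trajectories is reproduced.

## Numerical choices

* **Gate recovery tolerance 0.01 Å** covers single-precision DCD
  round-tripping; the generator itself is exact to machine precision.
* **Pore profiling** is compared against an exhaustive 0.1 Å grid
  oracle to within 0.05 Å on 200-atom artificial pores.  The compass
  polish runs to a 0.002 Å step, so the bound is dominated by basin
  selection, mitigated by the coarse grid and the seeded restarts.
* **SASA** uses a deterministic spiral rather than random sampling so
  results are bit-reproducible; the Monte-Carlo comparison (random
  points) lives only in the test oracle.  Per-atom agreement is within
  2% for meaningfully exposed atoms; almost-buried atoms are compared
  absolutely at the sampling quantum.  Occluders default to protein +
  CaM + lipid heavy atoms jointly (the parked headgroup must occlude),
  with ions and solvent excluded; absolute areas depend on this choice,
  which is why no absolute SASA value is asserted anywhere.
* **Event merging**: bridge events default to `min_dwell = 1` (every
  maximal run counts); gap merging is available as explicit smoothing
  and is applied before the run-length filter.
* **Conductance** uses net flux so opposing crossings cancel, matching
  the physical current; total event counts remain on the record.
* **k-medoids** (PAM via the cluster package) is deterministic, so the
  `seed` argument of `cluster_poses()` exists only for interface
  stability; k defaults to a silhouette scan over 2–5 with a fallback
  to a single cluster when no split has positive silhouette.
* **Ties**: simultaneous lipid visits are ordered by first frame, then
  residue label; degenerate strata (all-bound, single gate bin,
  constant-fraction profiles) are reported as such (NA or 0 trends)
  rather than erroring.

## Design decisions that were genuinely open

* The published protocol states "the centre of the charges" for the
  lipid without fixing whether each phosphate counts separately; the
  default here is the whole-headgroup centroid, with per-phosphate
  groups constructible through `charge_group()`.
* The alignment method behind published identity/similarity figures is
  rarely stated; `pairwise_align()` pins global Needleman–Wunsch,
  BLOSUM62, gap open 10 / extend 0.5, and documents that third-party
  percentages may differ by a few points under other choices.
* Frames are indexed from 1 throughout because this is an R package;
  all interval fields (`first_frame`, `formed_frame`, ...) are
  inclusive.
* DCD is the supported trajectory format (read through bio3d, written
  by this package); XTC input raises an explicit unsupported-format
  error rather than a silent fallback.
* SF site planes are time-averaged by default (the filter is
  restrained in the simulations this package targets); per-frame
  planes can be requested by passing a frame subset.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: 120–160-frame trajectories of ≈130 atoms for the recovery
suites, a 5001-frame ≈250-atom trajectory for the 58-crossing
conductance example, 200-atom artificial pores for the grid-oracle
comparison, 20-atom clusters against a 10^6-point Monte-Carlo SASA
oracle, and 10^4 random site walks against the permeation pattern
oracle.  These sizes were chosen so that each suite probes its
tolerance with comfortable statistics while the whole battery stays
interactive.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* No force-field or energetic reasoning anywhere: every quantity is
  geometric or counting-based.
* SASA ignores periodic images (the complex must not touch its own
  image, which holds for the intended solvated systems).
* The permeation state machine assumes the filter axis is z and that
  site planes do not cross during the trajectory.
* Reference-model checks (deposited open/closed structures, database
  sequences) require the user to download those inputs; the package
  ships no third-party structural data.
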