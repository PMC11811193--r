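---
title: "Analysing coarse-grained membrane-protein trajectories with memtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing coarse-grained membrane-protein trajectories with memtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtraj)
```

## The scientific setting

Coarse-grained (CG) molecular dynamics is the standard way to reach the
microsecond-to-millisecond timescales on which peripheral proteins engage
membranes and membrane proteins reshape the bilayer around themselves. A
recurring analysis problem is the one posed by amphipathic helices binding
β-barrel channels such as VDAC: the binding determinant is a glutamate
buried in the hydrophobic core of the outer channel wall, so understanding
the interaction requires, in one coherent frame of reference, (i) the
kinetics of residue–residue contacts between the helix and the buried
residue, (ii) how the channel locally thins the leaflet and lets water into
the core, (iii) how long the peptide stays adsorbed at all, and (iv) the
protonation equilibrium — the effective pKa — of the buried residue.

memtraj implements that analysis layer. It takes frames of bead
coordinates (nm) with per-frame orthorhombic boxes, a role map labelling
beads as lipid phosphates/glycerols, water, protein, proton particles or
titratable sites, and produces contact-event statistics, leaflet thinning
maps, water-defect and occupancy fields, residence times and titration
fits. It does not run dynamics: trajectories come from an MD engine, or —
for validation — from the package's own synthetic generators.

## Data model and conventions

* **Units**: nm and ns everywhere internally. PDB input (Å) is converted on
  read; the "2 Å" occupancy spacing is stored as 0.2 nm; OpenDX output is
  written in Å because molecular viewers expect it.
* **Indexing**: particle indices and frames are 1-based, the R convention.
  Role-map CSVs may carry 0-based indices (the convention of most
  trajectory tooling); `read_role_map(index_base = 0)` converts them. Frame
  `i` is reported at time `(i − 1)·dt`, so the first stored frame is t = 0.
* **Periodicity**: orthorhombic boxes only; all distances are
  minimum-image. Triclinic input is rejected rather than mishandled.
* **Two membrane centers** are maintained, because different stages call
  for different references: the *glycerol center* (mean of the two leaflet
  glycerol centres of geometry) anchors buried-residue depth traces, while
  the *global lipid center* (uniform-weight center of all lipid beads, with
  an optional mass-weight switch) anchors thinning maps and the defect
  cylinder. With symmetric leaflets they coincide; with asymmetric
  compositions they need not.
* **Leaflets** are assigned once, by the sign of phosphate z against the
  median at a reference frame. CG lipids do not flip-flop on the analyzed
  timescales, so no per-frame tracking is attempted (and none is offered).

## The analyses and their parameters

### Contacts and events

Residue contact prevalence counts frames where *any* bead pair of two
residues is within `d_contact` (default 0.6 nm — the CG bead-contact
distance). For kinetics, a single cutoff is noisy: when the distance
fluctuates around the threshold, one binding episode fragments into many
spurious events. The double-cutoff rule avoids this: a candidate event is a
maximal run of frames inside `d_event_outer` (1.0 nm), kept only if it
reaches below `d_contact` at least once. Both cutoffs are configurable via
`analysis_config()`; the inner must stay below the outer.

Lifetimes are summarized weighting by duration, `τ̄ = Σd²/Σd`, which is the
experimentally relevant occupancy-weighted mean (long events dominate the
bound ensemble). Its uncertainty is a weighted SEM with reliability weights
`w = d`: `SEM = sqrt(Var_w · Σw²/(Σw)²)`. For an exponential off-process
the duration-weighted mean converges to `2/k_off`, not `1/k_off` — tests
against the telegraph generator check the *unweighted* mean against
`1/k_off` and the weighted formula against its closed form. Histograms use
logarithmic bins (default five per decade from `dt` upward), each bin
holding summed event duration normalized by total simulated time.
Trajectory-truncated events are kept at their observed duration and
flagged censored; no survival model is applied.

### Thinning maps, defects, occupancy, depth

The thinning field is the per-bin (0.1 nm lateral) mean of
|z<sub>phosphate</sub> − z<sub>center</sub>| for one leaflet, pooled over
frames. Sparse bins lie: a bin is valid only with **more than 30**
phosphate observations (the 30/31 edge is tested explicitly). At ~1.6
lipids/nm² leaflet density this mask needs thousands of frames — the
package's own validation uses 2200 frames of a 386-lipid patch, which the
map accumulates in about a second. When a protein is present, frames are
first centered in xy on the protein and rotationally fitted about z only
(`center_and_rotfit()`; closed-form 2-D Kabsch angle, uniform bead
weights), so maps and grids share the protein's frame of reference. The
"minimum near the protein" summary takes the lowest valid bin in a
configurable annulus around the protein center, resolved by azimuth so
that separate thinning spots produce separate local minima.

Water defects count water beads inside a cylinder of radius 2.5 nm (xy,
minimum-image, re-anchored each frame on the protein's xy center) within
±1.5 nm of the global membrane center in z. Occupancy grids record, per
0.2 nm cell, the percentage of frames with at least one selected bead
present — binary per cell per frame, not a density — and export a 0.5 %
iso-occupancy mask plus a triangulated surface built from exposed voxel
faces (two triangles per face). A marching-cubes surface would be smoother;
the voxel surface preserves the tested property that mask volume is
non-increasing in the threshold, and writes standard OBJ.

Depth traces report side-chain z (center of geometry if several beads)
minus the glycerol center, positive toward the cytosolic leaflet, with
per-replica SD.

### Residence

Desorption is first passage: residence ends at the first frame whose
peptide–membrane minimum distance strictly exceeds `d_desorb` (1.4 nm —
comfortably beyond the CG interaction range, so recrossings from the
adsorbed state are rare). No smoothing is applied. Replicas that never
cross are censored and reported as lower bounds, never averaged in.

### Titration

Constant-pH CG simulations record, per frame, how many proton particles
are bound to a titratable site. The degree of deprotonation at a pH is the
fraction of *window* frames (the last 10 ns of each run, discarding the
approach to equilibrium) with zero bound protons, averaged over the three
independent titration sets with SEM. The pKa comes from a least-squares
Henderson–Hasselbalch fit with Hill slope fixed to 1 (one site, one
proton); a free-Hill option and a model-free interpolated midpoint are
provided as diagnostics, and the fit is flagged if the pKa falls outside
the fitted pH span. Shifts are reported against the 4.3 solution reference
of free glutamate.

## What the synthetic generators emulate — and what they do not

Each generator reproduces the *statistical geometry* an analysis stage
assumes, with an analytic truth record:

* `make_bilayer()` — leaflet planes at ±1.95 nm (the leaflet thickness of
  a pure-POPC CG bilayer) with Gaussian z-jitter (0.08 nm), lateral random
  walks, and imposed Gaussian funnels, so the map minimum is known exactly
  (`h − depth`). Defaults mirror a 386-lipid patch stored every 0.5 ns.
* `make_protein_wall()` — a static bead cylinder with one titratable side
  chain at a prescribed signed depth.
* `make_waters()` — bulk beads excluded from the membrane core plus a
  defect pool entering a column with per-frame probability `p`, giving an
  analytic expected count `n·p` (linear in the enrichment factor).
* `make_contact_trace()` — a two-state Markov chain with per-frame
  transition probabilities `1 − exp(−k·dt)`; bound/unbound emissions are
  separated from both cutoffs, optional excursions into (0.62, 0.98) nm
  exercise the double-cutoff logic.
* `make_desorption_trace()` — exponential desorption time, then a linear
  rise at 2.2 nm/ns so the analytic 1.4 nm crossing lags the drawn time by
  half a nanosecond.
* `make_titration_series()` — Bernoulli draws on the exact
  Henderson–Hasselbalch curve, 20 ns traces at 0.01 ns spacing (1000
  window frames), three replicate sets on the pH 3–8 half-step grid.

They are deterministic given a seed (the caller's RNG stream is left
untouched). What they do **not** emulate: real lipid packing and its
lateral correlations, protein conformational dynamics, undulations,
electrostatics, or any coupling between stages (the contact trace is not
generated from the bilayer geometry). Passing tests therefore demonstrate
that the *analysis* layer measures what it claims on data with known
structure — not that any particular physical system behaves this way.

## Numerical choices and degenerate inputs

* Bin origins anchor at the box corner; beads are wrapped into the box
  (`%%`) before binning, and the top edge folds into the last bin.
* The rotational fit uses the closed-form angle
  `atan2(Σ(p×q), Σ(p·q))` after centroid removal; a 0.01°-resolution grid
  scan is used as the independent oracle in tests (agreement within
  0.02°). The fit never increases the xy-RMSD to the reference.
* `fit_pka()` optimizes over pH ± 2 of the data span; all-0 or all-1
  fraction vectors are a non-identifiability error, not a silent fit.
* Single events and single replicas report SEM 0 with an explicit
  `sem_defined = FALSE` flag, distinct from a true zero spread.
* Empty selections, overlapping contact groups, all-equal phosphate z
  (degenerate membrane), inner ≥ outer cutoffs, and thresholds outside
  (0, 100) % are all hard errors naming the offending input.
* Problem sizes in the package's own validation: 2200-frame maps,
  60 000-frame telegraph traces, 200 desorption replicas, 100 titration
  experiments — sizes at which every Monte-Carlo tolerance in the test
  suite is a 3-SE band of the corresponding estimator.

## Known limitations

Orthorhombic boxes only; no XTC/TRR reading (convert to GRO/PDB or the
plain-text format first); no lipid flip-flop tracking; no survival
modeling beyond censoring flags; no curvature/tilt analysis; the pooled
("combined replicas") prevalence variant weights replicas by frame count
and is reported alongside, not instead of, the per-replica mean ± SEM.
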