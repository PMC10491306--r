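---
title: "Quantifying lipid scrambling from coarse-grained trajectories"
author: "scramblescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid scrambling from coarse-grained trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblescan)
```

## The observable and the model

A lipid scramblase moves phospholipids between bilayer leaflets. In
coarse-grained (Martini-style) simulations the cleanest per-lipid leaflet
observable is the orientation angle *θ* of the lipid's tail→head direction
against the membrane normal (+z). An upper-leaflet lipid has its headgroup
above its tails, so *θ* ≈ 0°; a lower-leaflet lipid has *θ* ≈ 180°. Each
lipid contributes two tail→head vectors (last tail bead of each chain to
the headgroup bead; `C4A→NC3` and `C4B→NC3` for Martini 3 DOPC), and the
per-lipid orientation is the angle of the *mean of the two unit vectors*.
This is a single splay-insensitive direction; the alternative of averaging
the two angles is available via `angle_method = "angle_mean"`, and on
well-formed lipids the two differ negligibly. Averaging vectors was chosen
as the default because it remains well defined as the two chains splay
apart, degrading only in the (flagged) pathological case of anti-parallel
chains.

Raw thermal motion makes *θ* fluctuate by tens of degrees within a leaflet,
so naive 90°-crossing counts would be dominated by noise. The detector is
therefore a hysteresis (two-threshold) state machine with a buffer band of
55–125°:

* state `UPPER` → one event and state `LOWER` at the first sample with
  *θ* strictly greater than 125°;
* state `LOWER` → one event and state `UPPER` at the first sample with
  *θ* strictly less than 55°;
* samples inside [55°, 125°] never change state and never emit events.

Angles are sampled on a fixed 1 ns grid; crossing times are the sample
times (no sub-sample interpolation — the measurement grid is the protocol's
time resolution). Equality with a threshold counts as buffer occupancy:
the event rule is a strict inequality. If a lipid's declared initial
leaflet contradicts its very first angle sample, the state is corrected
with a warning instead of emitting a phantom event; for traces that
*continue* from a known prior state (concatenation), `correct_initial =
FALSE` disables that correction, which is exactly what makes event counts
additive across concatenated traces.

## Rate statistics and classification

Counting starts after a 2 µs equilibration discard. Events are binned into
half-open 1 µs windows per replica (an event on a boundary belongs to the
later bin; incomplete trailing windows are dropped), so two replicas of
10 µs yield 16 data points per system. The pooled bins give boxplot
statistics — quartiles by linear interpolation of order statistics, and
whiskers in both common conventions (Tukey 1.5×IQR clamped to the data, and
plain min/max), since either may be wanted for plotting. A system is
classified `SCRAMBLER` when the *mean* pooled rate reaches the cut-off of
1 event/µs. The mean was chosen over the median because it is the unbiased
estimator of a Poisson rate and the median of 16 small counts is very
coarse; the cut-off and the rule are configurable.

## Membrane thickness and thinning

The hydrophobic body of the membrane is the set of lipid beads excluding
the headgroup and phosphate beads (defaults `NC3`, `PO4`). Its z-density —
referenced per frame to the bilayer midplane (mean z of the tail-terminal
beads), histogrammed in 0.1 nm bins, sampled every 5 ns after the same 2 µs
discard — forms a slab profile. Thickness is read off as the full width at
half maximum (FWHM) with linear interpolation at the half-maximum
crossings. FWHM was chosen because it is parameter-free, robust to overall
density scale, and exact on idealised slab shapes; a profile with more than
two half-maximum crossings (multimodal) raises an error rather than
guessing. Local thickness uses only lipids having any bead within 1.0 nm of
any protein bead (lipid-level selection: the lipid, not the bead, is the
physical unit), with xy minimum-image distances; thinning is bulk minus
local thickness. A cross-system report of Pearson correlation between mean
scrambling rate and thinning is provided (`rate_thinning_correlation`);
note that with ~20 systems the null sampling spread of *r* is already
about ±0.23, so only substantial correlations are interpretable at that
sample size.

## Pathway mapping

The transit window of an event is the contiguous buffer-resident interval
ending at the counted crossing — the buffer-entry sample through the
crossing sample, inclusive. Headgroup coordinates over that window form the
scrambling-pathway point cloud (exported as pseudo-atom PDB), and each
(event, sample) pair within 0.6 nm of any bead of a protein residue
increments that residue's contact count. 0.6 nm is a typical CG
bead-contact distance and is configurable. Only post-equilibration events
are mapped, mirroring the rate statistics. Both pooled and per-event
outputs are available, since a published pathway picture may show either a
representative event or the pool.

## The synthetic bilayer generator

`simulate_bilayer()` is a kinematic fixture generator, not an MD engine: no
force field, no energetics, no barostat. It emulates exactly the
statistical structure the analysis consumes:

* two leaflets of pseudo-DOPC lipids (12 beads: `NC3 PO4 GL1 GL2 C1A–C4A
  C1B–C4B`) on a lattice (0.8 nm spacing, ≈0.64 nm² per lipid), tail
  terminals anchored at the midplane, bead offsets chosen to give a
  ≈2.9 nm bulk hydrophobic span and ≈4.1 nm head–head distance — realistic
  DOPC values;
* within-leaflet angular noise: independent per frame, Gaussian with sd
  `angular_noise_deg` (default 15°) *clipped at 3 sd*. Clipping makes the
  generator's noise guarantees sharp: with the default, excursions never
  even enter the buffer; at sd 25° they may enter but can provably never
  cross it, so any detected event is a true flip. An unbounded Gaussian
  would violate that at a rate of ~3×10⁻⁷ per sample;
* flip-flop as a per-system Poisson process at `flip_rate` events/µs. Each
  flip picks a random non-transiting lipid and sweeps its angle linearly
  from one leaflet base to the other over an exponential dwell (mean
  `transit_dwell_ns`, default 25 ns, floored at one frame). The ledger
  records the start, the ramp end, and the first sampling-grid time at
  which the ramp is strictly beyond the far threshold — the generator-side
  kinematic truth of when the crossing becomes observable, which is what
  detector matching compares against (one-frame tolerance). Flips whose
  crossing would fall beyond the trajectory end are unobservable and are
  excluded from the ledger;
* positional noise: each lipid receives a rigid per-frame z shift (sd
  0.25 nm) plus small independent per-bead jitter (sd 0.02 nm). The rigid
  shift is what smooths the layered bead comb into a smooth slab density
  (it cannot perturb orientation angles); the per-bead jitter is kept small
  on purpose so that threshold-crossing times remain within one frame of
  the ledger;
* an optional cylindrical pseudo-protein (default radius 1 nm, height 4 nm,
  5 rings × 10 beads, one bead per residue). With `pore = TRUE`, flipping
  lipids are repositioned so their *headgroup* tracks a pathway line
  0.35 nm outside the ring column at azimuth zero; those column residues
  are recorded as the known pore lining. With `local_thinning_nm` set,
  lipids within 1 nm of the protein surface have all bead offsets scaled
  down so their hydrophobic span shrinks by exactly that amount;
* seeding: one root seed; replica seeds are drawn deterministically from
  it, and each replica consumes its stream in a fixed order, so output is
  bit-reproducible (same seed → byte-identical GRO files).

What the generator does *not* emulate — collective undulations, area/volume
fluctuations, protein conformational dynamics, realistic transit kinetics
(lipids pause and recross in real pores), lipid–lipid correlations —
bounds what green tests mean: they validate the *analysis protocol*
(thresholding, binning, discards, selections, FWHM extraction, contact
mapping) against known truth, not the physics of any particular scramblase.

## Numerical choices and degenerate inputs

* Units are nm and ns everywhere; PDB input (Å) is converted on read.
* xy distances use the minimum-image convention; the bilayer is assumed
  whole (not wrapped) along z and this is validated — a z extent above 90%
  of the box aborts with advice to re-image.
* Leaflet initialisation (unstated in typical protocol descriptions) uses
  head-bead z against the mean tail-terminal z at the first analysed frame,
  cross-checked against the initial angle; inconsistent lipids are flagged,
  a one-sided bilayer is a hard error. Leaflet state afterwards is owned
  exclusively by the event detector — there is no static re-assignment
  mid-trajectory.
* Trajectories whose sampling does not land on the requested stride are
  resampled to the nearest frame with a warning.
* Zero-length orientation vectors (coincident beads) and anti-parallel
  chain vectors are geometry errors naming the lipid.
* Replicates are identified by input file order (replica 0, 1, …) and the
  id is carried through every downstream record.

## Problem sizes used in the shipped tests

The per-system event rate is independent of the lipid count — flips arrive
as a per-system Poisson process — so rate-protocol tests run 16 lipids per
leaflet while keeping the protocol conditions themselves (two replicas of
10 µs, 1 ns stride, 2 µs discard, 1 µs bins) at their stated values.
Thinning recovery uses 256 lipids per leaflet: the bulk thickness is
defined over *all* lipids, so the proximal (thinned) annulus must be a
small area fraction for the bulk FWHM to be unbiased; at 256 lipids per
leaflet the annulus is ~4% of the membrane and an imposed 0.3 nm thinning
is recovered well within 0.05 nm. Pathway tests use 36 lipids per leaflet
around a pore protein, which yields tens of guided transits in 1 µs at
15 events/µs.

## Known limitations

* XTC/TRR trajectories are not read; use GRO, multi-model PDB or DCD
  (convert with standard MD tooling if needed).
* Frames are held in memory per replica; extremely long high-resolution
  trajectories should be strided on conversion.
* Thickness is a 1D (z-profile) measure near the protein, not an
  xy-resolved thickness map; curvature and area-per-lipid analyses are out
  of scope.
* The FWHM thickness convention differs by a smearing-dependent constant
  from head-to-head or phosphate-peak distances; *differences* (thinning)
  are insensitive to that constant, absolute values are convention-bound.
```{r example}
spec <- synthetic_spec(n_lipids_per_leaflet = 16, duration_ns = 4000,
                       n_replicas = 2, flip_rate = 3, seed = 7)
sim <- simulate_bilayer(spec, mode = "angles")
ev <- do.call(rbind, lapply(sim$traces, function(tr)
  detect_events(tr, sim$ledger$leaflets)$events))
bins <- bin_events(ev, t_end_ns = c(`0` = 4000, `1` = 4000),
                   equilibration_ns = 2000)
summarize_rates(bins)
```
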