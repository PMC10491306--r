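# scramblescan

Quantify lipid scrambling by membrane proteins in coarse-grained (CG)
molecular dynamics trajectories.

Lipid scramblases — and, as has recently become clear, many protein
insertases — let phospholipids cross between the two leaflets of a bilayer
by offering a hydrophilic path through the hydrophobic membrane core (the
"credit-card" mechanism). In Martini-style CG simulations a lipid's leaflet
can be followed through the angle *θ* between its tail→head vector and the
membrane normal (z): lipids in the upper leaflet sit at *θ* ≈ 0°, lipids in
the lower leaflet at *θ* ≈ 180°. `scramblescan` implements the full
quantification protocol around that observable:

- **Event detection.** Per-lipid orientation angles are sampled every 1 ns
  from the vectors C4A→NC3 and C4B→NC3 (Martini 3 DOPC naming; fully
  configurable). A buffered two-threshold state machine counts a scrambling
  event only when a lipid from the upper leaflet passes *θ* > 125°, or a
  lipid from the lower leaflet passes *θ* < 55°. The 55–125° band is a
  buffer: occupancy there never changes leaflet state, so angular noise
  cannot be double-counted (hysteresis).
- **Rate statistics.** The first 2 µs of each replica are discarded; events
  are counted in 1 µs bins and pooled over replicates (two 10 µs replicas
  give 16 data points per system). Boxplot statistics are computed and the
  system is classified as a **SCRAMBLER** when the mean rate reaches the
  cut-off of 1 event/µs.
- **Membrane thinning.** The hydrophobic thickness (full width at half
  maximum of the z-density of lipid beads excluding NC3/PO4, midplane
  referenced, sampled every 5 ns) is compared between lipids within 1 nm of
  the protein and the bulk bilayer.
- **Pathway mapping.** For each event, the headgroup positions across the
  buffer transit are mapped onto protein residues within 0.6 nm, localising
  the scrambling pathway; the transit point cloud is exported as a PDB.
- **Synthetic ground truth.** A kinematic bilayer generator produces
  GRO-format trajectories of pseudo-DOPC lipids with Poisson flip-flop at a
  known rate, a ground-truth event ledger, an optional cylindrical
  pseudo-protein with a known pore lining, and an imposed local thinning —
  so every stage of the pipeline is testable without running MD.

Input formats: GRO or PDB topologies; GRO (multi-frame), PDB (multi-model)
or DCD trajectories. Units are nm and ns throughout.

## Worked example

Simulate a scrambling system with known ground truth, then quantify it:

```r
library(scramblescan)

spec <- synthetic_spec(n_lipids_per_leaflet = 16, duration_ns = 10000,
                       n_replicas = 2, flip_rate = 5, seed = 1001)
sim <- simulate_bilayer(spec)
sel <- select_lipids(sim$topology, "DOPC", "NC3", c("C4A", "C4B"))

events <- do.call(rbind, lapply(sim$trajectories, function(tr) {
  leaf <- assign_initial_leaflets(get_frame(tr, 1), sel)
  detect_events(build_traces(tr, sel, stride_ns = 1), leaf)$events
}))
bins <- bin_events(events, t_end_ns = c(`0` = 10000, `1` = 10000))
summarize_rates(bins)
#> rate_summary: SCRAMBLER (mean 4.56 events/us over 16 points, cutoff 1)
#>   median 4  q1 3  q3 5.5  whiskers [1, 9]  range [1, 9]

match_events(sim$ledger, events, tolerance_ns = 1)$recall
#> [1] 1
```

The summary says: after the 2 µs discard, the two replicas contribute 16
one-microsecond bins whose mean count (4.56 events/µs) is above the 1
event/µs cut-off, so the system is classified a scrambler; every
ground-truth flip in the generator's ledger was recovered by the detector at
the correct time (recall 1).

File-based analyses use the same functions through a YAML config
(`run_scrambling()`, `run_thickness()`, `run_pathway()`), or the shipped
command-line script:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/scramblescan.R", package = "scramblescan"))')" \
    scramble --topology topology.gro --trajectories rep0.gro,rep1.gro --out results/
```

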