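# nucleoidwalk

Lattice Monte-Carlo models of bacterial chromosome organization.

Imaging of tagged loci in *Caulobacter crescentus* shows a striking linear
correlation between where a gene sits on the chromosomal map and where it
sits along the cell axis, with *ori* and *ter* at opposite poles.
`nucleoidwalk` implements a purely geometrical explanation of this
ordering and makes it quantitative: the chromosome is a random walk on a
cubic lattice confined to the cell volume, with one or two loci pinned to
fixed subcellular positions. Non-compacted DNA is a *non-self-avoiding*
walk with one Kuhn length `b` per bond (the *ori*–*ter* half of a 1.3 mm
chromosome is a 13000-step bridge in an 11×11×41 box); DNA compacted into
topological domains ("blobs" of diameter `d`) is a *self-avoiding* chain
of ~2000 blobs. Ensembles with fixed length and pinned loci are built by
hook-insertion growth and sampled with the Madras–Orlitsky–Shepp (MOS)
move set — bead flips, crankshafts and an atomic 3-D crankshaft
rebridging — which has the uniform distribution as its stationary law.

The package is aimed at people modelling nucleoid geometry: it provides
the simulator, *exact* oracles for validation (exhaustive enumeration on
small instances; transfer-matrix profiles and an independent-draw bridge
sampler for confined non-self-avoiding chains at full chromosome scale),
the ordering statistics used in the field — axial mean-position profiles
⟨z(s)⟩ with inter-cell standard deviations, RMS deviation from the linear
arrangement, plateau onset, per-arm correlation-sign fractions, occupation
densities, two-chromosome demixing — and named presets for the simulated
*C. crescentus* and *E. coli* experiments (wild type, free-*ter*,
*ter*-relocation mutant, newborn/pre-division/replicating cells, daughter
strand, midcell anchor variants) plus blob-ensemble and cell-geometry
sweeps.

## A worked example

The fictive mutant whose *ter* is moved from 12 to 3 o'clock on the
chromosomal map (arms of 1500 and 500 blobs between the polar anchors):

```r
library(nucleoidwalk)
set.seed(101)

mutant <- build_scenario(preset("caulo_mutant_ter3"))
mutant
#> <lattice_walk closed SAW: 2000 beads, 2000 bonds, 2 pin(s), box 11x11x41>

prof <- mos_profile(mutant, n_samples = 600, burn_in = 4e6, thinning = 4000)
correlation_sign_fractions(prof)
#> positive_fraction negative_fraction
#>              0.75              0.25

linearity_report(prof)
#> <linearity_report: rms 3.314, anchors 2.0/38.0, plateau onset 615, fractions 0.75/0.25>
```

Read: 75% of the chromosome (the 1500-blob *ori*→*ter* arm) moves *away*
from the *ori* pole as you walk the map — a positive correlation between
contour and axial position — and 25% moves back; the mean configuration is
nearly linear (RMS 3.3 lattice units from the ideal straight arrangement,
anchors at z = 2 and 38 of 40). Compare the non-compacted chromosome,
where the exact bridge machinery shows the mean position just sits at
midcell for ~90% of the contour:

```r
set.seed(1)
b <- preset("caulo_bare_bridge_4b")   # 13000 Kuhn segments, pins z = 4/36
p <- sample_bridges(b$box, b$pin_sites[1, ], b$pin_sites[2, ],
                    b$walk_length, n_samples = 1e4)
plateau_onset(p, tol = 0.5)
#> [1] 1294
```

Only compaction (fewer, thicker segments) makes the linear arrangement
possible — that contrast is the package's central result.

A thin command-line driver wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/nucleoidwalk.R", package="nucleoidwalk"))') \
    run --preset caulo_blob_wt --samples 500 --seed 7 --out results/wt
```

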