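---
title: "Geometrical lattice models of bacterial chromosome organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometrical lattice models of bacterial chromosome organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoidwalk)
```

## The model

Fluorescence-tagging experiments in *Caulobacter crescentus* show a strong
linear correlation between the position of a gene on the chromosomal map and
its average position along the cell axis, with the replication origin
(*ori*) and terminus (*ter*) at opposite poles. `nucleoidwalk` implements a
purely geometrical explanation: no motors or tracking machinery, only

* a chromosome of fixed contour length,
* confinement to the cellular volume,
* one or two loci (*ori*, possibly *ter*) held at fixed subcellular
  positions, and
* optionally, compaction of the DNA into "blobs" (topological domains
  organised by nucleoid-associated proteins), which makes the chain
  effectively short and thick enough that excluded volume matters.

The cell is a rectangular box of lattice sites
$\{0..n_x-1\}\times\{0..n_y-1\}\times\{0..n_z-1\}$, the $z$ axis being the
pole-to-pole cell axis; a cell of axial length $H$ bond units has $n_z=H+1$
site rows, and the wall-adjacent rows are $z=0$ and $z=H$. Pin positions
such as "distance $4b$ from the wall" therefore map to the row $z=4$.

Two parameterisations share this machinery:

* **Non-compacted DNA.** One lattice bond is one Kuhn length $b$ (twice the
  persistence length; default $b = 50\,$nm, absorbing the *in vivo*
  softening of DNA by supercoiling and architectural proteins). DNA is
  $\sim2\,$nm thick — far thinner than $b$ — so the walk is *not*
  self-avoiding: a site may be visited repeatedly. A *C. crescentus*
  chromosome of 1.3 mm maps to 26000 bonds in an $11\times11\times41$ box
  ($H=40$); the *ori*–*ter* segment alone (all that is needed for a
  non-self-avoiding chain, by symmetry of the two arms) is a 13000-step
  *bridge* with both endpoints pinned.
* **Compacted DNA.** One bond is one blob diameter $d$; each blob holds a
  fixed amount of DNA (a protein-organised loop, further condensed by
  supercoiling). Since a blob is an extended object the chain of blobs is
  **self-avoiding**. The default is $N = 2000$ blobs with $d$ chosen so the
  *C. crescentus* cell is 40 blob diameters long ($d = 50\,$nm for a
  2.0 µm cell).

The ensemble is athermal and uniform: every configuration satisfying the
constraints (length, pins, box, excluded volume) has equal weight. All
reported statistics are ensemble averages, e.g. the axial profile
$\langle z(s)\rangle$ and its inter-configuration standard deviation
$\sigma(s)$ as functions of the contour coordinate $s$ (in bonds, $s=0$ at
*ori*).

## Constructing a starting configuration

Sampling needs one constraint-satisfying configuration to start from:

1. **Minimal loop.** A closed chain through the pins starts from the
   smallest rectangular self-avoiding loop through them: two monotone
   staircases, with a one-unit lateral detour when the pins are collinear
   (`minimal_loop()`). Open bridges start from the canonical monotone
   staircase (`bridge_init()`).
2. **Hook growth.** The chain is lengthened two bonds at a time by *hook
   insertion*: a uniformly chosen bond is displaced one lattice unit in a
   uniformly chosen perpendicular direction, adding the two displaced sites
   as new beads (`hook_step()`, `grow_walk()`). If either site is outside
   the box or (self-avoiding case) occupied, the attempt is rejected and
   the walk is unchanged. Growth therefore preserves every invariant at
   every intermediate step, and the achievable lengths from a seed are
   exactly `seed + 2k` — a target of the wrong parity is raised by one bond
   with a warning (a discretisation error of one part in $L$).

Because pins delimit contour *segments*, growth targets are per segment:
this is how the chromosomal-map position of *ter* is encoded (wild type:
arms 1000/1000 blobs; the *ter*-relocation mutant: 1500/500).

## Sampling: the MOS move set

Fixed-length, fixed-endpoint ensembles are sampled with local moves in the
style of Madras, Orlitsky and Shepp:

* **bead flip** — a 90° corner bead jumps to the opposite corner of its
  unit square (the two adjacent step symbols swap);
* **crankshaft** — the two interior beads of a 3-bond U-segment
  (steps $a,b,-a$, $a\perp b$) rotate about the chord into one of the 3
  alternative perpendicular placements, chosen uniformly;
* **3-D crankshaft** — an atomic *rebridging* of a 3-bond window: the two
  interior beads are replaced by one of the alternative 3-step lattice
  paths between the window's (fixed) end beads, chosen uniformly. This is
  the composite that injects step symbols absent from the current chain —
  e.g. it gives a walk confined to the $xz$ plane its first $\pm y$ bond —
  which flips and plain crankshafts cannot always do.

A proposal picks a contour index uniformly, a move kind by the mixture
weights (default 0.6/0.3/0.1; the uniformity tests pass for any mixture),
and rejects when the move is inapplicable, would displace a pinned bead,
leave the box, or violate excluded volume. Each kernel is *symmetric*: the
number of alternatives depends only on quantities the move conserves (the
corner geometry, the U chord, the window's endpoint displacement), so
acceptance-by-constraint has the uniform distribution as its stationary
law. The design choice to realise the 3-D composite as a window rebridge —
rather than a literal sequence of two crankshafts and two flips — was made
because the rebridge is manifestly symmetric and atomic (all-or-nothing
constraint checks), while a literal move sequence would need careful
bookkeeping to keep the proposal reversible; the test suite verifies by
breadth-first search over enumerated state spaces that the rebridge reaches
everything the composite would.

Counting convention: "moves" are *attempted* proposals. Defaults are
`burn_in = 100 L` and `thinning = max(L, 1000)` attempted moves for a chain
of $L$ bonds; acceptance statistics are always returned.

### Ergodicity and its limits

On every enumerable instance we test, the move graph is connected for
**open bridges** (self-avoiding or not) and for **closed chains pinned at a
single bead**. For **closed chains with two pinned beads** small instances
exist whose state space splits into several components under these local
moves (the tests construct one deliberately). Two consequences, stated
plainly:

* the sampler is exactly uniform *on the component of its starting
  configuration*;
* ensemble averages over the full constraint set can be slightly biased
  for two-pin closed chains. On the tiny instances where exhaustive
  enumeration is available the package quantifies this instead of
  eyeballing it; at chromosome scale (2000 blobs in a $11\times11\times41$
  box) the arms are long and the effect is believed small, but it is a
  known limitation of local-move sampling, not an implementation accident.

### Mixing, and when to use the exact sampler instead

Local moves displace one or two beads at a time, so the slowest collective
modes relax in $O(N^2)$ sweeps (Rouse-like scaling). For the 13000-bond
non-compacted bridge that is far beyond any sensible budget: a
Markov-chain run of modest length retains a visible memory of its initial
staircase. For **non-self-avoiding** chains this package therefore provides
an exact alternative built on transfer (dynamic-programming) propagation
over the box graph:

* `exact_bridge_profile()` — the *exact* $\langle z(s)\rangle$ and
  $\sigma(s)$ of the confined bridge, by forward/backward count vectors
  (checkpointed, so memory stays modest at chromosome scale);
* `sample_bridges()` — *independent* exact draws from the uniform bridge
  ensemble, by sequential sampling from the backward conditionals.

Both are validated to machine precision against exhaustive enumeration on
small boxes. The MOS sampler remains the tool for self-avoiding (blob)
chains, where no polynomial exact method exists; its blob-scale
observables of interest here (correlation signs of whole arms, arm
symmetry) are far more forgiving of slow modes than a per-step mean, and
the acceptance checks estimate Monte-Carlo error from independent
replicate chains rather than from naive per-sample standard errors.

## Observables

* `axial_profile()` — $\langle z(s)\rangle$, $\sigma(s)$; pinned indices
  have $\sigma=0$ exactly.
* `linear_reference()` / `rms_from_linear()` — the idealised straight
  arrangement between the anchors (a piecewise-linear tent for circular
  chromosomes) and the contour-averaged RMS deviation of the mean profile
  from it. Closed forms used as test oracles: an exactly linear profile
  gives 0; a constant mid-plane profile against a $0\to H$ ramp gives
  $H\sqrt{(1+2/L)/12} \to H/\sqrt{12}$.
* `plateau_onset()` — the first contour step whose mean position is within
  `tol` of the cell midplane. The default `tol = 0.5` lattice units means
  "within half a bond of midcell". Because the approach to the plateau is
  exponential, the onset depends logarithmically on `tol`: tightening the
  tolerance moves the onset out roughly linearly in $-\log$ `tol`, so any
  comparison of onsets must fix the tolerance first. The acceptance
  machinery reports the default-tolerance onset together with a
  `tol`-scan over $[0.25, 1.0]$.
* `correlation_sign_fractions()` — per contour segment (chromosome arm),
  the sign of the Pearson correlation between $\langle z(s)\rangle$ and
  $s$; reported as contour fractions. The population-average framing is
  deliberate: the sign is taken on the ensemble-mean profile, matching how
  the imaging experiments average over many cells.
* `radial_density()` — mean per-site occupation (sums to the bead count;
  pinned sites are exactly 1).
* `demixing_score()` — the overlap coefficient
  $\sum_z \min(p_1(z), p_2(z))$ of the two chromosome halves' normalised
  axial occupation histograms: 0 = fully demixed, 1 = identical. The
  underlying experiments only gesture at demixing via position spreads;
  the overlap coefficient is this package's explicit operationalisation.

## Scenario presets and parameter choices

`preset()` encodes each simulated experiment; `to_lattice()` maps physical
parameters (genome size, $b$ or $d$, cell dimensions, anchor fractions) to
lattice specs, and `ensemble_sweep()` generates the two blob ensembles —
(i) constant DNA density per blob ($N \propto d^{-3}$, box $\propto
d^{-1}$) and (ii) constant blob count ($N=2000$, $d$ varies) — plus
cell-length and blob-number sweeps.

Several published geometry values are typeset as figures in the source
material and are not recoverable as numbers; the package fixes documented
defaults and exposes every one of them as a parameter:

* cross sections: square, `round(width / bond) + 1` sites, with cell width
  0.5 µm (*C. crescentus*) and 0.85 µm (newborn *E. coli*);
* anchor heights: fractions 0.05/0.95 of the cell length for polar pins
  (the experimental *ori*/*ter* distances from the poles are visibly
  nonzero); midcell variants use 0.4/0.6, 0.5, or equal heights at
  different $x$ for the left-*ori*-right geometry;
* pre-division *E. coli*: the two chromosomes are one open chain of twice
  the length; the two *ter* occupy *adjacent* midplane sites (excluded
  volume forbids coincidence), contributing one extra bond between the
  2000-blob halves;
* the daughter-strand scenario anchors a half-length strand at two
  midplane sites two lattice units from the mother's axis, with mutual
  exclusion between the chains.

If a requested anchor height is incompatible with the arm-length parity
forced by the lattice (an arm of even length cannot join sites an odd
Manhattan distance apart), the *ter* height is nudged one lattice unit —
an error of at most one bond unit, always reported in the returned spec.

## Numerical conventions

* Coordinates are 0-based; boxes are half-open integer products.
* Closed walks store one bead per bond; the closure bond is implicit.
* Pins are contour indices into the bead sequence, so they survive any
  move without positional search; pinned beads are simply never proposed
  targets.
* Occupancy is a dense integer-count grid (counts, so non-self-avoiding
  multiplicity is representable), making hook rejection and excluded
  volume checks O(1).
* All randomness flows through R's RNG: `set.seed()` (or the `seed`
  argument / `--seed` flag) makes growth, sampling and the exact bridge
  sampler reproducible bit for bit.
* Exhaustive enumeration is depth-first with Manhattan-distance and
  parity pruning toward the next pinned bead and a configurable state cap
  (default $10^7$).

## Problem sizes used by the test suite

The suite validates each claim at the smallest scale that exercises it:
enumeration oracles on $\le 3\times3\times5$ boxes and $\le 10$ bonds
(hundreds to thousands of states); uniformity of the sampler against
enumerated state lists with $10^4$–$10^5$ retained samples; the mutant and
wild-type blob chromosomes at full scale (2000 blobs, $11\times11\times41$
box) with hundreds of decorrelated samples and replicate chains for error
estimation; the non-compacted bridge at full scale (13000 bonds) through
the exact transfer-matrix machinery and $10^4$ independent draws.

## Known limitations

* Local-move sampling of two-pin closed chains can be confined to a state
  component (above); the package reports, rather than hides, the small
  discrepancies this produces against exact enumeration.
* Replication forks cannot move during sampling: a fork site shared by
  mother and daughter strands would have to be transformed while keeping
  both chains connected and self-avoiding, which this move set does not
  support. Scenarios represent before/after snapshots instead.
* Cell curvature (the crescent shape) is not modelled; boxes are straight.
* The blob picture collapses all sub-blob structure: supercoiling and
  protein binding enter only through the effective parameters $b$, $d$,
  $N$.
* The synthetic scenarios emulate pinned loci and confinement only; real
  nucleoids have transertion, replication and division dynamics that no
  equilibrium ensemble captures. Passing tests therefore validate the
  geometrical mechanism, not a full account of nucleoid biology.
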