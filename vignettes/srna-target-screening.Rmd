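---
title: "Accessibility-aware sRNA target screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility-aware sRNA target screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific models inside `srnascreen`, the
parameters that matter, the design decisions that were genuinely open, and
what the synthetic benchmark does and does not demonstrate.

# The screening procedure

The screen nominates direct targets of a small regulatory RNA from an
expression contrast. Genes changing at least `fold_threshold` (default 3,
boundary-inclusive, in either direction; `max(fc, 1/fc) >= 3`) are
candidates; for operon members the rank-1 ORF is added, because regulation
of a polycistronic mRNA acts through its shared 5' end. Each candidate's
search region is the full 5'UTR plus 100 nt of CDS when the TSS is known,
else 200 nt upstream of the translation start plus 100 nt of CDS.

Within the region, the sRNA-mRNA interaction is predicted by a duplex
dynamic program (below) requiring a seed of 8 consecutive base pairs, and
scored with the accessibility-corrected total energy

$$E_\mathrm{total} = E_\mathrm{hybrid} + ED_\mathrm{sRNA} + ED_\mathrm{mRNA},
\qquad ED = -RT \ln P_u,$$

where $P_u$ is the probability that the paired interval is free of
intramolecular pairs in the thermodynamic ensemble of its own molecule.

Down-regulated candidates become repression calls when a reported site
intersects the ribosome-covered region $[-39, +19]$ around the translation
start (+1 is the first start-codon nucleotide; there is no position 0).
Up-regulated candidates become activation calls when the best site strictly
upstream of the RBS raises the RBS unpaired probability by more than
`dpu_threshold` (default 0.001); the bound state is modelled as constrained
folding with the site's positions forced single-stranded, the standard
occupancy proxy. RBS positions come from an anti-Shine-Dalgarno scan:
the minimum duplex energy between the anti-SD sequence (default `CCUCCU`)
and the window $[-20, -4]$, with a 4-pair seed and a significance threshold
of $-3.5$ kcal/mol. The underlying genome-scale RBS predictor used in the
original screen is not described in reusable detail, so this module defines
a transparent hybridization-energy scan with the same role (positioned,
significance-flagged calls); whether the original used hybridization
energies or a position-weight model is unknown.

# The energy model

All folding and hybridization use one self-contained nearest-neighbour
parameterization (`energy_model()`): a symmetric stacking table derived
from per-pair-type strengths (GC/CG 3.3, AU/UA 2.2, GU/UG 1.1 kcal/mol;
a stack of pairs $p, q$ costs $-(s_p + s_q)/2$), affine hairpin
($5.0 + 0.3\,(\ell - 3)$), interior ($1.8 + 0.4\,(\ell_1+\ell_2)$) and bulge
($3.2 + 0.4\,(\ell - 1)$) penalties, a duplex initiation penalty of
4.1 kcal/mol, and $RT = 0.0019872 \times T$ with $T = 310.15$ K. Multiloops
and exterior bases are free; hairpin loops shorter than 3 nt are forbidden;
lonely pairs are allowed; pseudoknots are excluded. Published
nearest-neighbour tables are third-party data sets with their own
licensing and versioning; the pipeline's logic is independent of the exact
numbers, so the package ships this documented table (magnitudes in the
range of measured stacks) and accepts any alternative via the
`energy_model()` arguments. Consequently, absolute energies printed by this
package are not comparable to values computed with other parameter sets;
ranks and the screening logic are.

# Intramolecular ensembles and accessibility

`partition_function()` implements the inside algorithm over nested
structures with a base-pair span cap (span $= j - i + 1 \le$ `max_span`)
and forced-unpaired constraints; pair probabilities come from the
corresponding outside recursion. $P_u$ of an interval is computed exactly
as a ratio of constrained to unconstrained partition functions, which makes
the interval-monotonicity property ($P_u$ of an interval never exceeds that
of a sub-interval) hold by construction. Computations are done in double
precision; at the 100-nt window scale used throughout, Boltzmann sums stay
far from overflow, and the enumeration oracle agrees to ~1e-12 relative
(asserted at 1e-9 in the tests).

Local folding follows the windowed convention: 100-nt windows, 50-nt
maximal span. Two window placements are implemented. The profile function
`local_accessibility_profile()` averages $P_u$ over every full window
containing the probed interval (windows slide by 1 nt; a sequence shorter
than the window is folded as one truncated window — padding would invent
sequence). Screening-stage site queries default to a single window centred
on the queried interval (`window_mode = "center"`), the RNAup-style
convention for site-level opening energies; the averaged mode remains
available via `window_mode = "average"`. Which placement the original
procedure used is not stated; centred evaluation was chosen as the default
because a site's opening energy is a property of the locally refolded
neighbourhood of that site, and the option is exposed for sensitivity
analysis.

# The duplex dynamic program

`hybridize()` minimizes $E_\mathrm{hybrid}$ over antiparallel, non-crossing
intermolecular duplexes with interior/bulge loops of at most 10 unpaired nt
per side and no intramolecular structure inside the site (whose cost is
charged through the $ED$ terms instead). The seed constraint is tracked as
a run-length state: at least `seed` (default 8) consecutive stacked pairs,
GU allowed by default (`seed_gu = FALSE` excludes wobble pairs from the
run, since the seed convention leaves this open). The search is
seed-anchored: maximal complementary runs provide anchors, and the exact
DP runs in a box extending `extension` (default 20) nt beyond each anchor
on both molecules. This keeps interaction sites compact — the site-level
accessibility model presumes a local interaction — and on oracle-scale
inputs the box covers everything, so the tests compare against truly
exhaustive enumeration.

Because minimizing $E_\mathrm{hybrid}$ alone tends to append marginal
helices far from the seed whose gain does not pay their opening cost,
`scan_transcript()` refines each duplex: the pairing is split into stacked
blocks, and the contiguous block range that still contains a seed run and
minimizes $E_\mathrm{total}$ is reported. Sites with non-negative
$E_\mathrm{total}$ are dropped. Non-overlapping ranked sites are produced
by iterative masking (up to `max_sites`, default 3). Tie-breaks everywhere
are deterministic: lower energy, then longer pairing, then leftmost mRNA
start, then smallest sRNA start. Exact energy ties between distinct
co-optimal duplexes are possible with a finite energy alphabet, so oracle
tests assert exact energy equality plus membership in the enumerated
co-optimal set.

The ribosome-window filter uses overlap semantics ("located in the region"
is read as any intersection with $[-39, +19]$), because masking any part of
the initiating ribosome's footprint can block initiation; full containment
is available via `contained = TRUE`. Sites at exactly $-39$ or $+19$ pass;
$-40$ and $+20$ fail. "Upstream of the RBS" means the site's 3'-most mRNA
position lies strictly 5' of the RBS start, which keeps the two branches
disjoint. The activation probe is the RBS interval alone (not RBS plus
start codon); the probe is whatever interval `locate_rbs()` returns, so
extended probes can be studied by changing the scan. No multiple-testing
correction is applied anywhere: the screen is a cascade of pass/fail
filters, matching the procedure it implements.

# The synthetic benchmark

`make_srna()` builds a 191-nt sRNA with three stem-loops (SL1-SL3) and a
39-nt single-stranded linker between SL2 and SL3 — the architecture of the
studied sRNA — plus short leader/spacer/tail segments (the three stem-loops
alone cannot sum to the full length under the 50-nt span cap, so the
connecting segments are explicit). Composition is chosen so the designed
structure is the only structure: the linker is purine-only ({A,G}, runs
capped at 4) and therefore cannot pair internally; stem arms are G/C with
runs capped at 2, so a window-cut arm fragment can form at most a 2-bp
helix with the linker; loops are all-A and connecting segments are C/U,
inert against both the linker and the planted sites. A Shine-Dalgarno-like
purine motif inside the linker provides the anti-RBS tract used by
activation targets. The generator asserts its own contracts: mean linker
$P_u \ge 0.9$ and mean stem-arm $P_u \le 0.3$ under the default model.

`plant_trans_target()` writes the reverse complement of a linker
subsequence into a uniform-random transcript at a controlled
start-codon-relative placement (sites are C/U strings). Sites straddling
the start codon have the AUG re-imposed; the truth record then marks the
exactly-complementary upstream stretch (kept at least `seed + 2` nt).
Activation targets place the site so it covers the anti-RBS tract, which
pairs a planted AGGAGG RBS downstream — the accessibility mechanism is
physically realized, not just labelled.

Uniform backgrounds would defeat truth-scoring: a 191-nt sRNA against a
~300-nt region yields several chance 8-pair seeds per gene (match
probability 6/16 per diagonal cell). The generator therefore sanitizes
every transcript against chance complementarity: antiparallel runs of 7 or
more canonical pairs (wobble included) against the sRNA *and* against the
negative-control sRNA variant are broken by point mutations outside
planted features. For activation genes, two further hygiene steps enforce
the planted mechanism: chance intramolecular partners of RBS nucleotides
are removed (mutating, under the site-open constraint, the
highest-probability partner position until the constrained RBS unpaired
probability reaches 0.25), evaluated against the site the default screen
actually detects, iterated to a fixed point — composite hairpins clipping
single RBS nucleotides, and partners freed only once the detected (possibly
extended) site opens, are invisible to naive motif scans but dominate the
before/after comparison.

The negative control (`srna_mode = "linker_null"`) replaces the linker by a
C homopolymer, mirroring the homopolymer linker-replacement mutant used
experimentally; by the alphabet design it can form no base pair at all with
any planted site, so the expected outcome of the control — zero repression
calls — is structural, not statistical. Expression tables plant the effect
(default 5-fold, against the 3-fold selection threshold) under lognormal
multiplicative noise (`noise_sigma`, default 0.2); the benchmark's default
study conditions are 50 genes with 5 repression targets, 3 activation
targets and 10 off-window decoys. `make_cis_pair()` reproduces the
head-to-head cis-antisense arrangement: a 65-nt 5'-5' overlap with the
antisense gene's TSS 184 nt upstream of its translation start.

What passing these benchmarks shows: the pipeline's logic — selection,
coordinates, folding, duplex search, both classification branches, the
controls — is internally consistent and recovers planted truth exactly.
What it does not show: performance on real transcriptomes, where
accessibility landscapes are not sanitized, chance complementarity is
real, expression noise is not lognormal, and the energy model's absolute
values matter. The false-positive behaviour measured here is conditional
on the generator's hygiene and should not be quoted as an error rate for
real screens.

# Problem sizes and numerics

The test suite and the acceptance script run the full benchmark (50 genes)
plus 20 noisy replicates, 100 enumeration cross-checks of the folding
engine (sequences up to 20 nt, relative tolerance 1e-9), and 120-200
duplex cross-checks (up to 15 nt per strand) — sizes at which the
brute-force oracles are exact and fast. Degenerate inputs are defined, not
errors: empty intervals have $P_u = 1$; an unpairable sequence has $Z = 1$;
$P_u = 0$ marks a site unusable (infinite opening energy) rather than
producing `NaN`; leaderless transcripts (UTR length 0) yield a CDS-only
search region; transcripts shorter than a scan window are scanned
truncated, with a warning.

# Known limitations

* The energy model is simplified (no dangling ends, no coaxial stacking,
  free multiloops, affine loops); absolute energies are not comparable to
  Turner-parameter tools.
* One sRNA, single-contig genomes, and no MFE structure output or
  suboptimal enumeration for users.
* The activation branch evaluates the single best upstream site; multi-site
  cooperativity and kinetics are out of scope.
* Operon structures are required inputs, never inferred; the screening
  direction of an added first-ORF is inherited from the operon member that
  crossed the threshold.
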