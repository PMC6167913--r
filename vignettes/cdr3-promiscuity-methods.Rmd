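---
title: "Methods: profiling CDR-3 loops for binding promiscuity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: profiling CDR-3 loops for binding promiscuity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abloopr)
```

abloopr asks a structural question about antibody binding promiscuity: do
promiscuous antibodies differ from specific ones in the physico-chemical
make-up of their CDR-3 loops and in the secondary-structure behaviour of
those loops over conformational ensembles? This vignette documents the
models and procedures the package implements, the parameters that matter,
and the limits of what its synthetic validation can show.

## CDR-3 extraction and numbering

Full antibody numbering normally requires profile alignment against
germline HMMs. For the third CDR alone, the flanking framework is conserved
enough that anchor motifs suffice, and that is what `extract_cdr3()` does:
the heavy-chain loop is everything strictly between the conserved `C..`
motif (the Cys at Chothia position 92 plus two framework residues,
typically `CAR`) and the J-segment `WG.G` motif; the light-chain loop sits
between the conserved Cys and `FG.G`. The J motif closest to the C-terminus
wins when several match (with a warning), and the last Cys leaving a loop
of at least three residues is taken as the 5' anchor. This is
deterministic and dependency-free; its known failure modes are sequences
whose loop itself spells a J motif (the match then truncates the loop) and
heavily engineered frameworks without the canonical anchors, which raise an
extraction error rather than guessing.

Chothia-style labels are assigned per loop: heavy base positions 95–102
with insertion letters after 100 (…100, 100A, 100B, …, 101, 102), light
base 89–97 with insertions after 95. Loops shorter than the base range drop
numbers outward from the loop centre, mirroring how gaps are placed
centre-out in structural numbering schemes. Labels are presentation-layer
only; all internal coordinates are 0-based half-open.

## Kidera encoding and clustering

Each antibody is represented by the ten Kidera factors — orthogonal,
standardized summaries of 188 physical amino-acid properties — aggregated
over its CDR-H3 and CDR-L3 residues and concatenated (H3 then L3) into a
20-vector. Aggregation is the **per-factor mean** by default. The source
analyses say only that the two regions were "combined"; we chose the mean
because it is invariant to loop length, and CDR-H3 lengths vary by a factor
of two or more within a panel — a sum would let length dominate the
physico-chemistry. `kidera_encode(..., agg = "sum")` provides the
alternative for sensitivity checks.

Clustering is agglomerative (`stats::hclust`) under the Minkowski metric
with order `p = 4`, computed by `stats::dist`. Order 4 accentuates the
largest per-factor discrepancies relative to the Euclidean metric while
remaining a true metric. Linkage is **complete** — the analyses we
re-implement do not state a linkage, and complete linkage is the default of
the clustering software they cite; the choice is recorded in the result
object. Agglomeration ties are broken by `hclust`'s deterministic
lowest-index rule, and the suite verifies the whole procedure against an
exhaustive-scan agglomeration oracle on small instances. Enrichment reports
give, per cluster, the percentage of each phenotype captured (summing to
100% per phenotype) to one decimal.

The packaged Kidera table is embedded as code and checked at load: each
factor must have near-zero mean and near-unit variance over the twenty
amino acids, the construction property of the published table.

## Beta-propensity profiles

Residues are classified on the categorical five-class β-sheet propensity
scale (strong formers {V,I,M}; formers {F,Y,C,T,W,L,Q}; indifferent
{R,G,A,D}; breakers {H,S,K,N,P}; strong breakers {E}). Only the categories
are used — no numeric Chou–Fasman propensities — because the hypothesis
under test is categorical: hairpin-compatible loops keep breakers out of
their stems.

"Stem" and "apex" have no quantitative definition in the source analyses;
we define the apex as the **central third of the loop, rounded outward**
(apex length ≥ ⌈L/3⌉, the N-terminal stem taking the extra position when
the flanks split unevenly), configurable via `apex_frac`. The
`stem_breaker_score()` — breakers plus strong breakers over stem length —
is then a monotone, bounded summary of hairpin compatibility.

## Ensemble secondary structure

`assign_secondary_structure()` implements the Kabsch–Sander hydrogen-bond
algorithm on backbone coordinates. The amide hydrogen, absent from
backbone-only models, is reconstructed 1.01 Å from N anti-parallel to the
preceding carbonyl; the N-terminal residue and prolines donate no bond. A
bond exists where the electrostatic energy
`0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` falls below −0.5
kcal/mol (distances clamped below 0.5 Å to a −9.9 floor). n-turns (n = 3,
4, 5) arise from CO(i)→NH(i+n) bonds; helices (H/G/I) from two consecutive
n-turns; parallel and antiparallel bridges from the classic two-bond
patterns, promoted to strand (E) when bridges stack into ladders;
hydrogen-bonded turn interiors give T, CA-trace bends above 70° give S.
Priority is H > E > B > G > I > T > S > C, and chain termini are never
assigned helix or strand (they lack the bond context; this matches common
practice). Two simplifications relative to full DSSP are deliberate:
β-bulge ladder merging is omitted, and π-helices are detected but not
separately validated. On ideal fixtures the assigner agrees with a
reference DSSP implementation residue-for-residue; the suite requires ≥90%
interior-residue category agreement over ≥20 generated fixtures.

The four reported categories are fixed: {E,B}→Beta, {H,G,I}→Helix,
{T,S}→Turn, {C}→Coil.

Occupancy is the fraction of (frame, residue) observations of a region in
each category, so the four probabilities sum to one by construction.
Confidence intervals come from a seeded percentile bootstrap with **frames
as the resampling unit** (100 resamples, 95% by default): frames are the
independent draws of a conformational ensemble, whereas residues within a
frame are strongly coupled. Group contrasts pool per-frame category
fractions within each group (frames weighted equally, the default; pooling
per antibody first is available by passing one pooled assignment per
antibody), report the relative difference `100·(p_A − p_B)/p_B` against
the reference group, and attach a two-tailed p-value from a 10,000-resample
within-group bootstrap of the difference — a deliberately non-parametric
choice matching the bootstrap flavour of the occupancy intervals. A zero
reference probability leaves the relative difference undefined (`NA`); the
absolute difference is always reported.

## Ensemble PCA and dynamic residues

Frames are superposed by iterated least-squares: each frame is Kabsch-fit
to the current mean over a fit selection, the mean is recomputed, and the
loop runs to an RMS mean-shift below 1e-10 Å (at most 50 iterations),
seeded from the raw coordinate mean so that superposing twice is a no-op to
machine precision. The default fit selection is the stem Cα atoms, so apex
motion is measured relative to the loop scaffold; `"all"` reproduces
whole-structure fitting.

PCA is the eigendecomposition (via SVD) of the Cartesian covariance of the
superposed coordinates about their mean, in nm². No mass weighting is
applied: constraint-sampled ensembles are not dynamical trajectories, so
kinetic-energy weighting has no meaning here. The contribution of atom *a*
to component *k* is defined as `λ_k` times the squared eigenvector mass on
that atom's three coordinates — the axis convention of per-atom eigenvalue
displacement in nm² — so contributions are non-negative and sum exactly to
`λ_k` over the analysed atoms. Residues are ranked by their summed PC1+PC2
contribution; only the first two components are reported by default since
they are the ones dominating the spectrum in this setting.

## The synthetic-data generators

The generators define the package's study conditions and ground truth.

**Sequences.** `generate_antibody_set()` draws paired heavy/light chains
around fixed human-like frameworks whose anchors guarantee extraction. The
default panel is 4 promiscuous and 6 non-promiscuous antibodies with
CDR-H3 lengths uniform on 12–22 — a deliberately long-loop panel, matching
the emulated study's observation that its antibodies carried longer-than-
repertoire CDR-H3s. Promiscuous loops draw stem positions from the strong
formers with probability `stem_former_bias` (default 0.8) and apex
positions from the breakers with probability `apex_breaker_bias` (default
0.7); non-promiscuous loops scatter breakers uniformly (rate 0.4). The
biases are the planted effect size: at their defaults the phenotypes
separate in Kidera space with mean k=3 cluster purity above 0.9, while
values near 0.5 would erase the contrast. Loop alphabets exclude Cys and
reject accidental J-motifs so that extraction is unambiguous.

**Backbones and ensembles.** `build_ideal_backbone()` constructs N/CA/C/O
chains at textbook geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å,
C=O 1.231 Å) from repeating dihedrals: helix (−57°, −47°), strand (−139°,
135°), coil drawn from a generously allowed Ramachandran region, and
hairpin as two antiparallel strands joined by a four-residue
chain-reversing turn with dihedrals (60°, 45°), (60°, −120°), (−90°, 0°),
(−60°, −45°), selected by a design-time search over standard turn rotamers
so that the ideal strands sit in hydrogen-bond register. Because the ideal
strand twist accumulates, register holds for roughly five residue pairs;
longer hairpins fray at the ends, which is physical and shared by the
reference assigner.

`generate_ensemble()` emulates constraint-based conformational sampling
cheaply: per-frame Gaussian perturbation of φ/ψ (default σ = 5°, which
yields ensembles with ~1 Å mean RMSD to the mean structure and partial but
persistent native structure) with the chain rebuilt at the start frame's
exact covalent geometry, so bond lengths are conserved by construction.
Ensembles default to 500 conformers, the per-antibody ensemble size of the
emulated study. An optional planted displacement field (with a seeded
uniform amplitude schedule on [−1, 1]) injects a known collective motion;
afterwards any bond stretched beyond the fractional `constraint_tolerance`
(default 0.05) is repaired by moving single atoms back along the bond, and
an unrepairable bond is an error naming the bond. The planted-mode
recovery experiments use a 0.3 nm apex field over 0.5° noise — chosen so
the planted motion dominates the covariance by construction, which is the
point of a parameter-recovery design: they validate that the PCA machinery
finds a dominant mode that is known to be there, not that real loop
dynamics are this clean.

What the generators do **not** emulate: side chains beyond the sequence
labels (ensembles are backbone-only, with all-Ala rosters), solvation or
packing constraints, correlated dihedral moves, real germline diversity,
or any coupling between a loop's sequence and its ensemble. Consequently a
green test suite demonstrates that the machinery is correct and sensitive
under controlled conditions; it does not by itself establish effect sizes
on real antibody panels, whose headline contrasts depend on the original
sequences and structural models.

## Numerical and degenerate-input choices

* All randomness flows through one explicit integer seed per call
  (`withr::with_seed`); no function touches global RNG state.
* Identical configurations give byte-identical FASTA/PDB output.
* PDB coordinates round to 3 decimals on write; round trips are exact to
  that precision. Model rosters are validated on read and mismatches name
  the offending model.
* Chains shorter than 3 residues are all-Coil; loops shorter than 3
  residues and empty regions are errors, as are zero-length stems in the
  breaker score.
* Bootstrap p-values use the (1 + count)/(1 + B) convention, so they are
  never exactly zero; with the default B = 10,000 the floor is ~2e-4.
* Eigenvalue ties and signs: eigenvectors are reported as returned by the
  SVD (sign-indeterminate); all downstream quantities are sign-invariant.

## Problem sizes

The test suite and acceptance script run on 16-residue loops, ensembles of
40–500 frames, panels of 10 antibodies, 20-replicate purity sweeps and
100-replicate recovery sweeps — sizes chosen so the full validation runs
in about a minute while every assertion still has comfortable margin.
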