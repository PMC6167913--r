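# abloopr

Sequence and conformational profiling of antibody CDR-3 loops in R.

Some antibodies are *promiscuous*: they bind every antigen they are offered
(and even blank wells) rather than a single cognate target. abloopr
implements a reusable, tested pipeline for asking whether that binding
phenotype is written into the third complementarity-determining region of
the heavy chain (CDR-H3) — in its physico-chemical sequence properties and
in the secondary-structure behaviour of its conformational ensembles. It is
aimed at computational immunologists and structural bioinformaticians
working with paired heavy/light variable-region sequences and multi-model
PDB ensembles of loop conformers.

The pipeline has four analytic stages, each usable on its own:

1. **CDR-3 annotation** — anchor-motif extraction of CDR-H3/CDR-L3 (the
   conserved Cys / `WG.G` / `FG.G` anchors), Chothia-style numbering with
   insertion codes (…100, 100A, 100B, …), and loop-length distributions.
2. **Kidera clustering** — each antibody is encoded by the per-factor mean
   of the ten Kidera factors over its CDR-H3 and CDR-L3 residues
   (concatenated to a 20-vector), then clustered agglomeratively under the
   Minkowski metric
   `d_p(x, y) = (Σ_i |x_i − y_i|^p)^{1/p}` with `p = 4`, and cluster ×
   phenotype enrichment is tabulated.
3. **β-propensity and ensemble secondary structure** — loop residues are
   classified by the categorical β-sheet propensity scale (strong formers
   {V,I,M} … strong breakers {E}) and segmented into stems and a
   central-third apex; conformational ensembles are assigned per-residue,
   per-frame secondary structure with a Kabsch–Sander hydrogen-bond model
   (`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5` kcal/mol),
   mapped to Beta/Helix/Turn/Coil, and summarised as occupancies with
   bootstrap confidence intervals and between-group contrasts.
4. **Ensemble PCA** — frames are iteratively superposed (Kabsch fit to the
   converged mean), the Cartesian coordinate covariance is
   eigen-decomposed, and each region atom's contribution to PCk is
   `λ_k · Σ_{d∈{x,y,z}} v_{k,ad}²` (nm²), ranking the maximally dynamic
   residues of the loop.

A seeded synthetic-data module generates labelled antibody-like panels
(promiscuous loops get β-former-rich stems and apex-confined breakers) and
constraint-respecting backbone ensembles with known ground truth (ideal
helices, strands, β-hairpins, coils, optionally with a planted dominant
motion), so every stage is testable against construction.

## Worked example

```r
library(abloopr)

set  <- generate_antibody_set(seq_gen_config(4, 6, seed = 42))
cdrs <- annotate_cdr3(set)
cl   <- cluster_kidera(kidera_encode(cdrs), p = 4, k = 3)
enrichment(cl, set)
#>   cluster phenotype           n pct_of_phenotype pct_of_cluster
#> 1       1 promiscuous         4            100              100
#> 2       1 non_promiscuous     0              0                0
#> 3       2 promiscuous         0              0                0
#> 4       2 non_promiscuous     4             66.7            100
#> 5       3 promiscuous         0              0                0
#> 6       3 non_promiscuous     2             33.3            100
```

Cutting the Minkowski `p = 4` tree at `k = 3` puts all four promiscuous
antibodies in one pure cluster, and 66.7% of the non-promiscuous ones in a
second cluster containing no promiscuous member — the phenotypes separate
in Kidera space. The promiscuous loops carry breaker-free stems:

```r
propensity_profile(cdrs$loop_seq[1])     # YMTMFDPPVVII
stem_breaker_score(propensity_profile(cdrs$loop_seq[1]))
#> [1] 0
```

Ensemble stages run on multi-model PDB files or generated ensembles:

```r
hp  <- build_ideal_backbone("hairpin", 16)
ens <- generate_ensemble(hp, ensemble_gen_config(n_conformers = 500, seed = 7))
ss_occupancy(assign_secondary_structure(ens), seed = 7)
#>   category probability ci_lower ci_upper
#> 1 Beta          0.322    0.306     0.337
#> 2 Helix         0.0325   0.0271    0.039
#> 3 Turn          0.219    0.213     0.224
#> 4 Coil          0.426    0.410     0.441
```

A 500-conformer hairpin ensemble keeps about a third of its (frame,
residue) observations in β structure, with tight frame-bootstrap intervals.
`contrast_groups()` compares two groups of ensembles (e.g. promiscuous vs
non-promiscuous antibodies) and attaches a two-tailed bootstrap p-value to
the category-wise relative difference. For dynamics:

```r
pca <- ensemble_pca(superpose(ens, "stem"))
glance(pca)
#>   n_components total_variance pc1_explained pc12_explained
#> 1          192           1.44         0.463          0.826
head(tidy(project_region(pca, seq_len(nrow(hp$atoms)))), 3)
#>   chain resno resid    pc1    pc2 total rank label
#> 1 H         1 ALA   0.0735 0.0544 0.128     1 1
#> 2 H        16 ALA   0.0916 0.0305 0.122     2 16
#> 3 H         9 ALA   0.0519 0.0683 0.120     3 9
```

The two leading components carry 83% of the ensemble variance; the ranked
residue table localises it to the loop termini (which pivot about the stem
fit) and the apex. Every result type has `tidy()`/`glance()` and
`autoplot()` methods.

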