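---
title: "Evolutionary signatures of intrinsically disordered regions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary signatures of intrinsically disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrsig)
```

## The inference problem

Intrinsically disordered regions (IDRs) diverge so quickly in primary
sequence that conventional alignment-based conservation analysis says little
about their function. Yet an IDR can be under strong selection for *bulk
molecular features* — net charge, charge patterning, composition,
complexity, phosphosite density — even while individual residues turn over
freely. `idrsig` detects such selection by simulating, for each set of
orthologous IDRs, what the orthologs *would* look like if only the local
evolutionary rates and conserved short linear motifs (SLiMs) were
maintained, with no pressure on any bulk feature. Deviations of the real
ortholog set from this null are evidence of selection on the deviating
feature.

For each IDR the pipeline:

1. estimates per-column and local (31-column window) substitution rates and
   a conserved-segment mask on the ortholog alignment;
2. simulates `n = 1000` replicate ortholog sets from the reference sequence
   along the species tree (disorder-specific substitution model, power-law
   indels, mask-protected residues), discarding IDRs with fewer than 950
   fully non-empty replicates;
3. computes 82 molecular features on every real and simulated ortholog, and
   summarizes each feature across orthologs by its **mean** and its
   **natural-log unbiased variance**;
4. scores each feature × statistic cell with a two-tailed empirical p-value
   and a Z-score `(x - mu)/sigma` against the simulated null, giving a
   164-dimensional *evolutionary signature*;
5. filters signatures (at least one `|Z| >= 3`, at least 95% of cells
   present), clusters them with uncentered correlation distance and average
   linkage, and tests clusters for annotation enrichment (hypergeometric +
   Benjamini–Hochberg at FDR 5%, with uniform and composition-matched
   permutation controls using the sum of the top ten `-log10 Q` statistic).

## The null model

### Substitution process

The substitution model is a reversible 20-state CTMC built from stationary
frequencies `pi` and symmetric exchangeabilities `s`:
`q_ab = s_ab pi_b`, normalized to one expected substitution per site per
unit time. The bundled default uses a disorder-like composition (S, N, Q,
D, E, K, P, G, T enriched; aromatics and aliphatics depleted). The
exchangeabilities default to *uniform*: the matrix actually used in the
original analyses of this kind was inferred from closely related yeast
species and is not published as data, so rather than guess at it we ship
the maximally neutral choice (an F81-style model with disordered
composition) and document it. Both `pi` and `s` are plain arguments to
`build_rate_matrix()`; `estimate_stationary_freqs()` derives `pi` (with a
single pseudocount per residue) from any pool of disordered sequences.

Transition kernels `P(t) = exp(Qt)` are computed exactly by symmetric
eigendecomposition and cached per distinct `rate x time` product, so branch
simulation is exact CTMC end-state sampling, not an event-by-event
approximation.

### Indels and mask protection

Insertions and deletions arrive as Poisson processes (default 0.03 events
per residue per unit time each), with lengths from a Zipf law (exponent
1.8, truncated at 50) and inserted residues drawn from `pi`. None of these
constants are published values; they are order-of-magnitude defaults from
protein indel surveys, clearly exposed in `indel_model()`. Conserved-mask
residues substitute at their own (slow) column rate and are **never
deleted**: a deletion overlapping the mask is truncated to its unmasked
flank, and one anchored on a masked residue is dropped. Insertions adjacent
to masked residues are allowed — the mask protects residues, not
junctions. A replicate whose sequence shrinks to length zero at any node is
a legal outcome; it is counted and drives the 950-non-empty filter.

### Rates and the conservation mask

Column rates are maximum-likelihood scalars in `[1e-4, 100]` under the
pruning algorithm, with gaps treated as missing data; local rates are a
centered 31-column moving average. The conserved-segment mask is a
two-state HMM over columns (background at the local rate vs conserved at
`rho x local`, `rho` and transitions fitted by EM with restarts, posterior
threshold 0.5). This is a deliberate simplification of published
phylo-HMMs, which additionally model indels and motif emissions: the
contract here is a conservation mask comparable in *role* to SLiM
predictions, and externally computed masks can be passed straight to the
simulator. Because maximum-likelihood column rates fluctuate, the conserved
state can latch onto estimation noise; the fitted two-state model is
therefore only accepted when it beats the one-state background model by a
BIC-style margin (`1.5 log n` nats for its 3 extra parameters). On
simulated homogeneous alignments this keeps the false masking rate at
essentially zero while planted invariant blocks of 10 columns are
recovered at >= 80% sensitivity.

### Distance calibration

The simulator consumes branch lengths multiplied by a single scale factor
chosen so that the mean patristic distance between two designated
calibration taxa across all region trees equals 1 (`calibrate_scaling()`).
This pins "one unit" of simulated time to a fixed, data-defined divergence
and is exact by construction (the acceptance suite asserts it to 1e-12).

## Signatures

Empirical p-values are two-tailed with an add-one pseudocount:
`p = min(1, 2 min(p_hi, p_lo))` with `p_hi = (1 + #{null >= obs})/(n+1)`.
The add-one form guarantees `p > 0`, makes the floor explicit
(`2/(n+1) ~ 0.002` at 1000 replicates), and is exactly uniform on its
achievable grid under the null — the property the null-calibration
acceptance test checks. Whether the original analysis was one- or
two-tailed is not stated anywhere; two-tailed is the conservative choice
and is fixed here.

Zero across-ortholog variance gives a MISSING log-variance (never
`-Inf`), and a feature whose null distribution is degenerate (zero sd)
gives MISSING Z and p. MISSING cells reduce the signature's `presence` and
are never imputed before the clustering distance (which uses
pairwise-complete dimensions). The signature layout is fixed: the mean-Z
block in catalog order, then the log-variance-Z block.

The chance expectation for "how many features look significant in a null
IDR" treats one uniformly chosen replicate per IDR as the pseudo-real set
and scores it against the remaining replicates, leave-one-out — including
the chosen replicate in its own null would bias p upward. A subtlety worth
stating: on the add-one grid the achievable per-cell rate at `alpha =
0.01` is 0.008, so the chance count has mean close to one *and*
`P(count >= 1)` close to one half. "About one feature by chance" is a
statement about the expectation; the median of single draws is degenerate
between 0 and 1 and is not a stable summary of this distribution.

## The feature catalog

The default catalog has exactly 82 features (so signatures have 164
dimensions). Roughly 35 are named directly in the literature this package
operationalizes: the 20 amino-acid fractions; length; net charge and net
charge with phosphorylation (each `[ST]P` consensus site contributing −2,
a fully ionized phosphate — the per-site charge is configurable); charged /
positive / negative fractions; kappa and Omega charge/proline patterning;
sequence charge decoration (SCD); Wootton–Federhen complexity (entropy
form, base 20, bounded in [0,1]; the multinomial K1 form is a flag);
isoelectric point (Henderson–Hasselbalch bisection under the EMBOSS pKa
set); Kyte–Doolittle hydropathy; proline-directed (`[ST]P`), CDK
(`[ST]P.[KR]`) and CKII (`[ST]..[DE]`) phosphosite densities; FG motif
density; and polyglutamine / polylysine repeat densities.

The remainder of the published 82-feature list lives in supplementary
material that is not reproduced here, so the catalog is padded to 82 with
*documented* variants: residue-group fractions, windowed NCPR and
hydropathy statistics, run-length statistics, patterning blob-size
variants, and a windowed minimum complexity. Padding was chosen to be
**continuous-valued**: features that are almost always exactly zero across
an ortholog set (e.g. rare-residue homopolymer runs) have degenerate
log-variance cells, and a catalog full of them would push nearly every IDR
below the 95%-presence filter — the filter would then measure catalog
degeneracy, not data quality. The catalog is plain data
(`read_catalog_config()` / `write_catalog_config()`), so the exact
published list can be dropped in when available.

Kappa/Omega normalization uses the deterministic fully segregated
arrangement of the same composition (group A block, neutral block, group B
block) rather than a heuristic search; a brute-force enumeration oracle
over all `{E,K,A}` sequences of length <= 8 pins the implementation.
Feature computation has two routes — a per-sequence reference
(`compute_features()`) and a batched C++-backed matrix path
(`feature_matrix()`) — asserted equal cell-for-cell in the tests.

## Clustering and enrichment

Uncentered correlation (no mean-centering, optional dimension weights) is
the distance; items in dense neighbourhoods can be down-weighted with the
classic `1 / sum max(0, 1 - d/cutoff)^exponent` weights (cutoff 0.8,
exponent 1), but the default distance uses uniform weights because the
original tool's weighting semantics when only items are clustered are
ambiguous. UPGMA is implemented in-package with deterministic smallest-
index tie-breaking (an O(n^3) from-scratch reference serves as the test
oracle). The published clusters were picked *manually*; the programmatic
surrogate is a height/k cut with a minimum cluster size (default 15),
leaving small subtrees unassigned (they stay in the enrichment background).

Enrichment uses the hypergeometric upper tail against all proteins in the
clustering, BH-corrected within each cluster (a global-correction flag
exists; the original correction family is unstated), retaining q < 0.05.
The permutation control re-runs the entire enrichment on 1000 same-size
pseudo-clusters — drawn uniformly, or composition-matched by replacing
each member with a uniform draw from its cell in a K = 25 k-means
clustering of composition Z-scores — and summarizes each draw by the sum
of the ten largest `-log10 q` (missing slots contribute 0; q is floored at
machine epsilon before logging). The sequence-similarity control scores
BLOSUM62 global alignments (gap open 0, gap extend 1) transformed to
`d = 1 - S(a,b)/min(S(a,a), S(b,b))` — the transform is this package's
choice; only the matrix and penalties are stated — and reports, per
cluster, the percentage of members with a within-cluster partner inside
the overall top-1% similarity.

## The synthetic world

The generator's defaults state one world: coalescent trees over 16 taxa
rescaled to root-to-tip depth 1 in calibrated units, 100-residue roots
drawn i.i.d. from the disorder composition, 120 IDRs in 3 constraint
classes, planted annotation terms at 60% in-class vs 5% background
coverage. Stabilizing selection (`variance-clamp`) is emulated by
rejection-sampling each branch outcome until the child's feature value
lies within `tolerance x null-sd` of the root value — the inference
question is about the across-ortholog feature distribution, so constraining
outcomes rather than inventing a selection model keeps the null process
untouched. Directional selection (`mean-shift`) cannot be reached by
rejection alone: a 4-sigma shift has acceptance probability near zero, and
the substitution process mean-reverts toward the stationary composition.
It is therefore simulated from a feature-shifted ancestral state (greedy
directed substitutions on the root) with compensatory repair whenever
drift leaves the tolerance window, and the reference species' leaf is
restored to the unshifted root, so the orthologs deviate from a null
re-rooted at the reference — exactly the configuration the signature test
probes. The target compensates the reference leaf's dilution by
`n/(n-1)`.

What a green synthetic test does establish: calibration of the empirical
p-values and Z-scores under the package's own null; power against planted
variance collapse and mean shifts; end-to-end recovery of planted classes
and their annotations. What it does not establish: realism of yeast
composition and codon-level constraints, alignment error, disorder-call
boundary error, or the biological interpretability of real clusters — the
generator never attempts a real GO graph or real ortholog structure.

## Numerical choices and degenerate inputs

- Rate bounds `[1e-4, 100]`; invariant columns sit at the lower bound.
- EM: rho initialized at 0.3 (3 restarts over a 0.05–0.9 grid), transition
  self-probability 0.95, posteriors thresholded at 0.5; seeds logged.
- Bisection for pI to `|charge| < 1e-4` on pH 0–14.
- Distances: pairs sharing < 50% of dimensions get a MISSING distance,
  imputed as the matrix maximum (count reported on the matrix).
- UPGMA ties: smallest `(i, j)`; k-means: fixed seed, 5 starts.
- `filter_ensemble` boundary is exact: 950 of 1000 accepted, 949 rejected;
  all thresholds (30 aa, 10 species, 10 residues, |Z| >= 3, 95% presence,
  q < 0.05, <= 5000 genes) are inclusive/exclusive exactly as printed in
  their sources and asserted at the boundary in the tests.

## Known limitations

- The rate model is a rate-contrast HMM, not a full phylo-HMM with indel
  and motif emissions; masks from richer models can be injected.
- The default exchangeabilities are uniform; with real data, supply a
  matrix inferred from closely related species.
- Ungapped simulated orthologs are compared feature-wise, never
  re-aligned; features must therefore be alignment-free (all 82 are).
- Empirical p-values are not corrected across features within an IDR — the
  significant-feature counts are raw counts at p < 0.01 by design, and the
  chance expectation quantifies exactly what that implies.
- At 1000 replicates the smallest achievable p is ~0.002; claims below
  that resolution are outside the method's reach.
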