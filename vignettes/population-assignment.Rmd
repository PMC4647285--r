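---
title: "Genotype curation, diversity exploration and population assignment with divassign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype curation, diversity exploration and population assignment with divassign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divassign)
```

## The problem

Livestock and wildlife biodiversity studies routinely need to answer two
questions about newly genotyped individuals: *which known populations are
they closest to*, and *what mixture of reference populations best explains
their genome*? `divassign` provides a desk-scale toolkit for this workflow
on diploid biallelic SNP data: format conversion (PLINK text, EIGENSTRAT,
HapMap), marker curation, a quality-filtering cascade, allele sharing
distances, supervised-clustering ancestry estimation, principal component
analysis, and an evaluation protocol that quantifies how reliable
threshold-based assignment is. A seeded simulator generates reference
panels with known structure so every step can be validated end to end.

## Data model

A `genotype_dataset` holds a samples × markers matrix of diploid calls
coded as copies of each marker's *counted* allele (2/1/0, `NA` missing),
plus sample metadata (id, population, project, misidentification flag) and
marker metadata (id, synonyms, chromosome, 1-based position, the two
nucleotide letters). The counted allele of a marker read from a file is
the first allele letter encountered in file order — a deterministic,
frequency-independent convention — so dosages are always interpretable
against the marker table. All genotypes are treated as diploid, including
mitochondrial and sex-chromosome markers; chromosome labels only drive
location-based marker selection (`autosomal`, `sex`, `mitochondrial`).

Marker curation mirrors how chip data are consolidated: markers duplicated
at one (chromosome, position) are merged only when every individual's
non-missing genotypes agree after reconciling the counted-allele
orientation; discordant groups are dropped entirely and reported, never
silently merged. Dropped ids become searchable synonyms of the kept
marker, and dataset merging matches markers by id *or* synonym (one level;
transitive synonym chains across chips are not resolved). Alleles are
reconciled to the reference's counted allele, complementing dosages where
the counted alleles are swapped and flipping strand where letter pairs are
reverse complements; strand-ambiguous A/T and C/G pairs whose letters do
not match the reference directly are dropped, because a strand flip cannot
be told apart from an allele swap there.

## Quality filtering

`run_qc()` applies up to three stages, each optional:

| filter | default | rule |
|---|---|---|
| individual call rate | 0.95 | keep if rate ≥ threshold |
| marker call rate | 0.75 | keep if rate ≥ threshold |
| exact HWE test | P < 0.001 | remove strictly below |
| MAF | < 0.01 | remove strictly below |

The two call-rate stages run individuals-first by default, with the second
stage always computed on the first stage's survivors;
`reverse_call_rate_order` swaps them. The order matters whenever
missingness is concentrated in a few rows or columns, and the package
makes the choice explicit rather than hiding it. Individuals-first is the
default because sample-level failures (bad DNA, swapped plates) are
usually the upstream cause of missingness.

The Hardy-Weinberg filter uses the conditional exact test: given the
observed allele counts, all attainable heterozygote counts are enumerated
(they share the parity of the minor-allele count) and the two-sided
p-value is the total probability of configurations no more probable than
the observed one, computed with the stable neighbour-ratio recurrence. By
default genotype counts are pooled over all selected individuals —
matching how the MAF is computed "over all populations" — which is simple
but inflates rejections in structured data (the Wahlund effect); a
per-population mode is available via `hwe_per_population`.

## Allele sharing distance

For two individuals the per-locus proportion of alleles alike in state is
the multiset intersection of the two allele pairs over 2: identical
homozygotes 1, het vs het 1 (both allele types present at a biallelic
locus), hom vs het 0.5, opposite homozygotes 0. The distance is one minus
the mean over loci genotyped in *both* individuals (pairwise-complete);
the per-pair overlap count is always reported so callers can impose a
stricter floor than the default minimum of one shared locus.
`population_asd_summary()` ranks reference populations by ascending mean
distance (ties by label) and reports the top 5 or 10 with min/mean/max —
the distance-based assignment view.

## Supervised-clustering ancestry

Reference allele frequencies are estimated per population with add-one
(Laplace) smoothing, `f = (y + 1) / (n + 2)` with `y` the counted-allele
copies and `n` the total copies among genotyped individuals. Smoothing
keeps every frequency strictly inside (0, 1), so the likelihood below is
always finite; populations with fewer than 15 individuals (configurable)
are excluded from the panel.

With frequencies held fixed, the probability that an allele copy of query
*j* at locus *m* is the counted allele is `sum_k q_jk f_km`, and the
log-likelihood of the 0/1/2 dosages sums `g log(a) + (2 - g) log(1 - a)`
over non-missing loci. `supervised_em()` maximizes it per query with the
standard fixed-frequency EM update; the update never decreases the
likelihood, and each query stops once its per-iteration log-likelihood
gain falls below `epsilon`. Decisions embedded here, where the convention
was genuinely open:

* `epsilon` is interpreted as the absolute increase in total
  log-likelihood between successive iterations (the usual convention for
  this family of algorithms); presets 0.01, 0.1 and 1 are loose by design
  — supervised likelihoods are well behaved and a loose tolerance buys
  large speedups at a small accuracy cost. Tests confirm estimates at
  `epsilon = 0.01` are never worse than at `epsilon = 1` on the same data.
* Initialization is uniform `q = 1/K`, making runs deterministic; a seeded
  Dirichlet initialization is available behind `em_config(init =
  "random")`.
* Queries are optimized independently (the likelihood factorizes given
  fixed frequencies); missing loci are dropped per query, not imputed.
* `max_iterations` defaults to 10,000 as a safety cap with an explicit
  non-convergence flag.

## Assignment and its evaluation

`assign_populations()` assigns a query to its argmax-ancestry population
iff that maximum strictly exceeds the threshold `t`; exact ties are broken
by population label order and flagged. `rate_curve()` sweeps `t` over a
101-point grid and reports the assignment rate (assigned / all queries,
non-increasing in `t`) and the misassignment rate (wrongly assigned /
assigned, `NA` — never 0 — when nothing is assigned, to avoid flattering
curves). `self_assignment_experiment()` packages the evaluation protocol:
every individual of a labelled dataset is queried against a panel built
from the same dataset, across marker-subset sizes and `epsilon` values.
The evaluated individual stays inside its population's frequency estimate
by default, matching the plain self-assignment design; a leave-one-out
switch exists for the stricter variant.

## PCA

`run_pca()` drops monomorphic and all-missing markers, mean-imputes the
remaining missing calls per marker, centers, and (by default) scales each
marker by `sqrt(p(1-p))` with `p` the counted-allele frequency from the
analysis sample itself — the standard genotype-PCA normalization.
Coordinates are projections on the leading eigenvectors of the sample
covariance; components are defined up to sign. No outlier-removal
iterations are performed. Output follows the familiar evec/eval text
layout so downstream plotting scripts keep working.

## What the simulator emulates — and what it does not

`simulate_reference()` draws population allele frequencies from the
Balding-Nichols model: per marker an ancestral frequency uniform on
[0.05, 0.95], then per population a Beta draw with mean at the ancestral
frequency and variance `F p(1-p)`. This is the minimal model giving an
FST-controlled analog of a structured species-wide panel (a handful of
diverged groups plus admixed populations between them);
`simulate_admixed()` draws each allele copy from a source population
sampled with designed proportions `q*`, so the generative model matches
the estimation model exactly and `q*` is the recoverable truth.

Defaults are the validation study conditions used throughout the tests:
10 populations, F = 0.1, 20 individuals per population, 10,000 markers.
What the simulator deliberately omits: linkage disequilibrium (the
likelihood assumes unlinked loci, so simulating LD would test a different
model), ascertainment bias of real chips, genotyping error, and related
individuals. Passing tests therefore demonstrate correctness of the
algorithms under their own assumptions, not robustness to chip artefacts.

One geometry note: an admixed population mixing exactly two sources lies
*on* the segment between the parental centroids in expectation, not inside
the parental triangle. The structure-recovery test therefore designs its
admixed population as 45/45/10 — a two-way hybrid with a small third
contribution, as real admixed populations typically show — which puts its
centroid strictly inside the triangle and makes the barycentric check
well-posed.

## Numerical choices and degenerate inputs

* HWE probabilities are built in log space from the modal-neighbour
  recurrence and normalized once; the test suite checks equality with a
  direct enumeration oracle to 1e-12 for every genotype table up to 50
  individuals, and that attainable-configuration probabilities sum to 1.
* Ancestry rows are renormalized to the simplex after each EM update to
  absorb float drift (invariant: sum within 1e-9).
* ASD with zero overlapping loci, EM with zero shared markers, and a
  panel with zero qualifying populations are errors, distinct from any
  numeric result; emptying a dataset through call-rate filtering is *not*
  an error (a warning is recorded in the selection summary).
* Comparisons are deliberately asymmetric at the boundary: call-rate keeps
  at the threshold; HWE and MAF remove strictly below theirs.

## A worked example

```{r example}
sim <- simulate_study(
  n_populations = 3, n_per_population = 20, n_markers = 2000, fst = 0.1,
  admixture = list(list(q = c(0.7, 0.3, 0), n = 5)), seed = 42)

panel <- build_reference_panel(sim$reference, min_individuals = 15)
g <- align_to_panel(sim$queries, panel)
res <- supervised_em(g, panel, em_config(epsilon = 0.01))
round(res$q, 3)

out <- assign_populations(res$q, t = 0.5)
table(out$assigned, useNA = "ifany")
```

The recovered ancestries track the designed 0.7/0.3 mixture, and at a
threshold of 0.5 the admixed queries are assigned to their majority
source.

## Problem sizes and limitations

The validation experiments run at 10,000 and ~33,000 markers with 200
individuals and converge in minutes on a single core; the package is
vectorized but pure R, so panels beyond a few hundred thousand markers ×
thousands of individuals are better served by specialized compiled tools.
Other known limitations: no unsupervised admixture (frequencies are never
re-estimated), no linkage-aware model, no standard errors on ancestry
proportions, no VCF ingestion, and HapMap is export-only.
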