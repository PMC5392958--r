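---
title: "Methods: rare-CNV / common-variant convergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-CNV / common-variant convergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-data generator emulates, and the design
choices made where the protocol the package implements was genuinely open.

## 1. The convergence model

The package targets rare complex diseases where two weak lines of genetic
evidence exist side by side: a small set of large, case-only copy-number
variants (CNVs), and a list of candidate genes from a gene-based
common-variant association test. The working hypothesis is *biological
convergence*: if both variant classes perturb one shared process, the
proteins encoded by the two gene sets should interact with each other in
the protein–protein interaction (PPI) network more than random gene sets
of the same sizes do.

The convergence statistic for gene sets $A$ (CNV-affected) and $B$
(common-variant candidates) on PPI graph $G$ is the cross-set
connectivity

$$ T(A,B) \;=\; \#\{\,\{u,v\} \in E(G) : u \in A\setminus B,\, v \in
B\setminus A\,\} \;+\; \#\{\,\{u,v\} \in E(G) : u,v \in A \cap B\,\}, $$

i.e. direct interactions between the exclusive parts of the sets, plus
interactions internal to any shared genes, counted once. Genes absent from
the interactome (non-coding or unmapped symbols) are dropped before
computing $T$, with the dropped count logged. The null distribution is
obtained by redrawing node sets of the same mapped sizes (preserving the
overlap structure) uniformly without replacement from the graph's node
universe, and the reported empirical p uses the add-one rule

$$ p = \frac{1 + \#\{T_{\text{null}} \ge T_{\text{obs}}\}}{n_{\text{perm}} + 1}. $$

Assumptions worth stating: the statistic is unweighted (an interaction
either passed the confidence filter or it did not); the uniform null
treats all interactome genes as exchangeable, which they are not — hub
genes inflate connectivity — so a degree-binned resampler
(`method = "degree_binned"`, degree-decile bins) is provided as a
sensitivity check; and identity of genes across CNV annotation, pathway,
PPI and candidate files is by case-folded symbol string, with no aliasing.

## 2. Parameters, units, defaults

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `min_length` | 100,000 | bp | arrays cannot call small CNVs reliably; the discovery protocol keeps segments ≥ 100 kb |
| `min_probes` | 5 | probes | minimal per-segment evidence |
| `exclusion_overlap_threshold` | 0.5 (strict >) | fraction | MHC/centromere/telomere regions attract spurious calls |
| `novelty_overlap_threshold` | 0.5 (strict >) | fraction | a reference CNV covering more than half the segment, same direction, disqualifies privateness |
| `concordance_fraction` | 0.5 (strict >) | fraction | mutual query-anchored overlap for multi-caller concordance |
| `pad_bp` | 30,000 | bp | dosage effects reach flanking regulatory space; padding applies to the CNV, which has no strand |
| `candidate_eqtl_p_threshold` | 5e-3 (strict <) | p | candidate-selection cut on the per-gene eQTL association p |
| `min_set`, `max_set` | 20, 200 (inclusive) | genes | very small sets are unstable, very large ones uninformative |
| `q_significant`, `q_noteworthy` | 0.05, 0.20 | q | BH-FDR reporting tiers |
| `min_confidence` | 0.01 | score | interactome curation cut; self-loops always removed |
| `n_perm` | 10,000 | draws | resolution of the empirical p (add-one floor 1/10,001) |
| `max_interactors` | 3 | genes | bridge cap per candidate pair, random cut-off beyond it |

Every ">50%" rule is **strict**: a segment lying exactly half inside an
excluded region is retained, and a reference CNV covering exactly half of
a segment leaves it private. Boundary cases therefore resolve in favour of
keeping the case observation.

## 3. Coordinates and file dialects

All internal coordinates are 0-based half-open; length is `end - start`.
BED-like input is native; rawcnv-like input (1-based inclusive loci such
as `1:1000-2000`) is converted on read by `start - 1`, so the stored
length of that locus is 1,001 bp. A single convention everywhere keeps the
overlap-fraction arithmetic free of off-by-one drift, which matters
because three separate rules pivot on exactly 50%. Copy-number state 2
records carry no dosage change and are rejected at parse time (counted,
not erred). Gene symbols are uppercased at every boundary.

## 4. Concordance merging

The discovery protocol requires calls "by all callers" without defining
concordance. The package defines it as: a segment is retained when, for
every other caller, some same-direction segment covers strictly more than
half of it; the consensus segment is the **intersection** of the
supporting calls and its probe support the minimum across supporters.
Rationale: the intersection is the most conservative region all callers
agree on; minimum probes is the weakest supporting evidence; mutual
query-anchored overlap is symmetric and consistent with the pipeline's
other 50% rules. The fraction is exposed (`concordance_fraction`).
QC filters run in a fixed order (length, probes, exclusion regions) purely
for reproducible removal logs; the surviving set is order-independent and
`apply_qc` is idempotent.

## 5. Annotation and enrichment choices

- Padding is applied to CNV boundaries in both genomic directions;
  gene strand is ignored (a dosage change has no strand).
- An exon overlap of ≥ 1 bp counts; there is no minimum-fraction rule.
  A segment whose only overlap with a gene is intronic reports nothing.
- The enrichment universe defaults to the union of genes in the
  size-filtered collection (`universe_policy = "collection_union"`),
  because the protocol never states a universe and p-values depend
  strongly on it; an explicit universe can be supplied
  (`"annotated_genome"`). Query genes outside the universe are dropped
  with a logged count rather than erroring: CNVs routinely hit genes no
  pathway annotates.
- SNP-level pathway enrichment programs synthesize per-SNP statistics;
  the package deliberately replaces this with a documented
  threshold-then-Fisher surrogate (`snp_pathway_surrogate`), and labels
  its output `method = "threshold_fisher_surrogate"`. Cross-method
  comparability of q-values between the two arms is *not* asserted
  anywhere.

## 6. Network analysis choices

- **Empirical p**: add-one with a "≥ observed" tail. The add-one form
  never returns 0 and is conservative; a strict ">" tail is available
  (`tail = "gt"`).
- **Shared genes** (present in both candidate sets) are assigned to the
  CNV set for the cross-set statistic and reported separately; the
  pooled-set test treats the union.
- **Interactor cap**: "at most 3 interactors linking two candidates" is
  read as a cap on the number of single-intermediate bridges (common
  neighbours) per candidate pair, sub-sampled uniformly under the given
  seed when more exist. The alternative reading — path length ≤ 3 — would
  pull in paths with two or three intermediates; it is not implemented
  because bridge counting keeps every included interactor directly
  interpretable (it touches two candidates). Retained interactors keep
  all their edges to included candidates, so a pair may end up visually
  bridged by interactors selected for other pairs.
- **Modules** are found by multi-level modularity maximization (Louvain),
  deterministic under the seed; the protocol named no algorithm (its
  network tool was used for layout only, which this package does not
  compute — networks export to GraphML instead).
- **Centrality**: the source figure never states which centrality its
  node sizes encode, so degree and normalized betweenness are both
  offered; the pipeline reports degree by default.
- **Core–periphery** uses the discrete Borgatti–Everett-style objective:
  maximize the Pearson correlation between the observed adjacency and the
  ideal pattern in which core–core pairs are linked and all other pairs
  are not. The fit is computed in closed form from pair counts, optimized
  by greedy single-label flips from one degree-based start plus random
  restarts (all seeded). Isolates are periphery by definition; graphs
  with < 3 nodes or no edges return fit 0. A result is flagged unstable
  when restarts disagree on the best labeling or the fit is ≤ 0.1 —
  structureless graphs (e.g. cycles) land there.

## 7. Phenotype arithmetic

Prevalence percentages are rounded **half-up** to two decimals
(7/89 → 7.87); R's banker's rounding would disagree on exact ties.
Disease rows count distinct patients; category overalls count distinct
patients with ≥ 1 disease in the category, so multimorbid patients do not
double-count (overall ≤ sum of rows); the cohort overall de-duplicates
across categories. The phenotype and genotype arms may use different
denominators (all phenotyped patients vs patients with confident calls),
so the denominator is always explicit. GPC matching is driven entirely by
a gene–disease evidence file keyed by (gene, disease) — live database
queries are out of scope — and genes with a known association to the
index disease itself are reported in a separate known-genotype list
rather than as comorbidity correlations.

## 8. The synthetic world

The generator's defaults are the cohort conditions the package was
designed around, not tuning knobs:

- 89 phenotyped patients, 42 male; 86 with usable CNV calls;
- the published per-disease comorbidity counts (asthma 7, eczema 9, G6PD
  deficiency 6 — all male — and so on), laid out so that exactly 37
  patients (41.57%) carry ≥ 1 comorbidity, one patient carries both
  allergies, and 11 patients span two categories;
- 29 planted cohort-private CNVs (6 deletions) in 26 carriers, three of
  whom carry two; three planted genotype–phenotype correlations
  (duplications over genes mapped to the carrier's autoimmune/atopic
  comorbidity) and one known-genotype microdeletion in a comorbidity-free
  patient;
- every true CNV is emitted by all three synthetic callers with boundary
  jitter bounded at 10% of segment length per side — below half the 50%
  concordance margin, so all true calls merge — plus one caller-specific
  false positive per caller kept clear of true segments;
- the reference panel covers every non-private true CNV with the
  same-direction interval itself and adds background intervals rejected
  whenever they would cover > 35% of a private plant (a safety margin
  below the 50% rule, since consensus segments can be up to 20% shorter
  than the planted truth).

Where the cohort conditions state nothing, values were chosen once as
realistic for a desk-scale exercise and are documented here: a 4 × 60 Mb
genome with 600 non-overlapping genes of 5 exons (private CNVs of
200–300 kb centred on isolated genes, so each affects exactly one gene —
real CNVs hitting multi-gene clusters are emulated only in aggregate);
a 500-node interactome with Erdős–Rényi background (p = 0.008), four
planted 20-node modules (within-block edge probability 0.6), a 60-node
core of density 0.8 with 0.02 attachment, and a 5× background excess of
edges between the two designated gene sets; 40 pathways of 20–60 genes
with one planted set absorbing 30% of the CNV gene set. The planted core
is drawn from **all** nodes, candidate genes included: disease genes
belong to the interactome core at their population rate, which keeps the
uniform permutation null fair to the planted sets. One shared seed drives
forked substreams per generator, so adding a generator never perturbs the
others, and every emitted file is byte-identical under a fixed seed.

What a green test does and does not establish: recovery of the planted
signals shows the machinery is correct under a world where the planted
effects are strong and clean. It does not establish power or calibration
on real interactomes (scale-free degree distributions, ascertainment
bias in curated PPIs), on CNV calls with platform-specific artifacts, or
on comorbidity registries with coding noise. The permutation calibration
suite covers exchangeable nulls only.

## 9. Numerical notes and degenerate inputs

- Upper-tail Fisher p is computed as `phyper(k - 1, ...)`; zero overlap
  gives p = 1 exactly.
- BH q-values follow the standard step-up with enforced monotonicity;
  output order matches input order.
- The chi-square burden test uses no continuity correction by default; a
  zero margin is an error directing the user to an exact test.
- An empty query gene set is an error in enrichment (nothing to test) but
  an empty *mapped* set in connectivity is an error only when both sets
  vanish.
- `connectivity` permutations and interactor cut-offs are bit-for-bit
  reproducible under fixed seeds; seeds are mandatory arguments in the
  generator.

## 10. Known limitations

- Gene identity is by symbol string; no alias resolution.
- No X/Y chromosomes, no genome-build liftover, no isoform-level
  annotation.
- The connectivity statistic thresholds confidences rather than weighting
  by them.
- Reference panels from different platforms are merged logically into
  "any reference CNV"; platform-specific sensitivity differences are not
  modelled.
- The pooled (internal) connectivity test is reported but is noisier than
  the cross-set test at the default synthetic scale; no acceptance claim
  is attached to it.
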