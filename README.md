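# cnvconverge

Genotype–phenotype convergence analysis for rare copy-number variants in a
small, deeply phenotyped disease cohort.

## The problem

In a rare complex disease, neither the handful of large rare copy-number
variants (CNVs) found in cases nor the candidate genes from a common-variant
association test is individually conclusive. Evidence can still converge:
if the genes whose dosage the case-only CNVs disturb and the common-variant
candidate genes interact with each other in the protein–protein interaction
(PPI) network more than random gene sets of the same sizes do, the two
variant classes plausibly hit one shared pathogenic process. `cnvconverge`
implements that analysis end to end for cohorts of the type it was designed
around — a pediatric cholestatic disease (biliary atresia) cohort of ~90
patients with long clinical follow-up — and ships a fully seeded synthetic
data generator so that every stage can be exercised against planted ground
truth.

The pipeline stages:

1. **CNV discovery and QC** — per sample, only calls made concordantly by
   all three callers are kept (mutual >50% length overlap, same dosage
   direction; the consensus segment is the intersection of the supporting
   calls). Segments must span ≥ 100 kb, be supported by ≥ 5 probes, and
   not fall > 50% inside the MHC or centromere/telomere exclusion zones.
2. **Privatization** — a surviving CNV is *cohort-private* if no reference
   panel CNV of the same direction covers > 50% of its length.
3. **Dosage annotation** — private CNV boundaries are padded ± 30 kb and a
   gene counts as dosage-affected if any exon overlaps the padded interval
   by ≥ 1 bp. The common-variant arm selects candidates with a per-gene
   eQTL association p < 5 × 10⁻³.
4. **Pathway enrichment** — one-sided Fisher (upper-tail hypergeometric)
   tests against a pathway collection restricted to 20–200 genes, with
   Benjamini–Hochberg FDR tiers *q* < 0.05 (significant) and *q* < 0.20
   (noteworthy).
5. **Connectivity** — the convergence statistic is the number of PPI edges
   joining the two gene sets (confidence ≥ 0.01, self-loops removed). Its
   null distribution comes from re-drawing gene sets of the same sizes
   uniformly from the interactome; the empirical p uses the add-one rule
   p = (1 + #{null ≥ observed}) / (n_perm + 1).
6. **Network structure** — a candidate network (direct edges plus at most 3
   bridging interactors per candidate pair, random cut-off, seeded), with
   modularity-based modules, degree/betweenness centrality, a discrete
   Borgatti–Everett-style core–periphery fit, and a module-level meta-node
   graph; exportable to GraphML.
7. **Phenotype** — comorbidity prevalence tables with per-category and
   cohort roll-ups (distinct-patient counting, half-up rounding to two
   decimals), a carrier-burden chi-square test, and genotype–phenotype
   correlation (GPC) matching of each patient's CNV genes against a
   gene–disease evidence map.

## Worked example

```r
library(cnvconverge)

bundle <- generate_synthetic_bundle(synth_config(seed = 7))
res <- run_pipeline(bundle, n_perm = 9999, seed = 8)

res$private_summary
#>   direction n_cnvs n_affected_genes mean_length median_length
#> 1       DEL      6                6    232306.7        236012
#> 2       DUP     23               23    225938.1        226893

print(res$connectivity_cross)
#> PPI cross-connectivity permutation test
#>   observed connections: 161
#>   null mean (sd): 83.23 (21.86) over 9999 permutations [uniform sampling]
#>   empirical p: 0.0025

head(res$cnv_enrichment[, c("pathway", "overlap", "p", "q", "tier")], 1)
#>                  pathway overlap            p           q        tier
#> 1 PATHWAY_PLANTED_IMMUNE       9 4.979989e-05 0.002041795 significant

res$gpc$hits[, c("patient_id", "comorbidity", "gene", "direction")]
#>   patient_id              comorbidity  gene direction
#> 1      BA008    Hashimoto thyroiditis G0213       DUP
#> 2      BA012 Type 1 diabetes mellitus G0235       DUP
#> 3      BA046                   Eczema G0106       DUP
```

Reading the output: the generator planted 29 cohort-private CNVs (6
deletions, 21–23 duplications depending on seed) in 26 of 86 genotyped
patients; the pipeline recovered all of them. The 29 dosage-affected genes
and the 103 common-variant candidates share 161 PPI edges where random
same-size sets share ~83, an excess the permutation test flags at
p = 0.0025. The planted immune pathway ranks first in the enrichment table,
and all three planted genotype–phenotype correlations (a patient whose
duplicated gene is mapped to a comorbidity that patient actually has) are
reported, alongside one known-genotype microdeletion carrier without
comorbidities. The cohort-level comorbidity prevalence (41.57%) and the
carrier-burden chi-square (p ≈ 0.70) reproduce the phenotype arm.

Real data enter through the same `formats_io` readers: BED-like or
rawcnv-like call files, a reference-panel TSV, an exon BED, a GMT pathway
collection, a PPI edge TSV, a candidate-gene TSV and a phenotype CSV
(see `?read_cnv_calls`, `?read_ppi`, `?read_patients`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default synthetic bundle from the given seed, reruns the
entire pipeline from scratch (concordance merging through GPC matching,
with 9,999-permutation connectivity tests), logs the stage summaries to
stderr and writes the JSON report to `--out`.

## Documentation

The methods vignette (`vignettes/convergence-methods.Rmd`) documents the
model assumptions, every tunable threshold, what the synthetic generator
does and does not emulate, and the numerical/design choices.
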