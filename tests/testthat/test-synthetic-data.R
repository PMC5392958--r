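# Generators: determinism, reader compatibility, planted ground truth.

# reduced world for speed: the phenotype arm keeps the full 89-patient
# cohort (its planted counts are fixed), everything else is scaled down
small_cfg <- function(seed = 5) {
  synth_config(seed = seed, n_chromosomes = 2L, n_genes = 240L,
               n_private_cnvs = 8L, n_carriers = 7L, n_private_del = 2L,
               n_common_cnvs_per_patient = 1L,
               n_reference_background = 30L, n_snp_candidates = 25L,
               ppi = list(n_nodes = 150L, background_p = 0.01,
                          module_sizes = rep(12L, 2L), module_p_in = 0.6,
                          core_size = 20L, core_density = 0.8,
                          core_attach_p = 0.02, cross_excess = 5,
                          confidence_range = c(0.01, 1)),
               pathways = list(n_sets = 12L, size_range = c(20L, 40L),
                               planted_overlap = 0.4))
}

test_that("the genome generator is exact and deterministic", {
  cfg <- small_cfg()
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 240L)
  expect_true(all(g1$exons$start >= 0))
  expect_true(all(g1$exons$end <= cfg$chrom_length))
  # genes do not overlap within a chromosome
  for (ch in unique(g1$genes$chrom)) {
    gg <- g1$genes[g1$genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    expect_true(all(diff(gg$start) >= head(gg$end - gg$start, -1)))
  }
  # different seed, different layout
  expect_false(identical(generate_genome(small_cfg(6))$genes$start, g1$genes$start))
})

test_that("every emitted file is readable by its formats reader", {
  cfg <- small_cfg()
  b <- generate_synthetic_bundle(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_bundle(b, dir)

  exons <- read_exons(file.path(dir, "exons.bed"))
  expect_equal(nrow(exons), nrow(b$genome$exons))
  panel <- read_reference_panel(file.path(dir, "reference_panel.tsv"))
  expect_equal(nrow(panel), nrow(b$panel))
  g <- read_ppi(file.path(dir, "ppi.tsv"), min_confidence = 0.01)
  expect_equal(igraph::ecount(g), igraph::ecount(b$ppi$graph))
  gmt <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(length(gmt), length(b$pathways))
  coh <- read_patients(file.path(dir, "phenotypes.csv"))
  expect_equal(nrow(coh$patients), cfg$n_patients)
  cands <- read_gene_table(file.path(dir, "candidates.tsv"))
  expect_equal(nrow(cands), cfg$n_genes)
  one <- list.files(file.path(dir, "calls"), full.names = TRUE)[1]
  expect_gt(nrow(read_cnv_calls(one, "bed_like")), 0)
})

test_that("generators are byte-identical under one seed and differ across seeds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_synthetic_bundle(generate_synthetic_bundle(small_cfg(5)), d1)
  write_synthetic_bundle(generate_synthetic_bundle(small_cfg(5)), d2)
  write_synthetic_bundle(generate_synthetic_bundle(small_cfg(9)), d3)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "reference_panel.tsv")),
                         readLines(file.path(d3, "reference_panel.tsv"))))
})

test_that("caller concordance and privatization recover the planted truth", {
  cfg <- small_cfg()
  b <- generate_synthetic_bundle(cfg)
  truth <- b$truth

  # concordance merging recovers exactly the true per-patient call count
  for (pid in names(b$calls)[1:6]) {
    cons <- merge_concordant(b$calls[[pid]])
    n_true <- sum(truth$private_segments$sample_id == pid) +
      sum(truth$common_segments$sample_id == pid)
    expect_equal(nrow(cons), n_true)
  }

  # no panel interval covers >50% of any planted private CNV (same direction)
  priv <- truth$private_segments
  qc <- qc_config(excluded_regions = b$genome$excluded_regions)
  expect_true(all(is_private(priv, b$panel, qc)))
  # every common CNV is fully covered by a same-direction panel interval
  common_cov <- vapply(seq_len(nrow(truth$common_segments)), function(i) {
    s <- truth$common_segments[i, ]
    same <- b$panel[b$panel$chrom == s$chrom & b$panel$direction == s$direction, ]
    if (!nrow(same)) return(0)
    max(overlap_fraction(s[, c("chrom", "start", "end")], same))
  }, numeric(1))
  expect_true(all(common_cov > 0.5))

  # full recovery through the pipeline path
  res <- run_pipeline(b, n_perm = 99, seed = 11)
  expect_equal(nrow(res$private), nrow(priv))
  expect_setequal(paste(res$private$sample_id, res$private$direction),
                  paste(priv$sample_id, priv$direction))
  expect_setequal(res$gene_set$genes, truth$private_genes)
})

test_that("phenotype planting reproduces the published per-disease counts", {
  b <- generate_synthetic_bundle(synth_config(seed = 3))
  tab <- prevalence_table(b$cohort)
  planted <- b$truth$disease_counts
  got <- merge(tab$rows, planted, by = c("category", "disease"))
  expect_equal(nrow(got), nrow(planted))
  expect_equal(got$n.x, got$n.y)
  expect_equal(tab$overall_n, 37L)
  expect_equal(tab$overall_pct, 41.57)
  # G6PD deficiency is confined to, and frequent in, male patients
  males <- b$cohort$patients$sex == "M"
  expect_equal(sum(males), 42L)
  sp <- subgroup_prevalence(b$cohort, "G6PD deficiency", males)
  expect_equal(sp$n, 6L)
  expect_equal(sp$prevalence_pct, 14.29)
  expect_equal(subgroup_prevalence(b$cohort, "G6PD deficiency", !males)$n, 0L)
})

test_that("pathway and PPI plants carry their designed signals", {
  # the claims below are tied to the generator's DEFAULT effect sizes;
  # a dozen full-size generations keep the runtime tolerable
  bundles <- lapply(1:12, function(s) generate_synthetic_bundle(synth_config(seed = 300 + s)))

  # the planted pathway attains the smallest enrichment p
  wins <- vapply(bundles, function(b) {
    res <- enrich(b$truth$private_genes, b$pathways)
    res$pathway[1] == b$truth$planted_pathway && res$p[1] == min(res$p)
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # strong planted cross-set excess is flagged at p < 0.05 in >= 90% of
  # generations
  flags <- vapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    a <- b$truth$private_genes
    bb <- setdiff(b$truth$candidates, a)
    permutation_p(b$ppi$graph, a, bb, n_perm = 199, seed = i)$empirical_p < 0.05
  }, logical(1))
  expect_gte(mean(flags), 0.9)

  # planted core is recovered with a solid fit at default (full-size) settings
  bfull <- generate_synthetic_bundle(synth_config(seed = 4))
  cp <- core_periphery(bfull$ppi$graph, seed = 1)
  expect_gt(cp$fit, 0.5)
  core_found <- names(cp$labels)[cp$labels == "core"]
  expect_gt(length(intersect(core_found, bfull$truth$ppi$core_nodes)) /
              length(bfull$truth$ppi$core_nodes), 0.8)
})
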