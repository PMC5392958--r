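# End-to-end convergence analysis over a data bundle (synthetic or real
# files loaded through the formats_io readers).

#' Run the full genotype-phenotype convergence pipeline
#'
#' Per patient: merge concordant calls across callers, apply QC, determine
#' cohort-private CNVs against the reference panel. Cohort level: annotate
#' dosage-affected genes, test pathway enrichment of the CNV gene set and
#' of the common-variant candidate set (threshold-Fisher surrogate),
#' select candidates by the eQTL filter, test PPI inter-connectivity
#' (cross-set and pooled permutation tests), build the candidate network
#' with modules, centrality and core-periphery structure, and compute the
#' comorbidity prevalence table, carrier burden test and
#' genotype-phenotype correlation matches.
#'
#' The genes shared by the two candidate sets are assigned to the CNV set
#' for the cross-set statistic and reported in `shared_genes`.
#'
#' @param bundle a list shaped like [generate_synthetic_bundle()] output:
#'   `genome`, `cohort`, `calls`, `panel`, `ppi`, `pathways`,
#'   `candidate_table`, `gene_disease_map`, `known_map`.
#' @param qc a [qc_config()]; default uses the bundle genome's excluded
#'   regions.
#' @param ann an [annotation_config()].
#' @param enr an [enrichment_config()].
#' @param n_perm permutations for the connectivity tests.
#' @param seed seed for permutation tests and the interactor cut-off.
#' @return list of stage outputs (see Details in the vignette).
#' @export
run_pipeline <- function(bundle,
                         qc = qc_config(excluded_regions = bundle$genome$excluded_regions),
                         ann = annotation_config(),
                         enr = enrichment_config(),
                         n_perm = 1000L, seed = 1L) {
  consensus <- do.call(rbind, lapply(bundle$calls, function(views) {
    merge_concordant(views)
  }))
  rownames(consensus) <- NULL
  clean <- apply_qc(consensus, qc)
  private <- clean[is_private(clean, bundle$panel, qc), , drop = FALSE]

  idx <- exon_index(bundle$genome$exons)
  gene_set <- cohort_gene_set(private, idx, pad_bp = ann$pad_bp)
  summary_tab <- summarize_private(private, gene_set$by_direction)

  candidates <- select_candidates_by_eqtl(bundle$candidate_table,
                                          ann$candidate_eqtl_p_threshold)
  shared <- intersect(gene_set$genes, candidates)

  cnv_enrichment <- enrich(gene_set$genes, bundle$pathways, enr)
  snp_enrichment <- snp_pathway_surrogate(
    data.frame(gene = bundle$candidate_table$gene,
               p = bundle$candidate_table$p_eqtl, stringsAsFactors = FALSE),
    bundle$pathways, enr, p_cut = ann$candidate_eqtl_p_threshold)

  graph <- bundle$ppi$graph
  set_a <- gene_set$genes                    # shared genes stay on the CNV side
  set_b <- setdiff(candidates, shared)
  cross <- permutation_p(graph, set_a, set_b, n_perm = n_perm, seed = seed)
  pooled <- permutation_p(graph, union(set_a, set_b), n_perm = n_perm,
                          seed = seed + 1L)

  network <- build_candidate_network(graph, list(cnv = set_a, snp = set_b),
                                     seed = seed)
  modules <- detect_modules(network, seed = seed)
  centrality <- node_centrality(network, "degree")
  cp <- core_periphery(network, seed = seed)

  # phenotype arm: denominator is the full phenotyped cohort
  prev <- prevalence_table(bundle$cohort)
  carriers <- unique(private$sample_id)
  genotyped <- names(bundle$calls)
  comorbid <- unique(bundle$cohort$comorbidities$patient_id)
  in_g <- function(ids) intersect(ids, genotyped)
  with_c <- in_g(comorbid); without_c <- setdiff(genotyped, comorbid)
  burden <- burden_test(
    c(length(intersect(with_c, carriers)), length(setdiff(with_c, carriers))),
    c(length(intersect(without_c, carriers)), length(setdiff(without_c, carriers))))
  gpc <- gpc_match(gene_set$provenance, bundle$cohort,
                   bundle$gene_disease_map, bundle$known_map)

  list(consensus = consensus, qc_passed = clean, private = private,
       private_summary = summary_tab, gene_set = gene_set,
       candidates = candidates, shared_genes = shared,
       cnv_enrichment = cnv_enrichment, snp_enrichment = snp_enrichment,
       connectivity_cross = cross, connectivity_pooled = pooled,
       network = network, modules = modules, centrality = centrality,
       core_periphery = cp, prevalence = prev, burden = burden, gpc = gpc)
}
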