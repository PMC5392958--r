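# Pathway enrichment: size-restricted collections, one-sided Fisher
# (upper-tail hypergeometric) tests, and Benjamini-Hochberg FDR tiers.
#
# The universe defaults to the union of all genes in the size-filtered
# collection because the underlying protocol never states one; enrichment
# p-values depend strongly on this choice, so it is exposed.

#' Enrichment configuration
#'
#' @param min_set,max_set inclusive pathway size bounds (defaults 20, 200).
#' @param q_significant,q_noteworthy FDR q tiers (defaults 0.05, 0.20).
#' @param universe_policy `"collection_union"` (default) or
#'   `"annotated_genome"`; the latter requires an explicit universe vector
#'   at test time.
#' @return a list of class `enrichment_config`.
#' @export
enrichment_config <- function(min_set = 20L, max_set = 200L,
                              q_significant = 0.05, q_noteworthy = 0.20,
                              universe_policy = c("collection_union",
                                                  "annotated_genome")) {
  universe_policy <- match.arg(universe_policy)
  stopifnot(min_set <= max_set, q_significant > 0,
            q_significant <= q_noteworthy, q_noteworthy < 1)
  structure(list(min_set = min_set, max_set = max_set,
                 q_significant = q_significant, q_noteworthy = q_noteworthy,
                 universe_policy = universe_policy),
            class = "enrichment_config")
}

#' Restrict a pathway collection to testable sizes
#'
#' Inclusive bounds: a 20-gene set stays, a 19-gene set goes.
#'
#' @param collection named list of gene-symbol vectors (see [read_gmt()]).
#' @param config an [enrichment_config()].
#' @return the filtered collection (attributes preserved).
#' @export
filter_pathways <- function(collection, config = enrichment_config()) {
  sizes <- lengths(collection)
  out <- collection[sizes >= config$min_set & sizes <= config$max_set]
  attr(out, "source") <- attr(collection, "source")
  out
}

#' One-sided Fisher enrichment p for one pathway
#'
#' Upper-tail hypergeometric probability of drawing at least the observed
#' overlap when `length(query)` genes are sampled from the universe, of
#' which `length(pathway)` belong to the set. Query and pathway genes
#' absent from the universe are dropped first (their count is reported via
#' the `n_query_dropped` attribute on [enrich()] output).
#'
#' @param query_genes,pathway_genes,universe_genes character vectors of
#'   gene symbols.
#' @return list with `overlap`, `n_query`, `n_pathway`, `n_universe`, `p`.
#' @export
fisher_enrichment <- function(query_genes, pathway_genes, universe_genes) {
  u <- unique(toupper(universe_genes))
  q <- intersect(unique(toupper(query_genes)), u)
  s <- intersect(unique(toupper(pathway_genes)), u)
  if (!length(q)) stop("query gene set is empty after restriction to the universe")
  k <- length(intersect(q, s))
  p <- stats::phyper(k - 1L, length(s), length(u) - length(s), length(q),
                     lower.tail = FALSE)
  list(overlap = k, n_query = length(q), n_pathway = length(s),
       n_universe = length(u), p = p)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard BH adjustment with enforced monotonicity; output order matches
#' input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of a gene set across a pathway collection
#'
#' Applies the size filter, tests every remaining pathway with
#' [fisher_enrichment()], adjusts with [bh_fdr()], and assigns the
#' significance tier (`significant` q < 0.05, `noteworthy` q < 0.20, else
#' `ns`). Query genes outside the universe are dropped, not errors; the
#' dropped count is attached as attribute `n_query_dropped`.
#'
#' @param query_genes character vector of gene symbols.
#' @param collection named list of gene sets.
#' @param config an [enrichment_config()].
#' @param universe explicit universe (required when
#'   `universe_policy = "annotated_genome"`); default is the union of the
#'   size-filtered collection.
#' @return data.frame sorted by p: `pathway`, `overlap`, `n_pathway`,
#'   `n_query`, `n_universe`, `p`, `q`, `tier`.
#' @export
enrich <- function(query_genes, collection, config = enrichment_config(),
                   universe = NULL) {
  collection <- filter_pathways(collection, config)
  if (!length(collection)) {
    return(data.frame(pathway = character(), overlap = integer(),
                      n_pathway = integer(), n_query = integer(),
                      n_universe = integer(), p = numeric(), q = numeric(),
                      tier = character(), stringsAsFactors = FALSE))
  }
  if (is.null(universe)) {
    if (config$universe_policy == "annotated_genome") {
      stop("universe_policy 'annotated_genome' requires an explicit universe")
    }
    universe <- unique(toupper(unlist(collection, use.names = FALSE)))
  }
  query <- unique(toupper(query_genes))
  n_dropped <- length(setdiff(query, toupper(universe)))
  rows <- lapply(names(collection), function(nm) {
    r <- fisher_enrichment(query, collection[[nm]], universe)
    data.frame(pathway = nm, overlap = r$overlap, n_pathway = r$n_pathway,
               n_query = r$n_query, n_universe = r$n_universe, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$tier <- ifelse(out$q < config$q_significant, "significant",
                     ifelse(out$q < config$q_noteworthy, "noteworthy", "ns"))
  out <- out[order(out$p, out$pathway), ]
  rownames(out) <- NULL
  attr(out, "n_query_dropped") <- n_dropped
  out
}

#' Threshold-then-Fisher surrogate for SNP-based pathway enrichment
#'
#' A documented stand-in for SNP-level gene-set enrichment programs: genes
#' whose association p falls strictly below `p_cut` form the query set,
#' which is then tested with the same Fisher/BH machinery as the CNV gene
#' set. Results carry a `method = "threshold_fisher_surrogate"` attribute
#' so they are never mistaken for the original algorithm's output.
#'
#' @param gene_level_p data.frame with columns `gene` and `p`.
#' @param collection named list of gene sets.
#' @param config an [enrichment_config()].
#' @param p_cut strict significance cut defining the query set
#'   (default 0.05).
#' @return as [enrich()]; zero query genes yields all p = 1.
#' @export
snp_pathway_surrogate <- function(gene_level_p, collection,
                                  config = enrichment_config(), p_cut = 0.05) {
  stopifnot(all(c("gene", "p") %in% names(gene_level_p)))
  collection_f <- filter_pathways(collection, config)
  query <- toupper(gene_level_p$gene[gene_level_p$p < p_cut])
  if (!length(collection_f)) {
    out <- enrich(character(0)[0], collection, config)  # empty frame
    attr(out, "method") <- "threshold_fisher_surrogate"
    return(out)
  }
  if (!length(query)) {
    out <- data.frame(pathway = names(collection_f),
                      overlap = 0L, n_pathway = lengths(collection_f),
                      n_query = 0L, n_universe = NA_integer_, p = 1, q = 1,
                      tier = "ns", stringsAsFactors = FALSE)
    rownames(out) <- NULL
  } else {
    out <- enrich(query, collection, config)
  }
  attr(out, "method") <- "threshold_fisher_surrogate"
  out
}
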