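# Dosage annotation: map private CNVs to genes by padded exon
# intersection, and derive the common-variant candidate list via the eQTL
# p-value filter.
#
# Padding is applied to the CNV boundaries (which have no strand), so gene
# strand is irrelevant. Any >= 1 bp overlap between the padded segment and
# an exon counts; a segment sitting wholly inside an intron beyond the
# padding reports nothing.

#' Annotation configuration
#'
#' @param pad_bp symmetric CNV boundary extension before exon intersection
#'   (default 30 kb).
#' @param candidate_eqtl_p_threshold strict upper bound on the per-gene
#'   eQTL association p used to shortlist common-variant candidates
#'   (default 5e-3).
#' @return a list of class `annotation_config`.
#' @export
annotation_config <- function(pad_bp = 30000L, candidate_eqtl_p_threshold = 5e-3) {
  stopifnot(pad_bp >= 0, candidate_eqtl_p_threshold > 0,
            candidate_eqtl_p_threshold < 1)
  structure(list(pad_bp = pad_bp,
                 candidate_eqtl_p_threshold = candidate_eqtl_p_threshold),
            class = "annotation_config")
}

#' Build an exon index
#'
#' Groups exon intervals by chromosome for fast per-segment lookup and
#' merges overlapping exons of a gene, enforcing the gene-model invariant
#' (sorted, non-overlapping exons per gene).
#'
#' @param exons exon table (`chrom`, `start`, `end`, `gene_id`), e.g. from
#'   [read_exons()].
#' @return list of class `exon_index`.
#' @export
exon_index <- function(exons) {
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(exons)))
  exons$gene_id <- toupper(exons$gene_id)
  merged <- do.call(rbind, lapply(split(exons, paste(exons$chrom, exons$gene_id)),
                                  merge_exon_rows))
  rownames(merged) <- NULL
  structure(list(by_chrom = split(merged, merged$chrom),
                 genes = sort(unique(merged$gene_id))),
            class = "exon_index")
}

merge_exon_rows <- function(e) {
  e <- e[order(e$start), , drop = FALSE]
  if (nrow(e) > 1L) {
    keep_start <- e$start[1]; out <- e[0, , drop = FALSE]
    cur <- e[1, , drop = FALSE]
    for (i in seq_len(nrow(e))[-1]) {
      if (e$start[i] <= cur$end) {
        cur$end <- max(cur$end, e$end[i])
      } else {
        out <- rbind(out, cur); cur <- e[i, , drop = FALSE]
      }
    }
    e <- rbind(out, cur)
  }
  e
}

#' Genes whose dosage a CNV segment affects
#'
#' Pads the segment by `pad_bp` and reports every gene with at least one
#' exon overlapping the padded interval by >= 1 bp, with the segment and
#' direction as provenance.
#'
#' @param segments segment table (one or more rows).
#' @param index an [exon_index()].
#' @param pad_bp boundary padding (default from [annotation_config()]).
#' @return data.frame of hits: `gene_id`, `sample_id`, `chrom`, `start`,
#'   `end`, `direction` (one row per gene x segment).
#' @export
genes_hit <- function(segments, index, pad_bp = 30000L) {
  stopifnot(inherits(index, "exon_index"))
  hits <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, , drop = FALSE]
    ex <- index$by_chrom[[s$chrom]]
    if (is.null(ex) || !nrow(ex)) return(NULL)
    padded <- pad_interval(s[, c("chrom", "start", "end")], pad_bp)
    ov <- overlap_bp(ex, padded)
    g <- unique(ex$gene_id[ov > 0])
    if (!length(g)) return(NULL)
    data.frame(gene_id = g, sample_id = s$sample_id, chrom = s$chrom,
               start = s$start, end = s$end, direction = s$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), sample_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cohort-level dosage-affected gene set
#'
#' Deduplicated union of genes hit by private CNVs across patients. The
#' full per-segment provenance is kept alongside so that
#' genotype-phenotype matching can trace each gene back to carriers.
#'
#' @param private_segments private segment table for the whole cohort.
#' @inheritParams genes_hit
#' @return list with `genes` (unique symbols), `by_direction`
#'   (DEL/DUP gene vectors) and `provenance` (the per-hit table).
#' @export
cohort_gene_set <- function(private_segments, index, pad_bp = 30000L) {
  prov <- genes_hit(private_segments, index, pad_bp)
  list(genes = sort(unique(prov$gene_id)),
       by_direction = list(DEL = sort(unique(prov$gene_id[prov$direction == "DEL"])),
                           DUP = sort(unique(prov$gene_id[prov$direction == "DUP"]))),
       provenance = prov)
}

#' Select common-variant candidate genes by eQTL association p
#'
#' Keeps genes whose best eQTL SNP association p is strictly below the
#' threshold.
#'
#' @param gene_table data.frame with columns `gene` and `p_eqtl` (minimum
#'   eQTL SNP p per gene).
#' @param threshold strict upper bound (default 5e-3).
#' @return character vector of selected gene symbols.
#' @export
select_candidates_by_eqtl <- function(gene_table, threshold = 5e-3) {
  stopifnot(all(c("gene", "p_eqtl") %in% names(gene_table)))
  p <- gene_table$p_eqtl
  if (any(is.na(p) | p < 0 | p > 1)) stop("p_eqtl values must lie in [0, 1]")
  toupper(gene_table$gene[p < threshold])
}
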