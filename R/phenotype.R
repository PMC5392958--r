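# Comorbidity prevalence tables and genotype-phenotype correlation (GPC)
# matching.
#
# Percentages are rounded half-up to 2 decimals (7/89 -> 7.87), matching
# clinical-table conventions; R's default banker's rounding would differ
# on exact ties. Category and cohort roll-ups count distinct patients, so
# a patient with two allergies contributes once to the allergic overall.

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Prevalence percentage
#'
#' `100 * count / n_total`, rounded half-up to 2 decimals.
#'
#' @param count affected patients (0 <= count <= n_total).
#' @param n_total cohort denominator (> 0).
#' @return numeric percent.
#' @export
prevalence <- function(count, n_total) {
  stopifnot(n_total > 0, all(count >= 0), all(count <= n_total))
  round_half_up(100 * count / n_total, 2L)
}

#' Comorbidity prevalence table
#'
#' Per-disease rows count distinct affected patients; each category's
#' overall row counts distinct patients with at least one disease in the
#' category (hence overall <= sum of its rows under multimorbidity), and
#' the cohort overall counts distinct patients with any comorbidity.
#'
#' @param cohort list with `patients` and `comorbidities` (see
#'   [read_patients()]).
#' @param n_total denominator; defaults to the number of patients. The
#'   phenotype and genotype arms of a study may use different denominators
#'   (e.g. all phenotyped patients vs those with confident CNV calls), so
#'   it is explicit.
#' @return list: `rows` (category, disease, n, prevalence_pct,
#'   category_n, category_pct), `overall_n`, `overall_pct`, `n_total`.
#' @export
prevalence_table <- function(cohort, n_total = nrow(cohort$patients)) {
  com <- cohort$comorbidities
  bad <- setdiff(unique(com$category), comorbidity_categories())
  if (length(bad)) stop("unknown comorbidity category: ", paste(bad, collapse = ", "))
  cats <- intersect(comorbidity_categories(), unique(com$category))
  rows <- do.call(rbind, lapply(cats, function(cat) {
    sub <- com[com$category == cat, , drop = FALSE]
    cat_n <- length(unique(sub$patient_id))
    per <- stats::aggregate(patient_id ~ disease, sub,
                            function(x) length(unique(x)))
    per <- per[order(-per$patient_id, per$disease), , drop = FALSE]
    data.frame(category = cat, disease = per$disease, n = per$patient_id,
               prevalence_pct = prevalence(per$patient_id, n_total),
               category_n = cat_n, category_pct = prevalence(cat_n, n_total),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(category = character(), disease = character(),
                       n = integer(), prevalence_pct = numeric(),
                       category_n = integer(), category_pct = numeric(),
                       stringsAsFactors = FALSE)
  }
  rownames(rows) <- NULL
  overall_n <- length(unique(com$patient_id))
  list(rows = rows, overall_n = overall_n,
       overall_pct = prevalence(overall_n, n_total), n_total = n_total)
}

#' Prevalence of one disease within a patient subgroup
#'
#' @param cohort list with `patients` and `comorbidities`.
#' @param disease disease label.
#' @param subset logical vector over `cohort$patients` rows, or a
#'   character vector of patient ids, defining the subgroup (default: the
#'   full cohort).
#' @return list with `n`, `n_subgroup`, `prevalence_pct`.
#' @export
subgroup_prevalence <- function(cohort, disease, subset = NULL) {
  ids <- cohort$patients$patient_id
  if (is.null(subset)) {
    sub_ids <- ids
  } else if (is.logical(subset)) {
    stopifnot(length(subset) == length(ids))
    sub_ids <- ids[subset]
  } else {
    sub_ids <- intersect(ids, subset)
  }
  if (!length(sub_ids)) stop("subgroup is empty")
  com <- cohort$comorbidities
  n <- length(unique(com$patient_id[com$disease == disease &
                                      com$patient_id %in% sub_ids]))
  list(n = n, n_subgroup = length(sub_ids),
       prevalence_pct = prevalence(n, length(sub_ids)))
}

#' Genotype-phenotype correlation matching
#'
#' A GPC hit is a (patient, gene, comorbidity) triple where the patient's
#' private CNV affects the gene and the gene-disease evidence map links
#' that gene to a comorbidity the patient actually has. Genes with a known
#' association to the index disease itself (e.g. a developmental gene
#' deleted in a patient without comorbidities) are reported separately in
#' `known_genotypes`, driven by the `known_map` argument.
#'
#' @param gene_hits per-patient dosage hits (output of [genes_hit()] /
#'   `cohort_gene_set()$provenance`): columns `gene_id`, `sample_id`,
#'   `chrom`, `start`, `end`, `direction`.
#' @param cohort list with `patients` and `comorbidities`.
#' @param gene_disease_map data.frame `gene`, `disease`, plus optional
#'   `evidence`, `source` (see [read_gene_disease_map()]). Disease labels
#'   must match the comorbidity vocabulary of the cohort table.
#' @param known_map optional data.frame `gene`, `disease` of genotypes
#'   known for the index disease, matched regardless of comorbidities.
#' @return list: `hits` (patient_id, comorbidity, gene, chrom, start, end,
#'   direction, evidence), `known_genotypes` (same shape, comorbidity NA).
#' @export
gpc_match <- function(gene_hits, cohort, gene_disease_map, known_map = NULL) {
  map <- gene_disease_map
  if (!"evidence" %in% names(map)) map$evidence <- NA_character_
  com <- cohort$comorbidities
  hits <- merge(gene_hits, map, by.x = "gene_id", by.y = "gene")
  hits <- merge(hits, com, by.x = c("sample_id", "disease"),
                by.y = c("patient_id", "disease"))
  hits <- if (nrow(hits)) {
    data.frame(patient_id = hits$sample_id, comorbidity = hits$disease,
               gene = hits$gene_id, chrom = hits$chrom, start = hits$start,
               end = hits$end, direction = hits$direction,
               evidence = hits$evidence, stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(), comorbidity = character(),
               gene = character(), chrom = character(), start = numeric(),
               end = numeric(), direction = character(),
               evidence = character(), stringsAsFactors = FALSE)
  }
  hits <- unique(hits)
  hits <- hits[order(hits$patient_id, hits$gene, hits$comorbidity), , drop = FALSE]
  rownames(hits) <- NULL

  known <- hits[0, , drop = FALSE]
  if (!is.null(known_map) && nrow(known_map)) {
    km <- merge(gene_hits, known_map, by.x = "gene_id", by.y = "gene")
    if (nrow(km)) {
      known <- unique(data.frame(
        patient_id = km$sample_id, comorbidity = NA_character_,
        gene = km$gene_id, chrom = km$chrom, start = km$start, end = km$end,
        direction = km$direction,
        evidence = if ("disease" %in% names(known_map)) km$disease else NA_character_,
        stringsAsFactors = FALSE))
      known <- known[order(known$patient_id, known$gene), , drop = FALSE]
      rownames(known) <- NULL
    }
  }
  list(hits = hits, known_genotypes = known)
}
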