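# Concordance merging across callers, QC filtering, and cohort-private CNV
# determination against reference panels.
#
# All thresholds phrased ">50%" in the underlying protocol are strict: a
# segment sitting exactly half inside an excluded region is retained, and a
# reference CNV covering exactly half of a segment does not disqualify it
# from being private.

#' Quality-control configuration for CNV segments
#'
#' @param min_length minimum segment length in bp (default 100 kb).
#' @param min_probes minimum supporting probe count (default 5).
#' @param excluded_regions interval table of regions prone to spurious
#'   calls. The default contains the MHC (6:25,000,000-35,000,000);
#'   real-data users should append per-chromosome centromere/telomere
#'   intervals for their genome build, and the synthetic genome generator
#'   supplies its own.
#' @param exclusion_overlap_threshold fraction of a segment inside an
#'   excluded region above which (strictly) the segment is removed.
#' @param novelty_overlap_threshold fraction of a segment covered by a
#'   same-direction reference CNV above which (strictly) it is no longer
#'   private.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(min_length = 100000L, min_probes = 5L,
                      excluded_regions = mhc_region(),
                      exclusion_overlap_threshold = 0.5,
                      novelty_overlap_threshold = 0.5) {
  stopifnot(min_length > 0, min_probes >= 1,
            exclusion_overlap_threshold > 0, exclusion_overlap_threshold <= 1,
            novelty_overlap_threshold > 0, novelty_overlap_threshold <= 1)
  structure(list(min_length = min_length, min_probes = min_probes,
                 excluded_regions = excluded_regions,
                 exclusion_overlap_threshold = exclusion_overlap_threshold,
                 novelty_overlap_threshold = novelty_overlap_threshold),
            class = "qc_config")
}

#' @rdname qc_config
#' @export
mhc_region <- function() genomic_intervals("6", 25000000, 35000000)

#' Merge concordant CNV calls across callers
#'
#' A call is retained only when every caller reports it: for each candidate
#' segment, every other caller must have a same-direction segment covering
#' strictly more than `concordance_fraction` of it. The consensus segment is
#' the intersection of the supporting calls and its probe count the minimum
#' across supporters, so consensus coordinates are conservative.
#'
#' @param calls_by_caller named list of segment tables, one per caller, for
#'   a single sample.
#' @param min_callers minimum number of caller lists required (default 3).
#' @param concordance_fraction query-anchored overlap each supporter must
#'   exceed (default 0.5, strict).
#' @return consensus segment table (caller label `"consensus"`).
#' @export
merge_concordant <- function(calls_by_caller, min_callers = 3L,
                             concordance_fraction = 0.5) {
  if (length(calls_by_caller) < min_callers) {
    stop("need call lists from at least ", min_callers, " callers, got ",
         length(calls_by_caller))
  }
  k <- length(calls_by_caller)
  consensus <- list()
  for (ci in seq_len(k)) {
    segs <- calls_by_caller[[ci]]
    if (!nrow(segs)) next
    for (si in seq_len(nrow(segs))) {
      s <- segs[si, , drop = FALSE]
      supporters <- s
      ok <- TRUE
      for (cj in setdiff(seq_len(k), ci)) {
        other <- calls_by_caller[[cj]]
        if (nrow(other)) {
          cand <- other[other$chrom == s$chrom & other$direction == s$direction, ,
                        drop = FALSE]
        } else cand <- other
        if (!nrow(cand)) { ok <- FALSE; break }
        fr <- overlap_fraction(s, cand)
        if (max(fr) <= concordance_fraction) { ok <- FALSE; break }
        supporters <- rbind(supporters, cand[which.max(fr), , drop = FALSE])
      }
      if (!ok) next
      consensus[[length(consensus) + 1L]] <- data.frame(
        chrom = s$chrom,
        start = max(supporters$start), end = min(supporters$end),
        direction = s$direction, n_probes = min(supporters$n_probes),
        sample_id = s$sample_id, caller = "consensus",
        state = s$state, stringsAsFactors = FALSE)
    }
  }
  if (!length(consensus)) return(empty_cnv_segments())
  out <- do.call(rbind, consensus)
  # each concordant triple is discovered once per caller; keep one copy
  out <- out[!duplicated(out[, c("chrom", "start", "end", "direction", "sample_id")]), ]
  rownames(out) <- NULL
  out
}

#' Apply size, probe and excluded-region filters
#'
#' Keeps segments with length >= `min_length`, probe support >=
#' `min_probes`, and at most `exclusion_overlap_threshold` of their length
#' inside any excluded region (strictly greater overlap removes). The
#' removal tally per rule is attached as attribute `qc_log`.
#'
#' @param segments segment table.
#' @param config a [qc_config()].
#' @return filtered segment table.
#' @export
apply_qc <- function(segments, config = qc_config()) {
  if (!nrow(segments)) return(segments)
  len_ok <- interval_length(segments) >= config$min_length
  probe_ok <- segments$n_probes >= config$min_probes
  excl <- max_overlap_fraction(segments, config$excluded_regions)
  region_ok <- excl <= config$exclusion_overlap_threshold
  keep <- len_ok & probe_ok & region_ok
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_log") <- c(removed_short = sum(!len_ok),
                           removed_few_probes = sum(!probe_ok),
                           removed_excluded_region = sum(!region_ok))
  out
}

#' Is a CNV segment cohort-private?
#'
#' A segment is private (a case-only CNV) when no reference CNV of the
#' same dosage direction covers strictly more than
#' `novelty_overlap_threshold` of its length. Reference panels from
#' different sources are treated identically; pass them as one or several
#' interval tables.
#'
#' @param segments segment table.
#' @param panels a reference panel table (with `direction`) or a list of
#'   them.
#' @param config a [qc_config()] (supplies the novelty threshold).
#' @return logical vector, one per segment.
#' @export
is_private <- function(segments, panels, config = qc_config()) {
  if (!nrow(segments)) return(logical(0))
  if (is.data.frame(panels)) panels <- list(panels)
  ref <- if (length(panels)) do.call(rbind, panels) else
    cbind(genomic_intervals(character(), numeric(), numeric()),
          direction = character())
  cov <- max_overlap_fraction(segments, ref, match_direction = TRUE)
  cov <= config$novelty_overlap_threshold
}

#' Summarize private CNVs per dosage direction
#'
#' Reproduces the cohort summary layout: per direction, the number of
#' CNVs, the number of distinct dosage-affected genes, and the mean and
#' median segment length in bp.
#'
#' @param segments private segment table.
#' @param affected_genes_by_direction named list (`DEL`, `DUP`) of gene
#'   symbol vectors; defaults to empty.
#' @return data.frame with one row per direction.
#' @export
summarize_private <- function(segments,
                              affected_genes_by_direction = list()) {
  dirs <- c("DEL", "DUP")
  rows <- lapply(dirs, function(d) {
    sub <- segments[segments$direction == d, , drop = FALSE]
    lens <- interval_length(sub)
    genes <- affected_genes_by_direction[[d]]
    data.frame(direction = d, n_cnvs = nrow(sub),
               n_affected_genes = length(unique(genes)),
               mean_length = if (nrow(sub)) mean(lens) else 0,
               median_length = if (nrow(sub)) stats::median(lens) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' CNV carrier burden test between two patient groups
#'
#' 2x2 chi-square test (no continuity correction by default) of carrier
#' counts, e.g. patients with comorbidities versus without.
#'
#' @param counts_group_a,counts_group_b length-2 vectors
#'   `(carriers, non_carriers)`.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p_value`, `table`.
#' @export
burden_test <- function(counts_group_a, counts_group_b, correct = FALSE) {
  stopifnot(length(counts_group_a) == 2L, length(counts_group_b) == 2L,
            all(c(counts_group_a, counts_group_b) >= 0),
            sum(counts_group_a) > 0, sum(counts_group_b) > 0)
  tab <- rbind(a = counts_group_a, b = counts_group_b)
  colnames(tab) <- c("carrier", "non_carrier")
  if (any(colSums(tab) == 0)) {
    stop("a margin of the 2x2 table is zero; use an exact test instead")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), table = tab)
}
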