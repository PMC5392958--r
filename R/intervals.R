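# Interval arithmetic on 0-based half-open genomic coordinates.
#
# Every coordinate in the package is 0-based half-open [start, end); length
# is end - start in bp. Inputs in 1-based inclusive conventions are converted
# at the file boundary (see read_cnv_calls).

#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open: `start` is the first base covered,
#' `end` is one past the last. Chromosome labels are plain strings
#' ("1".."22" for autosomes); any leading "chr" prefix is stripped so that
#' files mixing conventions compare correctly.
#'
#' @param chrom character vector of chromosome labels.
#' @param start,end integer vectors, `0 <= start < end`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  chrom <- norm_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L) chrom <- rep_len(chrom, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  bad <- which(!nzchar(chrom) | is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    stop("invalid interval at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         ": require chrom non-empty, start >= 0, end > start")
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

norm_chrom <- function(x) sub("^chr", "", as.character(x))

interval_length <- function(x) x$end - x$start

#' Fraction of a query interval covered by a target interval
#'
#' One-directional (query-anchored) overlap: the number of bases shared by
#' query and target divided by the query length. This is the ">50% of the
#' CNV length" primitive used both for exclusion-region filtering and for
#' privatization against reference panels. Returns 0 when the chromosomes
#' differ or the intervals are disjoint.
#'
#' Vectorized over rows; the shorter argument is recycled.
#'
#' @param query,target single intervals (1-row data.frames from
#'   [genomic_intervals()]) or equal-length tables.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
overlap_fraction <- function(query, target) {
  ov <- overlap_bp(query, target)
  ov / rep_len(interval_length(query), length(ov))
}

# shared bp between interval rows (0 across chromosomes)
overlap_bp <- function(query, target) {
  n <- max(nrow(query), nrow(target))
  qs <- rep_len(query$start, n); qe <- rep_len(query$end, n)
  ts <- rep_len(target$start, n); te <- rep_len(target$end, n)
  same <- rep_len(query$chrom, n) == rep_len(target$chrom, n)
  pmax(0, pmin(qe, te) - pmax(qs, ts)) * as.numeric(same)
}

#' Pad an interval symmetrically
#'
#' Extends both boundaries by `pad_bp`, clamping the start at 0. Used to
#' extend CNV boundaries before exon intersection so that dosage effects on
#' genes flanking the rearrangement are captured.
#'
#' @param segment interval table.
#' @param pad_bp non-negative padding in bp (default 30 kb).
#' @return interval table with the same rows, padded.
#' @export
pad_interval <- function(segment, pad_bp = 30000L) {
  stopifnot(pad_bp >= 0)
  segment$start <- pmax(0, segment$start - pad_bp)
  segment$end <- segment$end + pad_bp
  segment
}

# Maximum single-target coverage of each query row by any row of `targets`
# restricted to matching chromosome (and direction when both carry one).
max_overlap_fraction <- function(query, targets, match_direction = FALSE) {
  if (nrow(targets) == 0L) return(rep(0, nrow(query)))
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, , drop = FALSE]
    keep <- targets$chrom == q$chrom
    if (match_direction) keep <- keep & targets$direction == q$direction
    t <- targets[keep, , drop = FALSE]
    if (nrow(t) == 0L) return(0)
    max(overlap_fraction(q, t))
  }, numeric(1))
}
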