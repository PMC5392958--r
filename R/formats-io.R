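# Readers and writers for every external file the pipeline touches.
#
# Dialects are strict: a malformed line is an error naming the line number,
# never a silent skip. All coordinates are normalized to 0-based half-open
# on read; writers emit the same dialect so that write-then-read is the
# identity on records.

cnv_columns <- c("chrom", "start", "end", "direction", "n_probes",
                 "sample_id", "caller", "state")

# canonical empty segment table
empty_cnv_segments <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             direction = character(), n_probes = numeric(),
             sample_id = character(), caller = character(),
             state = numeric(), stringsAsFactors = FALSE)
}

#' Assemble a CNV segment table
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param direction "DEL" or "DUP".
#' @param n_probes supporting probe counts (>= 1).
#' @param sample_id,caller provenance labels.
#' @param state optional integer copy number (NA allowed).
#' @return a segment `data.frame` with one row per call.
#' @export
cnv_segments <- function(chrom, start, end, direction, n_probes,
                         sample_id = "", caller = "", state = NA_real_) {
  iv <- genomic_intervals(chrom, start, end)
  n <- nrow(iv)
  direction <- toupper(rep_len(as.character(direction), n))
  if (!all(direction %in% c("DEL", "DUP"))) {
    stop("direction must be 'DEL' or 'DUP'")
  }
  n_probes <- rep_len(as.numeric(n_probes), n)
  if (any(is.na(n_probes) | n_probes < 1)) stop("n_probes must be >= 1")
  data.frame(iv, direction = direction, n_probes = n_probes,
             sample_id = rep_len(as.character(sample_id), n),
             caller = rep_len(as.character(caller), n),
             state = rep_len(as.numeric(state), n),
             stringsAsFactors = FALSE)
}

#' Read CNV segment calls
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`bed_like`}{tab-separated, 0-based half-open:
#'     `chrom start end sample_id direction n_probes [state]`.}
#'   \item{`rawcnv_like`}{whitespace-separated, 1-based inclusive locus as
#'     emitted by segmentation callers:
#'     `chr1:1000-2000 numsnp=7 state2,cn=1 sampleA`. Converted on read by
#'     `start - 1`; direction is derived from the copy number (`cn < 2` is a
#'     deletion, `cn > 2` a duplication).}
#' }
#' Records with copy-number state 2 carry no dosage change and are dropped
#' (reported via the `n_rejected` attribute), not errors.
#'
#' @param path input file.
#' @param dialect `"bed_like"` or `"rawcnv_like"`.
#' @param caller caller label stored with every record.
#' @return segment `data.frame` (see [cnv_segments()]).
#' @export
read_cnv_calls <- function(path, dialect = c("bed_like", "rawcnv_like"),
                           caller = "") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines_keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (!length(lines_keep)) {
    out <- empty_cnv_segments()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  parse_one <- if (dialect == "bed_like") parse_bed_line else parse_rawcnv_line
  recs <- lapply(lines_keep, function(i) {
    rec <- tryCatch(parse_one(lines[i], caller),
                    error = function(e) stop("malformed ", dialect, " record at line ",
                                             i, " of ", path, ": ", conditionMessage(e),
                                             call. = FALSE))
    rec
  })
  rejected <- vapply(recs, is.null, logical(1))
  out <- if (all(rejected)) empty_cnv_segments() else do.call(rbind, recs[!rejected])
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(rejected)
  out
}

parse_bed_line <- function(line, caller) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  if (length(f) < 6L) stop("expected >= 6 fields, got ", length(f))
  state <- if (length(f) >= 7L) as.numeric(f[7]) else NA_real_
  if (!is.na(state) && state == 2) return(NULL)
  cnv_segments(f[1], as.numeric(f[2]), as.numeric(f[3]),
               direction = f[5], n_probes = as.numeric(f[6]),
               sample_id = f[4], caller = caller, state = state)
}

parse_rawcnv_line <- function(line, caller) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  m <- regmatches(f[1], regexec("^([^:]+):([0-9]+)-([0-9]+)$", f[1]))[[1]]
  if (length(m) != 4L) stop("cannot parse locus '", f[1], "'")
  numsnp <- grep("^numsnp=", f, value = TRUE)
  cn <- regmatches(f, regexpr("cn=[0-9]+", f))
  sample <- setdiff(f[-1], grep("=", f, value = TRUE))
  if (!length(numsnp) || !length(cn) || !length(sample)) {
    stop("need numsnp=, cn= and a sample field")
  }
  cn <- as.numeric(sub("cn=", "", cn[1]))
  if (cn == 2) return(NULL)
  start1 <- as.numeric(m[3])  # 1-based inclusive
  cnv_segments(m[2], start1 - 1, as.numeric(m[4]),
               direction = if (cn < 2) "DEL" else "DUP",
               n_probes = as.numeric(sub("numsnp=", "", numsnp[1])),
               sample_id = sample[1], caller = caller, state = cn)
}

#' Write CNV segment calls
#'
#' Emits the exact dialects accepted by [read_cnv_calls()], so that a
#' write/read round trip reproduces the records.
#'
#' @inheritParams read_cnv_calls
#' @param segments segment table.
#' @export
write_cnv_calls <- function(segments, path, dialect = c("bed_like", "rawcnv_like")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed_like") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%d%s",
                     segments$chrom, as.integer(segments$start),
                     as.integer(segments$end), segments$sample_id,
                     segments$direction, as.integer(segments$n_probes),
                     ifelse(is.na(segments$state), "",
                            paste0("\t", as.integer(segments$state))))
  } else {
    state <- ifelse(is.na(segments$state),
                    ifelse(segments$direction == "DEL", 1, 3), segments$state)
    lines <- sprintf("%s:%d-%d\tnumsnp=%d\tstate%d,cn=%d\t%s",
                     segments$chrom, as.integer(segments$start) + 1L,
                     as.integer(segments$end), as.integer(segments$n_probes),
                     as.integer(state), as.integer(state), segments$sample_id)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT pathway collection
#'
#' GSEA gene-matrix-transposed dialect: one tab-separated line per set,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Gene symbols are
#' uppercased and deduplicated within a set.
#'
#' @param path GMT file.
#' @param source label stored on the collection.
#' @return named list of character vectors of gene symbols, with a
#'   `source` attribute.
#' @export
read_gmt <- function(path, source = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    list(name = f[1], genes = unique(toupper(f[-(1:2)])))
  })
  out <- stats::setNames(lapply(sets, `[[`, "genes"),
                         vapply(sets, `[[`, character(1), "name"))
  attr(out, "source") <- source
  out
}

#' @rdname read_gmt
#' @param collection named list of gene sets.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a confidence-weighted PPI edge list into a graph
#'
#' The file is a TSV of `gene_a<TAB>gene_b<TAB>confidence` (no header by
#' default; a `gene_a...` header line is skipped). Filtering mirrors
#' standard interactome curation: edges below `min_confidence` and
#' self-loops are dropped, symbols are uppercased, and parallel records are
#' collapsed keeping the maximum confidence. The result is an undirected
#' simple [igraph][igraph::graph] whose node universe is every gene with at
#' least one retained interaction.
#'
#' @param path edge-list TSV.
#' @param min_confidence minimum confidence score kept (default 0.01).
#' @return undirected igraph with a `confidence` edge attribute.
#' @export
read_ppi <- function(path, min_confidence = 0.01) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("gene_a", "gene_b", "confidence"),
                          colClasses = c("character", "character", "character"),
                          quote = "", comment.char = "#")
  if (nrow(df) && identical(tolower(df$gene_a[1]), "gene_a")) df <- df[-1, , drop = FALSE]
  conf <- suppressWarnings(as.numeric(df$confidence))
  if (anyNA(conf)) {
    stop("non-numeric confidence at record(s) ",
         paste(utils::head(which(is.na(conf)), 5L), collapse = ", "))
  }
  ppi_graph(data.frame(gene_a = df$gene_a, gene_b = df$gene_b,
                       confidence = conf, stringsAsFactors = FALSE),
            min_confidence = min_confidence)
}

#' @rdname read_ppi
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @export
ppi_graph <- function(edges, min_confidence = 0.01) {
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    stop("confidence scores must lie in [0, 1]")
  }
  a <- toupper(edges$gene_a); b <- toupper(edges$gene_b)
  keep <- edges$confidence >= min_confidence & a != b
  a <- a[keep]; b <- b[keep]; conf <- edges$confidence[keep]
  # undirected: canonical endpoint order, then max confidence per pair
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  conf <- tapply(conf, key, max)
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
  igraph::E(g)$confidence <- as.numeric(conf)
  attr(g, "min_confidence") <- min_confidence
  g
}

#' @rdname read_ppi
#' @param graph a PPI igraph.
#' @export
write_ppi <- function(graph, path) {
  e <- igraph::as_data_frame(graph, what = "edges")
  writeLines(sprintf("%s\t%s\t%s", e$from, e$to,
                     format(e$confidence, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read/write a reference CNV panel
#'
#' Tab-separated with header `chrom start end direction`, matching public
#' CNV-catalogue exports. Used for privatization only, so sample provenance
#' is not kept.
#'
#' @param path panel TSV.
#' @return interval table with a `direction` column.
#' @export
read_reference_panel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "numeric", "character"))
  out <- genomic_intervals(df$chrom, df$start, df$end)
  out$direction <- toupper(df$direction)
  stopifnot(all(out$direction %in% c("DEL", "DUP")))
  out
}

#' @rdname read_reference_panel
#' @param panel interval table with `direction`.
#' @export
write_reference_panel <- function(panel, path) {
  utils::write.table(panel[, c("chrom", "start", "end", "direction")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write exon annotation (BED4)
#'
#' `chrom start end gene_id`, tab-separated, 0-based half-open. Gene
#' symbols are uppercased; exon identity across the pipeline is by symbol.
#'
#' @param path BED file.
#' @return exon table (`chrom`, `start`, `end`, `gene_id`).
#' @export
read_exons <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"),
                          colClasses = c("character", "numeric", "numeric", "character"))
  out <- genomic_intervals(df$chrom, df$start, df$end)
  out$gene_id <- toupper(df$gene_id)
  out
}

#' @rdname read_exons
#' @param exons exon table.
#' @export
write_exons <- function(exons, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", exons$chrom, as.integer(exons$start),
                     as.integer(exons$end), exons$gene_id), path)
  invisible(path)
}

#' Declared comorbidity category vocabulary
#'
#' @return character vector of valid category labels.
#' @export
comorbidity_categories <- function() {
  c("allergic", "autoimmune", "hematological", "neural/psychiatric",
    "structural", "metabolic", "other")
}

#' Read/write the patient phenotype table
#'
#' Long-format CSV with header `patient_id,sex,category,disease`: one row
#' per comorbidity; a patient without comorbidities appears once with empty
#' `category` and `disease`. Categories must come from
#' [comorbidity_categories()].
#'
#' @param path CSV file.
#' @return list with `patients` (one row per patient: `patient_id`, `sex`)
#'   and `comorbidities` (`patient_id`, `category`, `disease`).
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("patient_id", "sex", "category", "disease") %in% names(df)))
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  patients <- unique(df[, c("patient_id", "sex")])
  if (anyDuplicated(patients$patient_id)) {
    stop("conflicting sex records for a patient_id")
  }
  com <- df[nzchar(df$category), c("patient_id", "category", "disease")]
  bad <- setdiff(unique(com$category), comorbidity_categories())
  if (length(bad)) stop("unknown comorbidity category: ", paste(bad, collapse = ", "))
  rownames(patients) <- rownames(com) <- NULL
  list(patients = patients, comorbidities = unique(com))
}

#' @rdname read_patients
#' @param cohort list as returned by [read_patients()].
#' @export
write_patients <- function(cohort, path) {
  com <- cohort$comorbidities
  pat <- cohort$patients
  rows <- merge(pat, com, by = "patient_id", all.x = TRUE, sort = FALSE)
  rows$category[is.na(rows$category)] <- ""
  rows$disease[is.na(rows$disease)] <- ""
  rows <- rows[order(rows$patient_id, rows$category, rows$disease), ]
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-gene association table
#'
#' TSV with header; must contain a `gene` column plus numeric p-value
#' columns (`p_gene`, `p_eqtl`, ...). Used for the common-variant candidate
#' list and its eQTL-based selection filter.
#'
#' @param path TSV file.
#' @return data.frame with uppercased `gene` symbols.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(df))
  df$gene <- toupper(df$gene)
  df
}

#' Read a gene-disease evidence map
#'
#' TSV with header `gene disease evidence source`; keyed by
#' (gene, disease) for genotype-phenotype correlation matching.
#'
#' @param path TSV file.
#' @return data.frame with uppercased gene symbols.
#' @export
read_gene_disease_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "disease") %in% names(df)))
  df$gene <- toupper(df$gene)
  df
}

#' Export a candidate network to GraphML
#'
#' Node type, module membership, centrality and core flag travel as node
#' attributes, so downstream visualization tools can size and color nodes
#' directly.
#'
#' @param network an igraph (e.g. from [build_candidate_network()]).
#' @param path output file.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
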