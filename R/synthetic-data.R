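# Seeded generators for every input the pipeline consumes, with planted
# ground truth so each stage has a recoverable answer.
#
# The defaults reproduce the stated study world: 89 phenotyped patients
# (42 male), the published comorbidity counts (37 patients with >= 1
# chronic condition), 86 patients with confident CNV calls, 26 carriers of
# 29 cohort-private CNVs (6 deletions), three planted genotype-phenotype
# correlations and one known-genotype microdeletion. Graph, pathway and
# genome sizes are scaled to what a single CPU can exercise in minutes;
# the methods vignette discusses which features of real data the
# generator does and does not emulate.
#
# Every generator draws from its own seeded substream (config seed plus a
# fixed offset), so adding a generator never perturbs the others.

#' Synthetic-data configuration
#'
#' @param seed mandatory RNG seed; every generator derives its own
#'   substream from it.
#' @param n_chromosomes,chrom_length synthetic genome shape.
#' @param n_genes,exons_per_gene gene annotation size.
#' @param n_patients phenotyped cohort size.
#' @param n_genotyped patients with usable CNV calls (<= n_patients).
#' @param n_private_cnvs planted cohort-private CNVs.
#' @param n_carriers patients carrying at least one private CNV.
#' @param n_private_del planted private deletions (the rest duplicate).
#' @param n_common_cnvs_per_patient reference-covered (non-private) CNVs
#'   per genotyped patient.
#' @param length_range log-uniform bp bounds for common CNVs.
#' @param private_length_range bp bounds for private CNVs (kept narrow so
#'   each private CNV affects exactly its one target gene).
#' @param probe_spacing_bp array probe spacing; probe support is
#'   `floor(length / spacing)`.
#' @param jitter_frac per-caller boundary jitter as a fraction of segment
#'   length (< 0.5 of the concordance threshold so all true calls merge).
#' @param n_fp_per_caller caller-specific false positives per patient.
#' @param n_reference_background random background panel intervals.
#' @param n_snp_candidates planted common-variant candidate genes (eQTL
#'   p below the selection threshold).
#' @param ppi list: `n_nodes`, `background_p`, `module_sizes`,
#'   `module_p_in`, `core_size`, `core_density`, `core_attach_p`,
#'   `cross_excess` (multiplier on the background A-B edge rate),
#'   `confidence_range`.
#' @param pathways list: `n_sets`, `size_range`, `planted_overlap`
#'   (fraction of the CNV gene set seeded into the planted pathway).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_chromosomes = 4L, chrom_length = 6e7,
                         n_genes = 600L, exons_per_gene = 5L,
                         n_patients = 89L, n_genotyped = 86L,
                         n_private_cnvs = 29L, n_carriers = 26L,
                         n_private_del = 6L,
                         n_common_cnvs_per_patient = 2L,
                         length_range = c(1e5, 1e6),
                         private_length_range = c(2e5, 3e5),
                         probe_spacing_bp = 1e4,
                         jitter_frac = 0.1,
                         n_fp_per_caller = 1L,
                         n_reference_background = 200L,
                         n_snp_candidates = 103L,
                         ppi = list(n_nodes = 500L, background_p = 0.008,
                                    module_sizes = rep(20L, 4L),
                                    module_p_in = 0.6,
                                    core_size = 60L, core_density = 0.8,
                                    core_attach_p = 0.02,
                                    cross_excess = 5,
                                    confidence_range = c(0.01, 1)),
                         pathways = list(n_sets = 40L, size_range = c(20L, 60L),
                                         planted_overlap = 0.3)) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_genotyped <= n_patients, n_carriers <= n_genotyped,
            n_private_del <= n_private_cnvs, n_carriers <= n_private_cnvs,
            jitter_frac < 0.25)
  structure(as.list(environment()), class = "synth_config")
}

with_substream <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((config$seed + offset) %% .Machine$integer.max)
  expr
}

#' Generate a synthetic genome annotation
#'
#' Non-overlapping genes with merged-exon models, laid out on chromosome
#' arms that avoid per-chromosome centromere/telomere exclusion zones.
#' Deterministic per seed.
#'
#' @param config a [synth_config()].
#' @return list: `genes` (chrom, start, end, gene_id), `exons` (BED4
#'   table), `excluded_regions` (telomeres + centromeres),
#'   `chrom_lengths`.
#' @export
generate_genome <- function(config) {
  with_substream(config, 101L, {
    L <- config$chrom_length
    chroms <- as.character(seq_len(config$n_chromosomes))
    telo <- 5e5; centro <- 1e6
    excluded <- do.call(rbind, lapply(chroms, function(ch) {
      genomic_intervals(rep(ch, 3),
                        c(0, L / 2 - centro / 2, L - telo),
                        c(telo, L / 2 + centro / 2, L))
    }))
    per_chrom <- config$n_genes %/% config$n_chromosomes
    extra <- config$n_genes %% config$n_chromosomes
    genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      ng <- per_chrom + (ci <= extra)
      # two arms, slots proportional to arm length
      arms <- rbind(c(telo, L / 2 - centro / 2), c(L / 2 + centro / 2, L - telo))
      n_arm1 <- round(ng * (arms[1, 2] - arms[1, 1]) / sum(arms[, 2] - arms[, 1]))
      counts <- c(n_arm1, ng - n_arm1)
      do.call(rbind, lapply(1:2, function(ai) {
        n <- counts[ai]
        if (!n) return(NULL)
        slot <- (arms[ai, 2] - arms[ai, 1]) / n
        len <- stats::runif(n, 3e4, 8e4)
        start <- arms[ai, 1] + (seq_len(n) - 1) * slot +
          stats::runif(n, 0, pmax(1, slot - len))
        data.frame(chrom = chroms[ci], start = floor(start),
                   end = floor(start + len), stringsAsFactors = FALSE)
      }))
    }))
    genes <- genes[order(genes$chrom, genes$start), ]
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      k <- config$exons_per_gene
      # evenly spaced exons occupying ~a third of the gene body
      bounds <- seq(g$start, g$end, length.out = 2L * k + 1L)
      data.frame(chrom = g$chrom, start = floor(bounds[seq(1, 2 * k, by = 2)]),
                 end = floor(bounds[seq(1, 2 * k, by = 2)] +
                               diff(bounds)[1] * 0.7),
                 gene_id = g$gene_id, stringsAsFactors = FALSE)
    }))
    rownames(exons) <- NULL
    list(genes = genes, exons = exons, excluded_regions = excluded,
         chrom_lengths = stats::setNames(rep(L, length(chroms)), chroms))
  })
}

# planted comorbidity layout: published per-disease counts over an
# 89-patient cohort; sums: category distinct 15/5/10/7/5/2/4, overall 37.
planted_disease_table <- function() {
  d <- rbind(
    c("allergic", "Asthma", 7), c("allergic", "Eczema", 9),
    c("autoimmune", "Psoriasis", 2), c("autoimmune", "Juvenile arthritis", 1),
    c("autoimmune", "Hashimoto thyroiditis", 1),
    c("autoimmune", "Type 1 diabetes mellitus", 1),
    c("hematological", "G6PD deficiency", 6),
    c("hematological", "Alpha thalassemia trait", 2),
    c("hematological", "Thrombocytopenia", 1), c("hematological", "Pancytopenia", 1),
    c("neural/psychiatric", "ADHD", 2), c("neural/psychiatric", "Epilepsy", 3),
    c("neural/psychiatric", "Depression", 1),
    c("neural/psychiatric", "Mental retardation", 1),
    c("structural", "Intestinal malrotation", 1),
    c("structural", "Pulmonary atresia with VSD", 1),
    c("structural", "Temporal AVM", 1),
    c("structural", "Vesicoureteric reflux grade IV", 1),
    c("structural", "Jejunal atresia", 1),
    c("metabolic", "Hyperlipidemia", 1),
    c("metabolic", "Congenital hypothyroidism", 1),
    c("other", "Sleep apnea", 3), c("other", "Deviated nasal septum", 1))
  data.frame(category = d[, 1], disease = d[, 2], n = as.integer(d[, 3]),
             stringsAsFactors = FALSE)
}

# deterministic multimorbidity layout over 37 affected patients: the first
# 11 belong to two categories (37 + 11 = 48 category memberships), chosen
# so no patient draws the same category twice.
assign_comorbidities <- function(affected) {
  stopifnot(length(affected) == 37L)
  tab <- planted_disease_table()
  cat_sizes <- c(allergic = 15L, autoimmune = 5L, hematological = 10L,
                 `neural/psychiatric` = 7L, structural = 5L, metabolic = 2L,
                 other = 4L)
  slots <- c(affected, affected[1:11])           # 48 patient slots
  cat_of_slot <- rep(names(cat_sizes), times = cat_sizes)
  by_cat <- split(slots, factor(cat_of_slot, levels = names(cat_sizes)))
  rows <- list()
  for (cat in names(by_cat)) {
    pats <- by_cat[[cat]]
    dis <- tab[tab$category == cat, ]
    if (cat == "allergic") {
      # one dual-allergy patient: asthma 1..7, eczema 7..15
      rows[[cat]] <- data.frame(
        patient_id = c(pats[1:7], pats[7:15]), category = cat,
        disease = c(rep("Asthma", 7), rep("Eczema", 9)),
        stringsAsFactors = FALSE)
    } else {
      rows[[cat]] <- data.frame(
        patient_id = pats, category = cat,
        disease = rep(dis$disease, times = dis$n), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate the synthetic patient cohort
#'
#' Emits the phenotype table (planted published comorbidity counts, G6PD
#' deficiency confined to males), per-patient three-caller CNV call sets
#' (every true CNV jittered into each caller plus one caller-specific
#' false positive), the planted private CNVs with their single target
#' genes, the genotype-phenotype correlation triples and a known-genotype
#' microdeletion carrier, plus the gene-disease evidence map.
#'
#' @param config a [synth_config()].
#' @param genome output of [generate_genome()].
#' @return list: `cohort` (patients + comorbidities), `calls`
#'   (per patient, per caller segment tables), `truth` (private segments,
#'   private target genes, gpc triples, known genotype, per-disease
#'   counts), `gene_disease_map`, `known_map`.
#' @export
generate_cohort <- function(config, genome) {
  with_substream(config, 202L, {
    ids <- sprintf("BA%03d", seq_len(config$n_patients))
    affected <- sample(ids, 37L)
    com <- assign_comorbidities(affected)
    com <- unique(com[order(com$patient_id, com$category, com$disease), ])
    rownames(com) <- NULL

    # sexes: G6PD carriers are male; fill to 42 males total
    g6pd <- unique(com$patient_id[com$disease == "G6PD deficiency"])
    males <- c(g6pd, sample(setdiff(ids, g6pd), 42L - length(g6pd)))
    patients <- data.frame(patient_id = ids,
                           sex = ifelse(ids %in% males, "M", "F"),
                           stringsAsFactors = FALSE)
    cohort <- list(patients = patients, comorbidities = com)

    # genotyped subset: the three unreliable samples are unaffected
    ungenotyped <- sample(setdiff(ids, affected), config$n_patients - config$n_genotyped)
    genotyped <- setdiff(ids, ungenotyped)

    # genotype-phenotype plants: three comorbid carriers + one known-genotype
    gpc_patients <- c(
      unique(com$patient_id[com$disease == "Type 1 diabetes mellitus"])[1],
      unique(com$patient_id[com$disease == "Hashimoto thyroiditis"])[1],
      setdiff(unique(com$patient_id[com$disease == "Eczema"]), affected[1:11])[1])
    gpc_diseases <- c("Type 1 diabetes mellitus", "Hashimoto thyroiditis", "Eczema")
    known_patient <- sample(setdiff(genotyped, affected), 1L)

    # carriers: GPC trio + known-genotype patient + others; three carry two
    other_carriers <- sample(setdiff(genotyped, c(gpc_patients, known_patient)),
                             config$n_carriers - 4L)
    carrier_of <- c(gpc_patients, known_patient, other_carriers,
                    other_carriers[seq_len(config$n_private_cnvs - config$n_carriers)])

    # private CNV targets: genes isolated enough that the padded segment
    # hits exactly its own gene
    iso <- isolated_genes(genome, margin = max(config$private_length_range) / 2 +
                            3e4 + 0.15 * max(config$private_length_range))
    stopifnot(length(iso) >= length(carrier_of))
    targets <- sample(iso, length(carrier_of))
    # directions: known-genotype is a deletion; remaining deletions drawn
    # from the non-GPC plants (the GPC plants are duplications)
    dir <- rep("DUP", length(carrier_of))
    dir[4L] <- "DEL"
    extra_del <- 4L + sample.int(length(carrier_of) - 4L, config$n_private_del - 1L)
    dir[extra_del] <- "DEL"

    gene_tab <- genome$genes
    priv <- do.call(rbind, lapply(seq_along(carrier_of), function(i) {
      g <- gene_tab[gene_tab$gene_id == targets[i], ]
      len <- exp(stats::runif(1, log(config$private_length_range[1]),
                              log(config$private_length_range[2])))
      center <- (g$start + g$end) / 2
      start <- max(0, floor(center - len / 2))
      data.frame(chrom = g$chrom, start = start, end = floor(start + len),
                 direction = dir[i], n_probes = floor(len / config$probe_spacing_bp),
                 sample_id = carrier_of[i], caller = "truth",
                 state = ifelse(dir[i] == "DEL", 1, 3),
                 gene_id = targets[i], stringsAsFactors = FALSE)
    }))

    # common (reference-covered) CNVs, kept clear of the private plants
    common <- list()
    for (pid in genotyped) {
      made <- 0L
      while (made < config$n_common_cnvs_per_patient) {
        seg <- random_segment(config, genome)
        clash <- overlaps_any(seg, priv, margin = 1e5) ||
          (length(common) && overlaps_any(seg, do.call(rbind, common)[
            do.call(rbind, common)$sample_id == pid, , drop = FALSE], margin = 0))
        if (clash) next
        seg$sample_id <- pid
        common[[length(common) + 1L]] <- seg
        made <- made + 1L
      }
    }
    common <- do.call(rbind, common)

    truth_segments <- rbind(priv[, names(common)], common)
    calls <- emit_caller_views(config, genome, truth_segments, genotyped)

    gpc_genes <- targets[1:3]
    gene_disease_map <- data.frame(
      gene = gpc_genes, disease = gpc_diseases,
      evidence = paste0("immune dysregulation locus (", gpc_genes, ")"),
      source = "synthetic-curation", stringsAsFactors = FALSE)
    # decoys: mapped genes nobody carries, and a disease no map row matches
    decoys <- sample(setdiff(genome$genes$gene_id, targets), 5L)
    gene_disease_map <- rbind(gene_disease_map, data.frame(
      gene = decoys, disease = sample(planted_disease_table()$disease, 5L),
      evidence = "decoy association", source = "synthetic-curation",
      stringsAsFactors = FALSE))
    known_map <- data.frame(gene = targets[4L], disease = "biliary atresia",
                            evidence = "known index-disease microdeletion",
                            stringsAsFactors = FALSE)

    disease_counts <- planted_disease_table()
    list(cohort = cohort, calls = calls,
         gene_disease_map = gene_disease_map, known_map = known_map,
         truth = list(
           private_segments = priv, private_genes = sort(unique(targets)),
           common_segments = common, genotyped = sort(genotyped),
           carriers = sort(unique(carrier_of)),
           gpc = data.frame(patient_id = gpc_patients, comorbidity = gpc_diseases,
                            gene = gpc_genes, stringsAsFactors = FALSE),
           known_genotype = data.frame(patient_id = known_patient,
                                       gene = targets[4L], stringsAsFactors = FALSE),
           disease_counts = disease_counts,
           n_affected = 37L, affected = sort(affected)))
  })
}

# genes whose neighbours are all farther than `margin` from their centre
isolated_genes <- function(genome, margin) {
  g <- genome$genes
  ok <- vapply(seq_len(nrow(g)), function(i) {
    ctr <- (g$start[i] + g$end[i]) / 2
    same <- g[g$chrom == g$chrom[i] & g$gene_id != g$gene_id[i], ]
    all(same$end < ctr - margin | same$start > ctr + margin)
  }, logical(1))
  g$gene_id[ok]
}

random_segment <- function(config, genome) {
  chrom <- sample(names(genome$chrom_lengths), 1L)
  len <- exp(stats::runif(1, log(config$length_range[1]), log(config$length_range[2])))
  arm_end <- genome$chrom_lengths[[chrom]] - 5e5 - len
  start <- floor(stats::runif(1, 5e5, arm_end))
  dirn <- sample(c("DEL", "DUP"), 1L)
  data.frame(chrom = chrom, start = start, end = floor(start + len),
             direction = dirn, n_probes = floor(len / config$probe_spacing_bp),
             sample_id = "", caller = "truth",
             state = ifelse(dirn == "DEL", 1, 3), stringsAsFactors = FALSE)
}

overlaps_any <- function(seg, others, margin = 0) {
  if (is.null(others) || !nrow(others)) return(FALSE)
  padded <- seg
  padded$start <- max(0, padded$start - margin); padded$end <- padded$end + margin
  any(overlap_bp(others[, c("chrom", "start", "end")], padded) > 0)
}

# per-caller jittered views of every true segment plus private false calls
emit_caller_views <- function(config, genome, truth_segments, genotyped) {
  callers <- c("callerA", "callerB", "callerC")
  out <- stats::setNames(vector("list", length(genotyped)), genotyped)
  for (pid in genotyped) {
    segs <- truth_segments[truth_segments$sample_id == pid, , drop = FALSE]
    views <- list()
    fps <- NULL  # false calls of this patient so far, across callers
    for (cl in callers) {
      v <- segs
      if (nrow(v)) {
        len <- v$end - v$start
        v$start <- pmax(0, floor(v$start +
                                   stats::runif(nrow(v), -1, 1) * config$jitter_frac * len))
        v$end <- floor(v$end + stats::runif(nrow(v), -1, 1) * config$jitter_frac * len)
        v$n_probes <- pmax(5, floor((v$end - v$start) / config$probe_spacing_bp))
        v$caller <- cl
      }
      # caller-specific false positives, clear of every true segment and
      # of this patient's other false calls (so no two callers concord)
      for (k in seq_len(config$n_fp_per_caller)) {
        repeat {
          fp <- random_segment(config, genome)
          if (!overlaps_any(fp, truth_segments, margin = 0) &&
              !overlaps_any(fp, fps, margin = 0)) break
        }
        fp$sample_id <- pid; fp$caller <- cl
        fps <- rbind(fps, fp)
        v <- rbind(v, fp)
      }
      views[[cl]] <- v[order(v$chrom, v$start), , drop = FALSE]
    }
    out[[pid]] <- views
  }
  out
}

#' Generate a reference CNV panel
#'
#' Covers every non-private true CNV with a same-direction interval (the
#' interval itself, so coverage is total), plus random background
#' intervals rejected whenever they would cover too much of a planted
#' private CNV. By construction no panel interval covers more than half of
#' any private plant.
#'
#' @param config a [synth_config()].
#' @param genome output of [generate_genome()].
#' @param cohort output of [generate_cohort()].
#' @return interval table with a `direction` column.
#' @export
generate_reference_panel <- function(config, genome, cohort) {
  with_substream(config, 303L, {
    priv <- cohort$truth$private_segments
    base <- cohort$truth$common_segments[, c("chrom", "start", "end", "direction")]
    bg <- list()
    while (length(bg) < config$n_reference_background) {
      seg <- random_segment(config, genome)
      same_dir <- priv[priv$direction == seg$direction, , drop = FALSE]
      if (nrow(same_dir)) {
        cover <- max_overlap_fraction(same_dir[, c("chrom", "start", "end")],
                                      cbind(seg[, c("chrom", "start", "end")],
                                            direction = seg$direction))
        if (any(cover > 0.35)) next
      }
      bg[[length(bg) + 1L]] <- seg[, c("chrom", "start", "end", "direction")]
    }
    panel <- rbind(base, do.call(rbind, bg))
    panel <- panel[order(panel$chrom, panel$start), ]
    rownames(panel) <- NULL
    panel
  })
}

#' Generate a synthetic PPI graph with planted structure
#'
#' Erdos-Renyi background over gene symbols, four planted
#' stochastic-block modules, a dense planted core, and a configurable
#' excess of edges between a designated pair of gene sets (the rare-CNV
#' genes and the common-variant candidates) beyond the background rate.
#' Edge confidences are uniform on the configured range.
#'
#' @param config a [synth_config()].
#' @param set_a,set_b designated gene sets (planted cross-connectivity).
#' @param all_genes symbol pool for the node universe.
#' @return list: `edges` (gene_a, gene_b, confidence), `graph`
#'   ([ppi_graph()] of the edges), `truth` (module labels, core labels,
#'   planted excess edge count).
#' @export
generate_ppi <- function(config, set_a, set_b, all_genes) {
  with_substream(config, 404L, {
    pp <- config$ppi
    ab <- unique(c(set_a, set_b))
    filler <- setdiff(all_genes, ab)
    n_fill <- pp$n_nodes - length(ab)
    stopifnot(n_fill >= sum(pp$module_sizes) + pp$core_size)
    nodes <- c(ab, sample(filler, n_fill))
    # the core is drawn from ALL nodes: disease candidate genes belong to
    # the interactome core at their population rate, so the uniform
    # permutation null is fair to the planted sets
    core_nodes <- sample(nodes, pp$core_size)
    pool <- sample(setdiff(nodes, core_nodes))
    module_nodes <- split(pool[seq_len(sum(pp$module_sizes))],
                          rep(seq_along(pp$module_sizes), pp$module_sizes))

    pair_sample <- function(v1, v2 = NULL, p) {
      if (is.null(v2)) {
        pr <- t(utils::combn(v1, 2L))
      } else {
        pr <- as.matrix(expand.grid(v1, v2, stringsAsFactors = FALSE))
      }
      pr[stats::runif(nrow(pr)) < p, , drop = FALSE]
    }

    edges <- pair_sample(nodes, p = pp$background_p)
    for (m in module_nodes) edges <- rbind(edges, pair_sample(m, p = pp$module_p_in))
    edges <- rbind(edges, pair_sample(core_nodes, p = pp$core_density))
    periph <- setdiff(nodes, core_nodes)
    edges <- rbind(edges, pair_sample(core_nodes, periph, p = pp$core_attach_p))
    # planted A-B excess beyond the background rate
    a_only <- setdiff(set_a, set_b); b_only <- setdiff(set_b, set_a)
    excess <- pair_sample(a_only, b_only,
                          p = (pp$cross_excess - 1) * pp$background_p)
    edges <- rbind(edges, excess)

    df <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2],
                     confidence = stats::runif(nrow(edges),
                                               pp$confidence_range[1],
                                               pp$confidence_range[2]),
                     stringsAsFactors = FALSE)
    df <- df[df$gene_a != df$gene_b, ]
    g <- ppi_graph(df, min_confidence = pp$confidence_range[1])
    module_labels <- stats::setNames(
      rep(seq_along(module_nodes), lengths(module_nodes)),
      unlist(module_nodes, use.names = FALSE))
    list(edges = df, graph = g,
         truth = list(module_labels = module_labels,
                      core_nodes = core_nodes, nodes = nodes,
                      n_excess_edges = nrow(excess),
                      set_a = set_a, set_b = set_b))
  })
}

#' Generate a synthetic pathway collection
#'
#' Random gene sets within the testable size bounds plus one planted
#' pathway seeded with a configurable fraction of the designated query
#' gene set.
#'
#' @param config a [synth_config()].
#' @param query_genes the gene set the planted pathway should be enriched
#'   for.
#' @param all_genes symbol pool.
#' @return list: `collection` (GMT-style named list), `planted` (name of
#'   the enriched pathway).
#' @export
generate_pathways <- function(config, query_genes, all_genes) {
  with_substream(config, 505L, {
    pw <- config$pathways
    sizes <- sample(pw$size_range[1]:pw$size_range[2], pw$n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(all_genes, k))
    names(sets) <- sprintf("PATHWAY_%02d", seq_len(pw$n_sets))
    planted <- "PATHWAY_PLANTED_IMMUNE"
    k_q <- max(1L, round(pw$planted_overlap * length(query_genes)))
    seed_genes <- sample(query_genes, k_q)
    fill <- sample(setdiff(all_genes, seed_genes),
                   max(pw$size_range[1], 40L) - k_q)
    sets[[planted]] <- c(seed_genes, fill)
    sets <- lapply(sets, function(s) unique(toupper(s)))
    attr(sets, "source") <- "synthetic"
    list(collection = sets, planted = planted)
  })
}

#' Generate the per-gene common-variant association table
#'
#' Uniform null p-values for every gene, with the designated candidate
#' genes planted strictly below the eQTL selection threshold.
#'
#' @param config a [synth_config()].
#' @param genome output of [generate_genome()].
#' @param avoid genes excluded from candidacy (e.g. to control the overlap
#'   between the CNV and SNP gene sets); one shared gene is kept when
#'   `shared` is given.
#' @param shared optional gene forced into the candidate list (emulating a
#'   gene tagged by both variant classes).
#' @return list: `table` (gene, p_gene, p_eqtl), `candidates`.
#' @export
generate_candidate_table <- function(config, genome, avoid = character(0),
                                     shared = character(0)) {
  with_substream(config, 606L, {
    genes <- genome$genes$gene_id
    n_cand <- config$n_snp_candidates
    cand <- c(shared, sample(setdiff(genes, c(avoid, shared)),
                             n_cand - length(shared)))
    p_eqtl <- stats::runif(length(genes), 5e-3, 1)
    p_eqtl[genes %in% cand] <- stats::runif(length(cand), 1e-6, 4.9e-3)
    tab <- data.frame(gene = genes,
                      p_gene = stats::runif(length(genes)),
                      p_eqtl = p_eqtl, stringsAsFactors = FALSE)
    list(table = tab, candidates = sort(cand))
  })
}

#' Generate the full synthetic bundle
#'
#' Runs every generator off one shared seed (independent substreams) and
#' returns all inputs plus the consolidated ground truth. The designated
#' rare-CNV gene set and common-variant candidate set share exactly one
#' gene, mirroring a locus tagged by both variant classes.
#'
#' @param config a [synth_config()].
#' @return list: `genome`, `cohort`, `calls`, `panel`, `ppi`, `pathways`,
#'   `candidate_table`, `gene_disease_map`, `known_map`, `truth`, `config`.
#' @export
generate_synthetic_bundle <- function(config) {
  genome <- generate_genome(config)
  coh <- generate_cohort(config, genome)
  panel <- generate_reference_panel(config, genome, coh)
  shared_gene <- coh$truth$private_genes[1]
  cand <- generate_candidate_table(config, genome,
                                   avoid = coh$truth$private_genes,
                                   shared = shared_gene)
  ppi <- generate_ppi(config, set_a = coh$truth$private_genes,
                      set_b = cand$candidates,
                      all_genes = genome$genes$gene_id)
  pw <- generate_pathways(config, query_genes = coh$truth$private_genes,
                          all_genes = genome$genes$gene_id)
  truth <- c(coh$truth,
             list(candidates = cand$candidates, shared_gene = shared_gene,
                  ppi = ppi$truth, planted_pathway = pw$planted))
  list(genome = genome, cohort = coh$cohort, calls = coh$calls, panel = panel,
       ppi = ppi, pathways = pw$collection,
       candidate_table = cand$table,
       gene_disease_map = coh$gene_disease_map, known_map = coh$known_map,
       truth = truth, config = config)
}

#' Write a synthetic bundle to disk
#'
#' Emits every input in the dialect its reader expects: per-patient
#' per-caller call files (`calls/<patient>.<caller>.bed`), exon BED, gene
#' table, reference panel TSV, PPI edge TSV, pathway GMT, candidate-gene
#' TSV, phenotype CSV, gene-disease map TSV, and the ground truth as JSON.
#'
#' @param bundle output of [generate_synthetic_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "calls"), recursive = TRUE, showWarnings = FALSE)
  write_exons(bundle$genome$exons, file.path(dir, "exons.bed"))
  utils::write.table(bundle$genome$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_reference_panel(bundle$panel, file.path(dir, "reference_panel.tsv"))
  write_ppi(bundle$ppi$graph, file.path(dir, "ppi.tsv"))
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  utils::write.table(bundle$candidate_table, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_patients(bundle$cohort, file.path(dir, "phenotypes.csv"))
  utils::write.table(bundle$gene_disease_map, file.path(dir, "gene_disease_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (pid in names(bundle$calls)) {
    for (cl in names(bundle$calls[[pid]])) {
      write_cnv_calls(bundle$calls[[pid]][[cl]],
                      file.path(dir, "calls", paste0(pid, ".", cl, ".bed")))
    }
  }
  truth <- bundle$truth
  truth$ppi$graph <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
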