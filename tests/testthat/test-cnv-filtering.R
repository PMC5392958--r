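# Concordance merging, QC rules, privatization, burden test.

test_that("overlap_fraction matches its definition and the base-grid oracle", {
  q <- genomic_intervals("1", 100, 200)
  expect_equal(overlap_fraction(q, genomic_intervals("1", 150, 250)), 0.5)
  expect_equal(overlap_fraction(q, q), 1.0)
  expect_equal(overlap_fraction(q, genomic_intervals("2", 100, 200)), 0.0)

  set.seed(7)
  for (i in 1:200) {
    a <- sort(sample(0:120, 2)); b <- sort(sample(0:120, 2))
    if (a[1] == a[2]) a[2] <- a[2] + 1
    if (b[1] == b[2]) b[2] <- b[2] + 1
    qi <- genomic_intervals("1", a[1], a[2])
    ti <- genomic_intervals(sample(c("1", "2"), 1), b[1], b[2])
    expect_equal(overlap_fraction(qi, ti), oracle_overlap_fraction(qi, ti))
    # symmetry through lengths: f(q,t)|q| == f(t,q)|t|
    expect_equal(overlap_fraction(qi, ti) * (a[2] - a[1]),
                 overlap_fraction(ti, qi) * (b[2] - b[1]))
  }
})

test_that("concordance requires every caller, matching direction, >50% overlap", {
  full <- list(c1 = seg("1", 0, 200000, "DUP", 10, caller = "c1"),
               c2 = seg("1", 1000, 201000, "DUP", 8, caller = "c2"),
               c3 = seg("1", 500, 199000, "DUP", 12, caller = "c3"))
  m <- merge_concordant(full)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1000)                # intersection of supporters
  expect_equal(m$end, 199000)
  expect_equal(m$n_probes, 8)                # minimum across supporters

  # direction mismatch on one caller kills the call
  flip <- full; flip$c3$direction <- "DEL"
  expect_equal(nrow(merge_concordant(flip)), 0L)

  # two of three callers agreeing is not enough
  two <- full; two$c3 <- empty_call_table()
  expect_equal(nrow(merge_concordant(two)), 0L)

  # exactly 50% mutual overlap is not concordant (strict rule)
  half <- list(c1 = seg("1", 0, 100, "DUP"), c2 = seg("1", 50, 150, "DUP"),
               c3 = seg("1", 0, 100, "DUP"))
  expect_equal(nrow(merge_concordant(half)), 0L)

  expect_error(merge_concordant(full[1:2]), "at least 3")
})

test_that("concordance merging agrees with an enumerated oracle on random fixtures", {
  set.seed(11)
  for (rep in 1:25) {
    # per-caller calls are disjoint (spacing > max length), so at most one
    # same-direction call per caller can cover >50% of any anchor and the
    # trio enumeration below is exhaustive
    mk <- function() {
      n <- sample(0:3, 1)
      if (!n) return(empty_call_table())
      st <- sample(seq(0, 2000, by = 250), n)
      seg("1", st, st + sample(c(100, 200), n, TRUE),
          sample(c("DEL", "DUP"), n, TRUE), sample(5:20, n, TRUE))
    }
    calls <- list(c1 = mk(), c2 = mk(), c3 = mk())
    got <- merge_concordant(calls)
    # oracle: a region is concordant iff some triple (one call per caller,
    # same direction) mutually overlaps >50% query-anchored in all
    # directions; expected consensus = triple intersections, deduplicated
    expected <- list()
    if (all(vapply(calls, nrow, 0L) > 0)) {
      for (i in seq_len(nrow(calls$c1))) for (j in seq_len(nrow(calls$c2)))
        for (k in seq_len(nrow(calls$c3))) {
          trio <- rbind(calls$c1[i, ], calls$c2[j, ], calls$c3[k, ])
          if (length(unique(trio$direction)) != 1) next
          ok <- TRUE
          for (x in 1:3) for (y in 1:3) {
            if (x == y) next
            if (oracle_overlap_fraction(trio[x, ], trio[y, ]) <= 0.5) ok <- FALSE
          }
          if (ok) {
            expected[[length(expected) + 1L]] <-
              c(max(trio$start), min(trio$end), trio$direction[1])
          }
        }
    }
    expected <- unique(do.call(rbind, expected))
    expect_equal(nrow(got), if (is.null(expected)) 0L else nrow(expected),
                 info = paste("rep", rep))
    if (nrow(got)) {
      expect_setequal(paste(got$start, got$end, got$direction),
                      paste(expected[, 1], expected[, 2], expected[, 3]))
    }
  }
})

test_that("QC removes short, under-probed and excluded-region segments", {
  cfg <- qc_config()
  segs <- rbind(
    seg("1", 0, 99999, "DEL", 10),            # 1 bp short of 100 kb
    seg("1", 0, 150000, "DUP", 4),            # too few probes
    seg("6", 26000000, 26150000, "DUP", 10),  # fully inside the MHC
    seg("6", 24900000, 25100000, "DUP", 10),  # exactly 50% in the MHC
    seg("2", 0, 100000, "DEL", 5))            # boundary pass
  out <- apply_qc(segs, cfg)
  expect_equal(out$chrom, c("6", "2"))
  expect_equal(out$start, c(24900000, 0))
  expect_equal(attr(out, "qc_log"),
               c(removed_short = 1L, removed_few_probes = 1L,
                 removed_excluded_region = 1L))
  # idempotence
  expect_equal(apply_qc(out, cfg), out, ignore_attr = TRUE)
})

test_that("privatization honours direction, strict threshold, and the quadratic oracle", {
  cfg <- qc_config()
  s <- seg("1", 0, 100, "DEL")
  panel_same <- cbind(genomic_intervals("1", 0, 60), direction = "DEL")
  panel_opp <- cbind(genomic_intervals("1", 0, 90), direction = "DUP")
  expect_false(is_private(s, panel_same, cfg))      # 60% same-direction cover
  expect_true(is_private(s, panel_opp, cfg))        # covered only by a DUP
  expect_true(is_private(s, list(), cfg))           # empty panels
  half <- cbind(genomic_intervals("1", 0, 50), direction = "DEL")
  expect_true(is_private(s, half, cfg))             # exactly 50% stays private

  set.seed(23)
  segs <- seg("1", st <- sample(seq(0, 5000, 10), 200),
              st + sample(c(50, 100, 200), 200, TRUE),
              sample(c("DEL", "DUP"), 200, TRUE))
  ps <- sample(seq(0, 5000, 10), 150)
  panel <- cbind(genomic_intervals(sample(c("1", "2"), 150, TRUE), ps,
                                   ps + sample(c(40, 120, 300), 150, TRUE)),
                 direction = sample(c("DEL", "DUP"), 150, TRUE))
  got <- is_private(segs, panel, cfg)
  expect_equal(got, oracle_is_private(segs, panel))

  # monotone in panels: adding reference intervals only shrinks the private set
  bigger <- rbind(panel, cbind(genomic_intervals("1", 0, 5500), direction = "DEL"))
  expect_true(all(is_private(segs, bigger, cfg) <= got))
})

test_that("private-CNV summaries recount correctly", {
  z <- summarize_private(empty_call_table())
  expect_equal(z$n_cnvs, c(0L, 0L))
  expect_equal(z$mean_length, c(0, 0))

  dels <- seg("1", c(0, 0, 0), c(100000, 200000, 300000), "DEL")
  s <- summarize_private(dels, list(DEL = c("GA", "GB", "GB")))
  del_row <- s[s$direction == "DEL", ]
  expect_equal(del_row$mean_length, 200000)
  expect_equal(del_row$median_length, 200000)
  expect_equal(del_row$n_affected_genes, 2L)

  set.seed(5)
  mix <- seg("1", st <- sample(1:100, 20) * 1000, st + sample(1:5, 20, TRUE) * 100000,
             sample(c("DEL", "DUP"), 20, TRUE))
  s2 <- summarize_private(mix)
  for (d in c("DEL", "DUP")) {
    lens <- (mix$end - mix$start)[mix$direction == d]
    expect_equal(s2$mean_length[s2$direction == d], mean(lens))
    expect_equal(s2$median_length[s2$direction == d], stats::median(lens))
  }
})

test_that("burden test matches the closed-form chi-square", {
  same <- burden_test(c(10, 10), c(10, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  bt <- burden_test(c(20, 10), c(10, 20))
  O <- rbind(c(20, 10), c(10, 20))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(bt$statistic, sum((O - E)^2 / E))
  expect_equal(bt$p_value, stats::pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE))

  swapped <- burden_test(c(10, 20), c(20, 10))
  expect_equal(swapped$p_value, bt$p_value)
  expect_error(burden_test(c(0, 10), c(0, 20)), "margin")
})
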