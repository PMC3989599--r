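test_that("read verdicts: definition cases on both strands", {
  b <- toy_boundary(1000, 1300)          # + strand, donor 1000, acceptor 1300
  blk <- function(...) lapply(list(...), as.integer)
  expect_equal(call_read(data.frame(chrom = "c1", block_start = 975,
                                    block_end = 1025), b), "unspliced")
  spl <- data.frame(chrom = "c1", block_start = c(975, 1300),
                    block_end = c(1000, 1325))
  expect_equal(call_read(spl, b), "spliced")
  mis <- data.frame(chrom = "c1", block_start = c(975, 1308),
                    block_end = c(1000, 1333))
  expect_equal(call_read(mis, b), "mis_spliced")
  ## only 9 exonic nt -> uninformative
  expect_equal(call_read(data.frame(chrom = "c1", block_start = 991,
                                    block_end = 1040), b), "uninformative")
  ## wrong chromosome -> uninformative
  expect_equal(call_read(data.frame(chrom = "c9", block_start = 975,
                                    block_end = 1025), b), "uninformative")
  ## split with only 9 nt beyond the gap -> uninformative
  short <- data.frame(chrom = "c1", block_start = c(975, 1300),
                      block_end = c(1000, 1309))
  expect_equal(call_read(short, b), "uninformative")

  bneg <- toy_boundary(1000, 1300, strand = "-")   # donor 1300
  expect_equal(call_read(data.frame(chrom = "c1", block_start = 1275,
                                    block_end = 1325), bneg), "unspliced")
  spln <- data.frame(chrom = "c1", block_start = c(975, 1300),
                     block_end = c(1000, 1325))
  expect_equal(call_read(spln, bneg), "spliced")
  misn <- data.frame(chrom = "c1", block_start = c(975, 1292),
                     block_end = c(1000, 1317))
  ## gap [1000,1292) starts at the minus-strand acceptor side; gap end is not
  ## the donor junction 1300 -> not an informative split, no intron coverage
  expect_equal(call_read(misn, bneg), "uninformative")
  misn2 <- data.frame(chrom = "c1", block_start = c(975, 1300),
                      block_end = c(992, 1325))
  expect_equal(call_read(misn2, bneg), "mis_spliced")
})

test_that("verdicts agree exactly with the brute-force oracle (sweep)", {
  ## toy two-exon gene: exon [900,1000) intron [1000,1060) exon [1060,1200)
  for (strand in c("+", "-")) {
    b <- toy_boundary(1000, 1060, strand = strand)
    placements <- list()
    for (s in seq(950, 1120, by = 1L)) {       # unsplit, length 40
      placements[[length(placements) + 1L]] <- list(c(s, s + 40L))
    }
    for (s in seq(950, 1000, by = 1L)) {       # splits with varying gap ends
      for (gap_end in c(1060L, 1052L, 1068L)) {
        placements[[length(placements) + 1L]] <-
          list(c(s, s + 20L), c(gap_end, gap_end + 30L))
      }
    }
    for (pl in placements) {
      pl <- lapply(pl, as.integer)
      ## skip degenerate split placements whose first block crosses the gap
      if (length(pl) == 2L && pl[[1L]][2L] > pl[[2L]][1L]) next
      blocks <- data.frame(
        chrom = "c1",
        block_start = vapply(pl, `[`, integer(1), 1L),
        block_end = vapply(pl, `[`, integer(1), 2L))
      expect_equal(call_read(blocks, b), oracle_verdict(pl, b),
                   info = paste(strand, paste(unlist(pl), collapse = ",")))
    }
  }
})

test_that("intron size bins split at 100 and 500 inclusively", {
  expect_equal(as.character(bin_intron_size(c(99L, 100L, 500L, 501L))),
               c("lt100", "100to500", "100to500", "gt500"))
  set.seed(12)
  lens <- sample(1:2000, 500, TRUE)
  bins <- bin_intron_size(lens)
  expect_false(anyNA(bins))
  expect_equal(as.integer(table(bins)),
               c(sum(lens < 100), sum(lens >= 100 & lens <= 500),
                 sum(lens > 500)))
})

test_that("boundary tallies: thresholds, merging and denominators", {
  b <- toy_boundary(1000, 1300)
  unsplit <- function(id, mate = 1L)
    data.table::data.table(aln_id = NA_integer_, read_id = id, mate = mate,
                           chrom = "c1", block_start = 975L,
                           block_end = 1025L)
  spliced <- function(id, mate = 1L)
    data.table::data.table(aln_id = NA_integer_, read_id = id, mate = mate,
                           chrom = "c1",
                           block_start = c(975L, 1300L),
                           block_end = c(1000L, 1325L))
  mk <- function(dts) {
    x <- data.table::rbindlist(dts)
    x[, aln_id := .GRP, by = .(read_id, mate)]
    data.table::setkey(x, chrom, block_start, block_end)
    x
  }
  ## 9 informative fragments -> not informative; 10 -> informative
  a9 <- mk(lapply(1:9, function(i) spliced(paste0("r", i))))
  t9 <- tally_boundary(a9, b)
  expect_false(t9$informative)
  expect_true(is.na(t9$retention_pct))
  a10 <- mk(lapply(1:10, function(i) spliced(paste0("r", i))))
  t10 <- tally_boundary(a10, b)
  expect_true(t10$informative)
  expect_equal(t10$retention_pct, 0)

  ## mates with one informative verdict merge; two mates of one fragment
  ## count once
  a_pair <- mk(list(unsplit("r1", 1L), unsplit("r1", 2L),
                    spliced("r2", 1L),
                    unsplit("r3", 1L)))
  t_pair <- tally_boundary(a_pair, b, min_fragments = 1L)
  expect_equal(t_pair$n_unspliced, 2L)
  expect_equal(t_pair$n_spliced, 1L)
  expect_equal(t_pair$retention_pct, 100 * 2 / 3)

  ## conflicting informative mate verdicts discard the fragment
  a_conf <- mk(list(unsplit("r1", 1L), spliced("r1", 2L),
                    spliced("r2", 1L)))
  t_conf <- tally_boundary(a_conf, b, min_fragments = 1L)
  expect_equal(t_conf$n_spliced, 1L)
  expect_equal(t_conf$n_unspliced, 0L)
  expect_equal(attr(t_conf, "n_conflict"), 1L)

  ## mis-spliced fragments count toward informativeness but not retention
  mis <- function(id) data.table::data.table(
    aln_id = NA_integer_, read_id = id, mate = 1L, chrom = "c1",
    block_start = c(975L, 1310L), block_end = c(1000L, 1335L))
  a_mix <- mk(c(lapply(1:8, function(i) mis(paste0("m", i))),
                list(spliced("s1"), unsplit("u1"))))
  t_mix <- tally_boundary(a_mix, b)
  expect_true(t_mix$informative)           # 10 informative fragments
  expect_equal(t_mix$n_mis_spliced, 8L)
  expect_equal(t_mix$retention_pct, 50)    # 1 / (1 + 1)

  ## retention invariant under uniform duplication of all fragments
  a_dup <- mk(c(lapply(1:6, function(i) spliced(paste0("r", i))),
                lapply(1:6, function(i) unsplit(paste0("q", i)))))
  t1 <- tally_boundary(a_dup, b)
  dup <- data.table::copy(a_dup)[, read_id := paste0(read_id, "_dup")]
  dup[, aln_id := aln_id + max(a_dup$aln_id)]
  both <- mk(list(a_dup, dup))
  t2 <- tally_boundary(both, b)
  expect_equal(t2$retention_pct, t1$retention_pct)
  expect_equal(t2$n_spliced, 2L * t1$n_spliced)
})

test_that("verdict partition: counts sum to reads examined", {
  set.seed(31)
  world <- generate_world(sim_config(
    n_genes = c(maternal = 4L, early_zygotic = 4L),
    target_fragments = 80L, seed = 31L))
  b <- extract_boundaries(world$models)
  calls <- irquant:::read_calls(world$alignments, b)
  per_b <- calls[, .N, by = .(boundary_id, verdict)]
  totals <- per_b[, sum(N), by = boundary_id]
  expect_equal(per_b[, sum(N)], nrow(calls))
  expect_true(all(calls$verdict %in% c("spliced", "unspliced", "mis_spliced",
                                       "uninformative")))
})

test_that("retention table stratifies and summarises correctly", {
  tl <- data.table::data.table(
    boundary_id = sprintf("b%02d", 1:10),
    gene_id = rep(c("gz", "gm"), each = 5L),
    intron_len = c(50L, 99L, 100L, 500L, 501L, 80L, 200L, 600L, 90L, 400L),
    n_spliced = 10L, n_unspliced = 10L, n_mis_spliced = 0L,
    retention_pct = c(0, 10, 20, 30, 40, 0, 0, 0, 0, 0),
    informative = TRUE)
  gc <- data.table::data.table(
    gene_id = c("gz", "gm"),
    gene_class = factor(c("early_zygotic", "maternal"),
                        levels = levels(classify_gene(0, 20))))
  rt <- build_retention_table(tl, gc)
  expect_equal(nrow(rt$rows), 10L)
  expect_equal(as.character(rt$rows$size_bin[1:5]),
               c("lt100", "lt100", "100to500", "100to500", "gt500"))
  ## single stratum arithmetic: {0,10,20,30,40}
  one <- build_retention_table(
    tl[1:5][, intron_len := 200L], gc)
  s <- one$summaries
  expect_equal(s$median, 20)
  expect_equal(s$q1, 10)
  expect_equal(s$q3, 30)
  ## maternal stratum medians all zero
  ms <- rt$summaries[gene_class == "maternal"]
  expect_true(all(ms$median == 0))

  ## unknown gene -> unclassified stratum with a warning, never dropped
  tl2 <- data.table::copy(tl)[1, gene_id := "gMystery"]
  expect_warning(rt2 <- build_retention_table(tl2, gc), "no expression")
  expect_equal(nrow(rt2$rows), 10L)
  expect_equal(as.character(rt2$rows[gene_id == "gMystery", gene_class]),
               "unclassified")
})

test_that("parameter recovery: estimates track truth retention (scaled)", {
  ## scaled-down version of the acceptance sweep: 1 safe boundary per world
  ## at each truth level, ~200 informative fragments
  levels_p <- c(0, 0.1, 0.3, 0.5, 0.9)
  est <- numeric(0); tru <- numeric(0)
  for (i in seq_along(levels_p)) {
    w <- generate_world(sim_config(
      n_genes = c(maternal = 3L), intronless_frac = 0, max_introns = 1L,
      retention_levels = levels_p[i], mis_splice_rate = 0,
      frag_mean = 150, frag_sd = 15, target_fragments = 200L,
      seed = 300L + i))
    safe <- filter_safe(extract_boundaries(w$models), w$models)
    t <- tally_boundaries(w$alignments, safe)
    t <- t[informative == TRUE & !is.na(retention_pct)]
    est <- c(est, t$retention_pct)
    tru <- c(tru, rep(100 * levels_p[i], nrow(t)))
  }
  expect_lt(mean(abs(est - tru)), 3)
  pooled <- tapply(est, tru, mean)
  expect_true(all(diff(pooled[order(as.numeric(names(pooled)))]) > 0))
})
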