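test_that("GTF parsing converts coordinates and handles edge cases", {
  gtf <- c(
    'c1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'c1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    'c1\tsrc\tCDS\t10\t90\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";',
    '# a comment',
    'c1\tsrc\texon\t201\t300\t.\t+\t.\tgene_id "gA"; transcript_id "gA.t1";')
  m <- parse_gene_models(text = gtf)
  expect_equal(nrow(m$exons), 2L)            # CDS ignored, duplicate collapsed
  expect_equal(m$exons$start, c(0L, 200L))
  expect_equal(m$exons$end, c(100L, 300L))

  expect_equal(n_genes(parse_gene_models(text = character(0))), 0L)

  expect_error(parse_gene_models(text = "c1\tsrc\texon\t5"),
               "malformed GTF line 1")
  bad <- 'c1\tsrc\texon\t50\t10\t.\t+\t.\tgene_id "g"; transcript_id "t";'
  expect_error(parse_gene_models(text = bad), "end < start")
  noattr <- 'c1\tsrc\texon\t1\t9\t.\t+\t.\tgene_id "g";'
  expect_error(parse_gene_models(text = noattr), "transcript_id")
})

test_that("GTF round-trips the generator's truth structure", {
  world <- generate_world(sim_config(
    n_genes = c(maternal = 2L, early_zygotic = 1L), seed = 11L,
    target_fragments = 1L))
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(world$models, path)
  back <- parse_gene_models(path)
  a <- data.table::setkey(data.table::copy(world$models$exons),
                          gene_id, transcript_id, start, end)
  b <- data.table::setkey(data.table::copy(back$exons),
                          gene_id, transcript_id, start, end)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("exon table validation rejects bad structures", {
  expect_error(gene_model_set(ex_tab("g", "t", 0, 10, strand = "*")),
               "strand")
  expect_error(gene_model_set(ex_tab("g", "t", c(0, 5), c(10, 40))),
               "overlapping exons")
  expect_error(gene_model_set(ex_tab("g", "t", 10, 10)), "end <= start")
})

test_that("boundary extraction matches definition cases", {
  m <- gene_model_set(ex_tab("gA", "gA.t1", c(0, 200), c(100, 300)))
  b <- extract_boundaries(m)
  expect_equal(nrow(b), 1L)
  expect_equal(b$intron_len, 100L)
  expect_equal(b$donor, 100L)
  expect_equal(b$acceptor, 200L)
  expect_equal(b$up_exon_len, 100L)

  ## two transcripts sharing the intron -> one boundary; flank lengths are
  ## the minima across sharing transcripts
  m2 <- gene_model_set(rbind(
    ex_tab("gA", "gA.t1", c(0, 200), c(100, 300)),
    ex_tab("gA", "gA.t2", c(40, 200), c(100, 260))))
  b2 <- extract_boundaries(m2)
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$up_exon_len, 60L)
  expect_equal(b2$down_exon_len, 60L)

  ## minus strand: donor is the genomic right edge of the intron
  m3 <- gene_model_set(ex_tab("gB", "gB.t1", c(0, 200), c(100, 300),
                              strand = "-"))
  b3 <- extract_boundaries(m3)
  expect_equal(b3$donor, 200L)
  expect_equal(b3$acceptor, 100L)
  expect_equal(b3$up_exon_len, 100L)

  ## intronless transcripts contribute nothing
  expect_equal(nrow(extract_boundaries(
    gene_model_set(ex_tab("gC", "gC.t1", 0, 500)))), 0L)
})

test_that("boundary extraction equals brute-force enumeration (property)", {
  set.seed(42)
  for (rep in 1:100) {
    m <- random_models(n_genes = sample(2:12, 1L))
    b <- extract_boundaries(m)
    got <- sort(paste(b$chrom, b$intron_start, b$intron_end, b$strand,
                      sep = ":"))
    expect_identical(got, oracle_boundaries(m))
  }
})

test_that("safe filter removes intron/exon overlaps and is idempotent", {
  ## nested gene B inside A's intron
  m <- gene_model_set(rbind(
    ex_tab("gA", "gA.t1", c(0, 500), c(100, 600)),
    ex_tab("gB", "gB.t1", 200, 300, strand = "-")))
  b <- extract_boundaries(m)
  s <- filter_safe(b, m)
  expect_equal(nrow(s), 0L)

  ## isolated gene keeps all boundaries
  m2 <- gene_model_set(ex_tab("gA", "gA.t1", c(0, 200, 400),
                              c(100, 300, 500)))
  b2 <- extract_boundaries(m2)
  s2 <- filter_safe(b2, m2)
  expect_equal(nrow(s2), 2L)
  expect_true(all(s2$safe))

  ## alternative 5'SS: t1's exon extends into t2's intron -> t2's boundary
  ## removed, t1's kept
  m3 <- gene_model_set(rbind(
    ex_tab("gA", "gA.t1", c(0, 200), c(150, 300)),
    ex_tab("gA", "gA.t2", c(0, 200), c(100, 300))))
  b3 <- extract_boundaries(m3)
  s3 <- filter_safe(b3, m3)
  expect_equal(nrow(b3), 2L)
  expect_equal(s3$intron_start, 150L)

  ## idempotence + shrink-only, against the brute-force oracle
  set.seed(7)
  for (rep in 1:25) {
    m <- random_models(n_genes = 8L)
    b <- extract_boundaries(m)
    s <- filter_safe(b, m)
    expect_lte(nrow(s), nrow(b))
    expect_identical(boundary_key(s), boundary_key(b)[oracle_safe(b, m)])
    s_again <- filter_safe(s, m)
    expect_identical(boundary_key(s_again), boundary_key(s))
  }
})

test_that("minimum flank filter uses >= threshold", {
  b <- data.table::rbindlist(list(
    toy_boundary(100, 149, up = 50, down = 50),     # intron 49
    toy_boundary(300, 350, up = 50, down = 50),     # intron 50
    toy_boundary(600, 700, up = 49, down = 50),     # exon 49
    toy_boundary(900, 1000, up = 50, down = 49)))   # exon 49
  kept <- filter_min_flank(b)
  expect_equal(kept$intron_start, 300L)
  expect_equal(nrow(filter_min_flank(b, min_len = 0L)), 4L)

  set.seed(3)
  lens <- data.table::data.table(
    i = sample(20:200, 50, TRUE), u = sample(20:200, 50, TRUE),
    d = sample(20:200, 50, TRUE))
  b2 <- data.table::rbindlist(lapply(seq_len(50), function(k)
    toy_boundary(1000 * k, 1000 * k + lens$i[k], up = lens$u[k],
                 down = lens$d[k])))
  expect_equal(
    boundary_key(filter_min_flank(b2)),
    boundary_key(b2[lens$i >= 50 & lens$u >= 50 & lens$d >= 50]))
})

test_that("structure profile: limiting cases and per-base oracle", {
  ## intronless genes -> exactly 100 everywhere
  m <- gene_model_set(data.table::rbindlist(lapply(1:5, function(i)
    ex_tab(paste0("g", i), paste0("g", i, ".t1"),
           5000 * i, 5000 * i + 1200 + 7 * i))))
  p <- structure_profile(m)
  expect_equal(p$freq, rep(100, 1000))

  ## one gene, exon covering exactly the first half
  m2 <- gene_model_set(ex_tab("g1", "g1.t1", c(0, 1990), c(1000, 2000)))
  p2 <- structure_profile(m2)
  expect_equal(p2$freq[1:500], rep(100, 500))
  expect_equal(p2$freq[501:994], rep(0, 494))

  ## minus strand is 5'->3' flipped
  m3 <- gene_model_set(ex_tab("g1", "g1.t1", c(0, 1990), c(1000, 2000),
                              strand = "-"))
  p3 <- structure_profile(m3)
  expect_equal(p3$freq, rev(p2$freq))

  ## random structures match the rasterising oracle
  set.seed(19)
  for (rep in 1:5) {
    m4 <- random_models(n_genes = 12L, max_introns = 5L)
    n_seg <- 50L
    got <- suppressWarnings(structure_profile(m4, n_seg))
    expect_equal(got$freq, oracle_structure(m4, n_seg))
  }

  ## short genes are skipped with a warning; empty set errors
  m5 <- gene_model_set(rbind(ex_tab("g1", "t1", 0, 400),
                             ex_tab("g2", "t2", 1000, 2200)))
  expect_warning(p5 <- structure_profile(m5), "skipped")
  expect_equal(p5$n_genes, 1L)
  expect_error(structure_profile(
    gene_model_set(m5$exons[0])), "empty")
})

test_that("boundary motifs: canonical sites, IC bounds, dropped sequences", {
  ## hand-built genome: gene + strand, exon [0,20) intron [20,48) exon [48,68)
  intron <- paste0("GT", strrep("A", 24), "AG")
  genome <- c(c1 = paste0(strrep("C", 20), intron, strrep("C", 20)))
  m <- gene_model_set(ex_tab("g1", "t1", c(0, 48), c(20, 68)))
  b <- extract_boundaries(m)
  mm <- boundary_motifs(genome, b)
  expect_equal(dim(mm$donor$counts), c(4L, 9L))
  ## exonic positions 1-3 are C; intronic 4-5 are G,T
  expect_equal(unname(mm$donor$counts["C", 1:3]), rep(1L, 3))
  expect_equal(unname(mm$donor$counts["G", 4L]), 1L)
  expect_equal(unname(mm$donor$counts["T", 5L]), 1L)
  ## acceptor window: 6 intronic then 3 exonic; intronic end is A,G
  expect_equal(unname(mm$acceptor$counts["A", 5L]), 1L)
  expect_equal(unname(mm$acceptor$counts["G", 6L]), 1L)
  ## single sequence -> IC exactly 2 everywhere
  expect_equal(mm$donor$info_content, rep(2, 9))

  ## minus-strand gene gives the same transcript-sense motif
  mneg <- gene_model_set(ex_tab("g1", "t1", c(0, 48), c(20, 68),
                                strand = "-"))
  bneg <- extract_boundaries(mneg)
  rc <- unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genome))))
  mm_neg <- boundary_motifs(c(c1 = rc), bneg)
  expect_equal(mm_neg$donor$counts, mm$donor$counts)
  expect_equal(mm_neg$acceptor$counts, mm$acceptor$counts)

  expect_error(boundary_motifs(genome, toy_boundary(10, 40, chrom = "cX")),
               "cX")

  ## N in window -> dropped and counted
  genome_n <- c(c1 = paste0(strrep("C", 19), "N", intron, strrep("C", 20)))
  mm_n <- boundary_motifs(genome_n, b)
  expect_equal(mm_n$donor$n_dropped, 1L)
  expect_equal(mm_n$acceptor$n_dropped, 0L)
})

test_that("motif matrices on the synthetic world match generator truth", {
  world <- generate_world(sim_config(
    n_genes = c(maternal = 30L), noncanonical_frac = 0.1,
    target_fragments = 1L, seed = 23L))
  b <- extract_boundaries(world$models)
  mm <- boundary_motifs(world$genome, b)
  ## column sums constant and equal to sequence count
  expect_true(all(colSums(mm$donor$counts) == mm$donor$n_seqs))
  expect_true(all(mm$donor$info_content >= 0 & mm$donor$info_content <= 2))
  ## canonical fraction at donor +1/+2 close to the configured 90%
  gt_frac <- mm$donor$counts["G", 4L] / mm$donor$n_seqs
  expect_gt(gt_frac, 0.75)
  ## acceptor is always canonical AG in the generator
  expect_equal(unname(mm$acceptor$counts["A", 5L]), mm$acceptor$n_seqs)
  expect_equal(unname(mm$acceptor$counts["G", 6L]), mm$acceptor$n_seqs)
})
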