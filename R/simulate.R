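## Seeded synthetic world: genome, gene models, expression table and
## paired-end split alignments with known per-boundary retention truth.
##
## Draw order under the single seeded RNG stream (documented so worlds are
## reproducible across versions): (1) genome bases per chromosome, (2) gene
## structures in gene order, (3) expression units in gene order, (4)
## per-boundary retention truth in boundary order, (5) fragments gene by
## gene (isoform states, fragment lengths, start positions).
##
## Alignments are emitted directly -- the simulator writes the split-block
## structure itself; no mapper is involved.  Unspliced fragments from
## retained precursors may still miss the junction: informativeness is
## emergent from uniform fragment placement, never forced.

#' Simulation configuration
#'
#' Defaults describe the stated desk-scale world: 50 genes (20 maternal, 20
#' early-zygotic, 5 excluded-high, 5 unclassified), 100 bp paired-end reads
#' (fragment length 250 +/- 30), a target of 500 informative fragments per
#' boundary, per-boundary truth retention drawn uniformly from
#' {0, 0.1, 0.3, 0.5, 0.9}, introns spread over the three size bins
#' (<100, 100-500, >500 bp), canonical GT..AG splice sites, and a 2%
#' mis-splice rate.
#'
#' @param n_genes Named integer vector of gene counts per class.
#' @param intronless_frac Fraction of intronless (single-exon) genes per
#'   class.
#' @param max_introns Maximum introns per gene (1..max drawn uniformly).
#' @param exon_len_range,intron_len_ranges Exon length range; list of intron
#'   length ranges, one per size bin (a bin is picked uniformly).
#' @param retention_levels Truth retention values drawn uniformly per
#'   boundary.
#' @param mis_splice_rate Probability a spliced intron is excised at a wrong
#'   acceptor (15 nt into the downstream exon).
#' @param noncanonical_frac Fraction of introns given non-canonical (non-GT)
#'   donor dinucleotides.
#' @param read_len,frag_mean,frag_sd Read and fragment-length model (nt).
#' @param target_fragments Target informative fragments per boundary.
#' @param min_overlap Junction overlap the downstream analysis will use;
#'   only validated against the read length here.
#' @param seed Integer seed fixing all draws.
#' @param read_seed Optional separate seed for the fragment draws; with a
#'   fixed `seed`, varying `read_seed` changes the reads but not the genome,
#'   gene models, expression table or retention truth.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = c(maternal = 20L, early_zygotic = 20L,
                                   excluded_high = 5L, unclassified = 5L),
                       intronless_frac = 0.1,
                       max_introns = 3L,
                       exon_len_range = c(100L, 400L),
                       intron_len_ranges = list(c(60L, 99L), c(100L, 500L),
                                                c(501L, 1500L)),
                       retention_levels = c(0, 0.1, 0.3, 0.5, 0.9),
                       mis_splice_rate = 0.02,
                       noncanonical_frac = 0,
                       read_len = 100L, frag_mean = 250, frag_sd = 30,
                       target_fragments = 500L,
                       min_overlap = 10L,
                       seed = 1L, read_seed = NULL) {
  stopifnot(all(n_genes >= 0L), sum(n_genes) > 0L,
            all(names(n_genes) %in% gene_class_levels),
            intronless_frac >= 0, intronless_frac <= 1,
            mis_splice_rate >= 0, mis_splice_rate <= 1,
            noncanonical_frac >= 0, noncanonical_frac <= 1,
            all(retention_levels >= 0), all(retention_levels <= 1),
            read_len > 0L, frag_mean >= read_len, target_fragments > 0L)
  if (read_len < 2L * min_overlap) {
    stop("config error: reads shorter than twice the junction overlap (",
         2L * min_overlap, " nt) can never be informative")
  }
  structure(list(
    n_genes = n_genes, intronless_frac = intronless_frac,
    max_introns = max_introns, exon_len_range = exon_len_range,
    intron_len_ranges = intron_len_ranges,
    retention_levels = retention_levels,
    mis_splice_rate = mis_splice_rate,
    noncanonical_frac = noncanonical_frac,
    read_len = as.integer(read_len), frag_mean = frag_mean,
    frag_sd = frag_sd, target_fragments = as.integer(target_fragments),
    min_overlap = as.integer(min_overlap), seed = as.integer(seed),
    read_seed = if (!is.null(read_seed)) as.integer(read_seed)),
    class = "SimConfig")
}

expr_ranges <- list(
  ## class-conditional draws kept well away from the 10 / 5x / 50 / 1000
  ## thresholds so truth recovery is exact
  early_zygotic = list(e02 = c(0, 2), e24 = c(20, 500)),
  maternal = list(e02 = c(60, 800), e24 = c(0, 200)),
  excluded_high = list(e02 = c(1200, 5000), e24 = c(0, 500)),
  unclassified = list(e02 = c(5, 40), e24 = c(0, 8)))

runif_int <- function(n, lo, hi) {
  as.integer(floor(runif(n, lo, hi + 1)))
}

## transcript-sense "first n nt" of a genomic segment
seg_head_interval <- function(g0, g1, strand, n) {
  if (strand == "+") c(g0, g0 + n) else c(g1 - n, g1)
}

#' Generate a synthetic world
#'
#' Builds genome (FASTA-ready `DNAStringSet`), gene models, stage-expression
#' table and paired-end split alignments with per-boundary retention truth.
#' The world always contains at least one nested gene (a single-exon gene
#' inside another gene's intron, making that boundary unsafe) and, when the
#' intronless fraction allows, intronless genes.  About 30% of multi-exon
#' genes carry a duplicated second transcript (exercising boundary
#' deduplication).
#'
#' @param cfg A `SimConfig` from [sim_config()].
#' @return List of class `SimWorld`: `models` (GeneModelSet), `genome`
#'   (DNAStringSet), `expression` (data.table), `alignments`
#'   (ReadAlignments), `truth` (list: `genes`, `boundaries`, `fragments`),
#'   `config`.
#' @export
generate_world <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  rl <- cfg$read_len
  classes <- rep(names(cfg$n_genes), cfg$n_genes)
  n_tot <- length(classes)
  gene_ids <- sprintf("g%03d", seq_len(n_tot))

  ## ---- gene structures ----------------------------------------------------
  chrom <- "chrS1"
  cursor <- 500L
  exon_rows <- list()
  gene_meta <- list()   # per gene: segments in transcript order
  intronless <- runif(n_tot) < cfg$intronless_frac
  intronless[1L] <- FALSE      # gene 1 hosts the nested gene
  ## terminal exons are long enough that no junction sits within a fragment
  ## length of a template end: junction-overlap windows are then identical
  ## across isoforms and retention estimates are unbiased (no edge effects)
  term_exon <- as.integer(ceiling(cfg$frag_mean + 4 * cfg$frag_sd))

  for (i in seq_len(n_tot)) {
    n_introns <- if (intronless[i]) 0L else runif_int(1L, 1L, cfg$max_introns)
    n_exons <- n_introns + 1L
    ex_len <- runif_int(n_exons, cfg$exon_len_range[1L], cfg$exon_len_range[2L])
    ex_len[1L] <- runif_int(1L, term_exon, term_exon + 150L)
    ex_len[n_exons] <- runif_int(1L, term_exon, term_exon + 150L)
    if (n_introns > 0L) {
      bins <- runif_int(n_introns, 1L, length(cfg$intron_len_ranges))
      in_len <- vapply(bins, function(b) {
        r <- cfg$intron_len_ranges[[b]]
        runif_int(1L, r[1L], r[2L])
      }, integer(1))
    } else {
      in_len <- integer(0)
    }
    if (i == 1L) {            # host gene: first intron long enough to nest
      n_introns <- max(n_introns, 1L)
      n_exons <- n_introns + 1L
      if (length(ex_len) < n_exons) ex_len <- c(ex_len, 200L)
      in_len <- c(800L, in_len[-1L])
    }
    strand <- sample(c("+", "-"), 1L)
    seg_len <- integer(0)
    seg_kind <- character(0)
    for (k in seq_len(n_exons)) {
      seg_len <- c(seg_len, ex_len[k])
      seg_kind <- c(seg_kind, "exon")
      if (k <= n_introns) {
        seg_len <- c(seg_len, in_len[k])
        seg_kind <- c(seg_kind, "intron")
      }
    }
    glen <- sum(seg_len)
    ## genomic layout: segments left->right; transcript order follows strand
    g0 <- cursor
    segs <- data.table(kind = seg_kind, len = seg_len)
    segs[, gend := g0 + cumsum(len)]
    segs[, gstart := gend - len]
    if (strand == "-") segs <- segs[rev(seq_len(.N))]   # transcript order
    gene_meta[[i]] <- list(gene_id = gene_ids[i], chrom = chrom,
                           strand = strand, segs = segs)
    tid <- paste0(gene_ids[i], ".t1")
    exon_rows[[length(exon_rows) + 1L]] <- data.table(
      gene_id = gene_ids[i], transcript_id = tid, chrom = chrom,
      strand = strand, start = segs[kind == "exon", gstart],
      end = segs[kind == "exon", gend])
    if (n_introns > 0L && runif(1) < 0.3) {   # duplicated transcript
      exon_rows[[length(exon_rows) + 1L]] <- copy(
        exon_rows[[length(exon_rows)]])[, transcript_id := paste0(gene_ids[i], ".t2")]
    }
    cursor <- cursor + glen + 500L
  }

  ## nested single-exon gene inside gene 1's largest intron
  host <- gene_meta[[1L]]
  host_intron <- host$segs[kind == "intron"][which.max(len)]
  nest_start <- host_intron$gstart + 100L
  nest_id <- "gNest"
  exon_rows[[length(exon_rows) + 1L]] <- data.table(
    gene_id = nest_id, transcript_id = "gNest.t1", chrom = chrom,
    strand = "+", start = nest_start, end = nest_start + 150L)
  gene_meta[[n_tot + 1L]] <- list(
    gene_id = nest_id, chrom = chrom, strand = "+",
    segs = data.table(kind = "exon", len = 150L,
                      gstart = nest_start, gend = nest_start + 150L))
  classes <- c(classes, "maternal")
  gene_ids <- c(gene_ids, nest_id)

  models <- gene_model_set(rbindlist(exon_rows))
  genome_len <- cursor + 500L
  genome_chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  ## stamp splice-site motifs (transcript sense GT..AG) onto the genome
  for (gm in gene_meta) {
    introns <- gm$segs[kind == "intron"]
    for (j in seq_len(nrow(introns))) {
      canonical <- runif(1) >= cfg$noncanonical_frac
      don <- if (canonical) c("G", "T") else sample(c("C", "A", "T"), 2L, TRUE)
      acc <- c("A", "G")
      g0 <- introns$gstart[j]; g1 <- introns$gend[j]
      if (gm$strand == "+") {
        genome_chars[(g0 + 1L):(g0 + 2L)] <- don
        genome_chars[(g1 - 1L):g1] <- acc
      } else {
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        genome_chars[(g1 - 1L):g1] <- rev(comp[don])
        genome_chars[(g0 + 1L):(g0 + 2L)] <- rev(comp[acc])
      }
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(
    paste(genome_chars, collapse = ""), chrom))

  ## ---- expression table ---------------------------------------------------
  expression <- rbindlist(lapply(seq_along(gene_ids), function(i) {
    r <- expr_ranges[[classes[i]]]
    data.table(gene_id = gene_ids[i],
               expr_0_2 = round(runif(1, r$e02[1L], r$e02[2L]), 2),
               expr_2_4 = round(runif(1, r$e24[1L], r$e24[2L]), 2))
  }))

  ## ---- boundary truth -----------------------------------------------------
  boundaries <- extract_boundaries(models)
  bkey <- boundary_key(boundaries)
  truth_b <- data.table(
    boundary_id = bkey, gene_id = boundaries$gene_id,
    chrom = boundaries$chrom, strand = boundaries$strand,
    intron_start = boundaries$intron_start,
    intron_end = boundaries$intron_end,
    truth_p = sample(cfg$retention_levels, nrow(boundaries), replace = TRUE),
    truth_eps = cfg$mis_splice_rate)

  ## ---- fragments ----------------------------------------------------------
  if (!is.null(cfg$read_seed)) set.seed(cfg$read_seed)
  all_blocks <- list()
  frag_truth <- list()
  aln_counter <- 0L
  for (i in seq_along(gene_meta)) {
    gm <- gene_meta[[i]]
    sim <- simulate_gene_fragments(gm, truth_b, cfg, aln_counter)
    aln_counter <- aln_counter + sim$n_alignments
    all_blocks[[i]] <- sim$blocks
    frag_truth[[i]] <- sim$fragments
  }
  blocks <- rbindlist(all_blocks)
  setkey(blocks, chrom, block_start, block_end)
  alignments <- structure(blocks,
                          class = c("ReadAlignments", "data.table",
                                    "data.frame"))
  structure(list(
    models = models, genome = genome, expression = expression,
    alignments = alignments,
    truth = list(
      genes = data.table(gene_id = gene_ids,
                         gene_class = factor(classes,
                                             levels = gene_class_levels)),
      boundaries = truth_b, fragments = rbindlist(frag_truth)),
    config = cfg), class = "SimWorld")
}

## Per-gene fragment simulation; returns blocks table + fragment truth.
##
## Sampling model: a molecule's isoform is the per-intron state vector
## (retained with probability p, else spliced, rerouted to a wrong acceptor
## with probability eps), and fragments are produced at a constant rate per
## template nt -- a molecule contributes fragments in proportion to its
## length.  Implemented as a per-fragment isoform draw followed by
## length-proportional thinning, which makes the verdict proportions of
## junction-overlapping fragments match the per-intron truth exactly (the
## informative window has the same width on every isoform).
simulate_gene_fragments <- function(gm, truth_b, cfg, aln_offset) {
  rl <- cfg$read_len
  segs <- copy(gm$segs)
  segs[, seg_id := .I]
  introns <- segs[kind == "intron"]
  ## match transcript introns to truth rows by genomic coordinates
  if (nrow(introns) > 0L) {
    ikey <- paste(gm$chrom, introns$gstart, introns$gend, gm$strand, sep = ":")
    p <- truth_b[match(ikey, boundary_id), truth_p]
    eps <- truth_b[match(ikey, boundary_id), truth_eps]
  } else {
    p <- numeric(0); eps <- numeric(0)
  }
  L_all <- segs[, sum(len)]          # full precursor, longest template
  w_inf <- 2 * (rl - 2L * cfg$min_overlap + 1L)
  n_frags <- max(cfg$target_fragments,
                 ceiling(cfg$target_fragments * (L_all - cfg$frag_mean + 1) /
                           w_inf))
  k <- nrow(introns)
  ## per-fragment, per-intron state: R retained / S spliced / M mis-spliced
  if (k > 0L) {
    states <- matrix("S", nrow = n_frags, ncol = k)
    for (j in seq_len(k)) {
      u <- runif(n_frags)
      states[, j] <- fifelse(u < p[j], "R",
                             fifelse(u < p[j] + (1 - p[j]) * eps[j], "M", "S"))
    }
    pattern <- apply(states, 1L, paste, collapse = "")
  } else {
    pattern <- rep("", n_frags)
  }
  flen <- as.integer(round(rnorm(n_frags, cfg$frag_mean, cfg$frag_sd)))
  u_start <- runif(n_frags)
  u_keep <- runif(n_frags)

  out_blocks <- list()
  out_frags <- list()
  frag_idx <- 0L
  for (pat in unique(pattern)) {
    sel <- which(pattern == pat)
    iso <- isoform_segmap(segs, pat, gm$strand)
    L <- iso[, sum(tlen)]
    fl <- pmin(pmax(flen[sel], rl), L)
    ## length-proportional thinning (see header comment)
    keep <- u_keep[sel] <= (L - fl + 1) / (L_all - fl + 1)
    sel <- sel[keep]
    if (length(sel) == 0L) next
    fl <- fl[keep]
    s0 <- as.integer(floor(u_start[sel] * (L - fl + 1)))
    frag_ids <- sprintf("%s_f%05d", gm$gene_id, frag_idx + seq_along(sel))
    frag_idx <- frag_idx + length(sel)
    ## mate template intervals
    m1 <- data.table(read_id = frag_ids, mate = 1L, t0 = s0, t1 = s0 + rl)
    m2 <- data.table(read_id = frag_ids, mate = 2L, t0 = s0 + fl - rl,
                     t1 = s0 + fl)
    mates <- rbind(m1, m2)
    bl <- template_blocks(iso, mates, gm$strand)
    bl[, `:=`(chrom = gm$chrom,
              aln_id = aln_offset + .GRP), by = .(read_id, mate)]
    aln_offset <- aln_offset + uniqueN(bl[, paste(read_id, mate)])
    out_blocks[[length(out_blocks) + 1L]] <-
      bl[, .(aln_id, read_id, mate, chrom, block_start, block_end)]
    out_frags[[length(out_frags) + 1L]] <-
      data.table(read_id = frag_ids, gene_id = gm$gene_id, isoform = pat)
  }
  blocks <- rbindlist(out_blocks)
  list(blocks = blocks, fragments = rbindlist(out_frags),
       n_alignments = uniqueN(blocks$aln_id))
}

## genomic segment map of one isoform pattern; transcript order with
## cumulative transcript coordinates.  Mis-splicing ("M") removes the intron
## plus the first 15 nt of the downstream exon.
isoform_segmap <- function(segs, pattern, strand) {
  states <- strsplit(pattern, "")[[1L]]
  keep <- copy(segs)
  keep[, drop := FALSE]
  keep[, trim5 := 0L]
  if (length(states) > 0L) {
    int_rows <- which(keep$kind == "intron")
    for (j in seq_along(states)) {
      if (states[j] == "R") next
      keep$drop[int_rows[j]] <- TRUE
      if (states[j] == "M") {
        keep$trim5[int_rows[j] + 1L] <- 15L   # next segment in transcript order
      }
    }
  }
  iso <- keep[drop == FALSE]
  ## apply 5' trims in transcript sense
  iso[trim5 > 0L & strand == "+", gstart := gstart + trim5]
  iso[trim5 > 0L & strand == "-", gend := gend - trim5]
  iso[, tlen := gend - gstart]
  iso[, tend := cumsum(tlen)]
  iso[, tstart := tend - tlen]
  iso[]
}

## map mate template intervals [t0, t1) to genomic blocks, merging segments
## that stay contiguous in the genome
template_blocks <- function(iso, mates, strand) {
  mates <- copy(mates)[, mate_key := .I]
  grid <- CJ(mate_key = mates$mate_key, seg_i = seq_len(nrow(iso)))
  pieces <- mates[grid, on = "mate_key"]
  pieces <- cbind(pieces,
                  iso[pieces$seg_i, .(gstart, gend, tstart, tend)])
  pieces <- pieces[pmax(t0, tstart) < pmin(t1, tend)]
  pieces[, `:=`(ov0 = pmax(t0, tstart), ov1 = pmin(t1, tend))]
  if (strand == "+") {
    pieces[, `:=`(b0 = gstart + (ov0 - tstart), b1 = gstart + (ov1 - tstart))]
  } else {
    pieces[, `:=`(b0 = gend - (ov1 - tstart), b1 = gend - (ov0 - tstart))]
  }
  setorder(pieces, mate_key, b0)
  pieces[, new_run := cumsum(b0 != shift(b1, fill = b0[1L])), by = mate_key]
  blocks <- pieces[, .(read_id = read_id[1L], mate = mate[1L],
                       block_start = min(b0), block_end = max(b1)),
                   by = .(mate_key, new_run)]
  blocks[, c("mate_key", "new_run") := NULL]
  blocks[]
}

#' Write a synthetic world to disk as standard formats
#'
#' Emits genome FASTA, annotation GTF, expression TSV, coordinate-sorted SAM
#' with header, and the truth tables (genes/boundaries/fragments) as TSV.
#'
#' @param world A `SimWorld` from [generate_world()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "SimWorld"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    expression = file.path(dir, "expression.tsv"),
    sam = file.path(dir, "alignments.sam"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_boundaries = file.path(dir, "truth_boundaries.tsv"),
    truth_fragments = file.path(dir, "truth_fragments.tsv"))
  Biostrings::writeXStringSet(world$genome, paths$genome, width = 70L)
  write_gtf(world$models, paths$gtf)
  fwrite(world$expression, paths$expression, sep = "\t")
  write_sam(world$alignments, world$genome, paths$sam)
  fwrite(world$truth$genes, paths$truth_genes, sep = "\t")
  fwrite(world$truth$boundaries, paths$truth_boundaries, sep = "\t")
  fwrite(world$truth$fragments, paths$truth_fragments, sep = "\t")
  invisible(paths)
}

#' Write alignments as a sorted SAM file
#'
#' Reconstructs CIGAR strings (M blocks, N gaps) from aligned blocks and
#' writes a minimal valid SAM: paired-end flags, MAPQ 60, no sequence or
#' qualities (`*`).
#'
#' @param alignments A `ReadAlignments` object.
#' @param genome `DNAStringSet` supplying the `@SQ` header lines.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  bl <- copy(as.data.table(alignments))
  setorder(bl, aln_id, block_start)
  aln <- bl[, .(
    read_id = read_id[1L], mate = mate[1L], chrom = chrom[1L],
    pos = min(block_start),
    cigar = {
      m <- block_end - block_start
      if (.N == 1L) paste0(m, "M")
      else paste0(paste0(m[-.N], "M",
                         block_start[-1L] - block_end[-.N], "N",
                         collapse = ""), m[.N], "M")
    }), by = aln_id]
  mate_pos <- aln[, .(aln_id, read_id, mate, pos)]
  other <- mate_pos[, .(read_id, mate = 3L - mate, mpos = pos)]
  aln <- other[aln, on = c("read_id", "mate")]
  aln[is.na(mpos), mpos := pos]
  aln[, flag := fifelse(mate == 1L, 99L, 147L)]
  setorder(aln, chrom, pos, read_id, mate)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t*\t*",
                  aln$read_id, aln$flag, aln$chrom, aln$pos + 1L,
                  aln$cigar, aln$mpos + 1L)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Emit the miniature hand-checkable fixture world
#'
#' A deterministic 3-gene world (one plus-strand two-intron gene, one
#' minus-strand one-intron gene, one intronless gene, plus the nested gene)
#' with about 200 fragments, small enough that every verdict can be
#' enumerated by hand.  Always built with the same internal world seed; the
#' `read_seed` argument perturbs only the reads, never the gene models.
#'
#' @param dir Output directory, or NULL to return the world without writing.
#' @param read_seed Read-level seed (default 421).
#' @return The `SimWorld`, invisibly if written.
#' @export
emit_worked_fixture <- function(dir = NULL, read_seed = 421L) {
  cfg <- sim_config(
    n_genes = c(maternal = 1L, early_zygotic = 1L, unclassified = 1L),
    intronless_frac = 0.5, max_introns = 2L,
    exon_len_range = c(120L, 220L),
    intron_len_ranges = list(c(80L, 99L), c(100L, 300L), c(501L, 700L)),
    retention_levels = c(0, 0.5),
    mis_splice_rate = 0.05,
    read_len = 50L, frag_mean = 120, frag_sd = 10,
    target_fragments = 12L,
    seed = 421L, read_seed = read_seed)
  world <- generate_world(cfg)
  if (!is.null(dir)) {
    write_world(world, dir)
    return(invisible(world))
  }
  world
}
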