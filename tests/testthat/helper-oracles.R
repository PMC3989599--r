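## Independent brute-force oracles and tiny model builders for the tests.
## These deliberately use naive per-base / per-pair loops, not the package's
## vectorised code paths.

## quick exon-table builder: ex(gene, tx, chrom, strand, starts, ends)
ex_tab <- function(gene, tx, starts, ends, chrom = "c1", strand = "+") {
  data.table::data.table(gene_id = gene, transcript_id = tx, chrom = chrom,
                         strand = strand, start = as.integer(starts),
                         end = as.integer(ends))
}

## random model set: n genes, random exon structures, both strands
random_models <- function(n_genes = 10L, max_introns = 4L,
                          chroms = c("c1", "c2")) {
  rows <- list()
  cursor <- stats::setNames(rep(0L, length(chroms)), chroms)
  for (i in seq_len(n_genes)) {
    chrom <- sample(chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    k <- sample(0:max_introns, 1L)
    ex_len <- sample(20:200, k + 1L, replace = TRUE)
    in_len <- if (k > 0L) sample(20:400, k, replace = TRUE) else integer(0)
    g0 <- cursor[[chrom]] + sample(10:100, 1L)
    starts <- integer(0); ends <- integer(0); pos <- g0
    for (j in seq_len(k + 1L)) {
      starts <- c(starts, pos); ends <- c(ends, pos + ex_len[j])
      pos <- pos + ex_len[j] + if (j <= k) in_len[j] else 0L
    }
    cursor[[chrom]] <- pos
    gid <- sprintf("g%02d", i)
    rows[[length(rows) + 1L]] <-
      ex_tab(gid, paste0(gid, ".t1"), starts, ends, chrom, strand)
    if (k > 0L && stats::runif(1) < 0.4) {   # duplicate transcript
      rows[[length(rows) + 1L]] <-
        ex_tab(gid, paste0(gid, ".t2"), starts, ends, chrom, strand)
    }
  }
  irquant::gene_model_set(data.table::rbindlist(rows))
}

## oracle 1: enumerate all consecutive-exon gaps, dedup by coordinates
oracle_boundaries <- function(models) {
  ex <- models$exons
  seen <- character(0)
  for (tid in unique(ex$transcript_id)) {
    t <- ex[ex$transcript_id == tid]
    t <- t[order(t$start)]
    if (nrow(t) < 2L) next
    for (j in seq_len(nrow(t) - 1L)) {
      seen <- c(seen, paste(t$chrom[1L], t$end[j], t$start[j + 1L],
                            t$strand[1L], sep = ":"))
    }
  }
  sort(unique(seen))
}

## oracle 2: boundary unsafe iff any exon overlaps its intron interval
oracle_safe <- function(boundaries, models) {
  ex <- models$exons
  keep <- logical(nrow(boundaries))
  for (i in seq_len(nrow(boundaries))) {
    b <- boundaries[i]
    hit <- FALSE
    for (j in seq_len(nrow(ex))) {
      if (ex$chrom[j] == b$chrom &&
          ex$start[j] < b$intron_end && ex$end[j] > b$intron_start) {
        hit <- TRUE; break
      }
    }
    keep[i] <- !hit
  }
  keep
}

## oracle 3: per-base gene-structure rasteriser, then segment mapping
oracle_structure <- function(models, n_segments = 1000L) {
  ex <- models$exons
  counts <- numeric(n_segments)
  gids <- unique(ex$gene_id)
  used <- 0L
  for (gid in gids) {
    g <- ex[ex$gene_id == gid]
    g0 <- min(g$start); g1 <- max(g$end); L <- g1 - g0
    if (L < n_segments) next
    used <- used + 1L
    pres <- logical(n_segments)
    for (j in seq_len(nrow(g))) {
      for (b in (g$start[j] - g0):(g$end[j] - g0 - 1L)) {
        s_lo <- floor(b * n_segments / L)
        s_hi <- floor(((b + 1) * n_segments - 1) / L)
        pres[(s_lo:s_hi) + 1L] <- TRUE
      }
    }
    if (g$strand[1L] == "-") pres <- rev(pres)
    counts <- counts + pres
  }
  100 * counts / used
}

## oracle 4: first-principles read verdict at a boundary.  blocks: matrix-ish
## list of c(start, end) in genomic 0-based half-open, sorted.
oracle_verdict <- function(blocks, b, min_overlap = 10L) {
  cov <- function(w0, w1) {      # every base in [w0, w1) covered?
    for (base in w0:(w1 - 1L)) {
      inblk <- FALSE
      for (bl in blocks) if (base >= bl[1L] && base < bl[2L]) inblk <- TRUE
      if (!inblk) return(FALSE)
    }
    TRUE
  }
  plus <- b$strand == "+"
  if (plus) {
    e0 <- b$intron_start - min_overlap; e1 <- b$intron_start
    i0 <- b$intron_start; i1 <- b$intron_start + min_overlap
  } else {
    e0 <- b$intron_end; e1 <- b$intron_end + min_overlap
    i0 <- b$intron_end - min_overlap; i1 <- b$intron_end
  }
  verdict <- "uninformative"
  if (length(blocks) >= 2L) {
    for (j in seq_len(length(blocks) - 1L)) {
      g1 <- blocks[[j]][2L]; g2 <- blocks[[j + 1L]][1L]   # gap [g1, g2)
      if (plus) {
        at_donor <- g1 == b$intron_start
        exon_side <- cov(e0, e1) &&
          blocks[[j]][2L] == g1 && blocks[[j]][1L] <= e0
        beyond <- (blocks[[j + 1L]][2L] - g2) >= min_overlap
        to_acceptor <- g2 == b$intron_end
      } else {
        at_donor <- g2 == b$intron_end
        exon_side <- cov(e0, e1) &&
          blocks[[j + 1L]][1L] == g2 && blocks[[j + 1L]][2L] >= e1
        beyond <- (g1 - blocks[[j]][1L]) >= min_overlap
        to_acceptor <- g1 == b$intron_start
      }
      if (at_donor && exon_side && beyond) {
        verdict <- if (to_acceptor) "spliced" else "mis_spliced"
      }
    }
  }
  if (verdict == "uninformative" && cov(e0, e1) && cov(i0, i1)) {
    verdict <- "unspliced"
  }
  verdict
}

## wrap loose blocks as a ReadAlignments-shaped table
as_alignments <- function(blocks_list, chrom = "c1") {
  rows <- list()
  for (i in seq_along(blocks_list)) {
    bl <- blocks_list[[i]]
    rows[[i]] <- data.table::data.table(
      aln_id = i, read_id = paste0("r", i), mate = 1L, chrom = chrom,
      block_start = vapply(bl, `[`, integer(1), 1L),
      block_end = vapply(bl, `[`, integer(1), 2L))
  }
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, chrom, block_start, block_end)
  structure(out, class = c("ReadAlignments", "data.table", "data.frame"))
}

## simple one-intron boundary row
toy_boundary <- function(intron_start, intron_end, strand = "+",
                         chrom = "c1", gene_id = "gT",
                         up = 1000L, down = 1000L) {
  data.table::data.table(
    chrom = chrom, strand = strand,
    intron_start = as.integer(intron_start),
    intron_end = as.integer(intron_end),
    donor = if (strand == "+") as.integer(intron_start)
            else as.integer(intron_end),
    acceptor = if (strand == "+") as.integer(intron_end)
               else as.integer(intron_start),
    gene_id = gene_id,
    intron_len = as.integer(intron_end - intron_start),
    up_exon_len = up, down_exon_len = down, safe = TRUE)
}
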