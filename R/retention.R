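## Fragment classification at 5' splice sites and per-boundary retention.
##
## A read is informative for a boundary when its aligned footprint covers at
## least `min_overlap` nt of exon immediately upstream of the donor junction
## and either (a) `min_overlap` nt of intron immediately downstream (an
## unsplit read) or (b) carries a splice gap starting exactly at the donor
## with `min_overlap` nt aligned beyond the gap.  Verdicts:
##   spliced     gap runs exactly donor -> acceptor
##   unspliced   contiguous coverage across the junction
##   mis_spliced informative split whose gap does not end at the acceptor
## Blocks have positive gaps between them, so "window fully covered" is
## equivalent to "some single block contains the window".

verdict_levels <- c("spliced", "unspliced", "mis_spliced", "uninformative")

## per-(boundary, alignment) verdicts for all alignments whose blocks overlap
## the +/- min_overlap junction window; returns data.table
## (boundary_id, aln_id, read_id, mate, verdict)
read_calls <- function(alignments, boundaries, min_overlap = 10L) {
  stopifnot(min_overlap >= 1L)
  b <- copy(as.data.table(boundaries))
  b[, boundary_id := boundary_key(b)]
  ## junction coordinate: first intron-side base boundary in genomic coords.
  ## "+": junction J = intron_start, exon window [J-mo, J), intron [J, J+mo).
  ## "-": J = intron_end, exon window [J, J+mo), intron [J-mo, J).
  b[, `:=`(
    jxn = fifelse(strand == "+", intron_start, intron_end),
    e0 = fifelse(strand == "+", intron_start - min_overlap, intron_end),
    e1 = fifelse(strand == "+", intron_start, intron_end + min_overlap),
    i0 = fifelse(strand == "+", intron_start, intron_end - min_overlap),
    i1 = fifelse(strand == "+", intron_start + min_overlap, intron_end))]
  win <- b[, .(boundary_id, chrom, w0 = jxn - min_overlap,
               w1 = jxn + min_overlap)]
  bl <- copy(as.data.table(alignments))
  empty <- data.table(boundary_id = character(), aln_id = integer(),
                      read_id = character(), mate = integer(),
                      verdict = factor(character(), levels = verdict_levels))
  if (nrow(bl) == 0L || nrow(win) == 0L) return(empty)
  setkey(bl, chrom, block_start, block_end)
  ov <- foverlaps(win, bl, by.x = c("chrom", "w0", "w1"),
                  type = "any", nomatch = NULL)
  ## foverlaps overlaps closed intervals; restore half-open semantics.  Every
  ## informative alignment still qualifies: a donor-split block ends exactly
  ## at the junction, i.e. strictly inside [w0, w1).
  ov <- ov[block_end > w0 & block_start < w1]
  pairs <- unique(ov[, .(boundary_id, aln_id)])
  if (nrow(pairs) == 0L) return(empty)
  ## all blocks of every candidate alignment, replicated per boundary
  blocks_by_aln <- as.data.table(alignments)
  setkey(blocks_by_aln, aln_id)
  pb <- blocks_by_aln[pairs, on = "aln_id", allow.cartesian = TRUE]
  pb <- b[, .(boundary_id, strand, intron_start, intron_end, e0, e1, i0, i1)][
    pb, on = "boundary_id"]
  setorder(pb, boundary_id, aln_id, block_start)
  ## gap between this block and the next within (boundary_id, aln_id)
  pb[, `:=`(
    nxt_start = shift(block_start, type = "lead"),
    nxt_end = shift(block_end, type = "lead")),
    by = .(boundary_id, aln_id)]
  pb[, `:=`(
    exon_cov_blk = block_start <= e0 & block_end >= e1,
    intron_cov_blk = block_start <= i0 & block_end >= i1)]
  ## informative split gap, transcript sense: on "+" the gap starts at the
  ## donor, the block before it must cover the exon window and the block
  ## after it must be >= min_overlap long; mirrored on "-".
  pb[, gap_ok := !is.na(nxt_start) & fifelse(
    strand == "+",
    block_end == intron_start & block_start <= e0 &
      (nxt_end - nxt_start) >= min_overlap,
    nxt_start == intron_end & nxt_end >= e1 &
      (block_end - block_start) >= min_overlap)]
  pb[, gap_spliced := gap_ok & fifelse(
    strand == "+", nxt_start == intron_end, block_end == intron_start)]
  calls <- pb[, .(
    exon_cov = any(exon_cov_blk),
    intron_cov = any(intron_cov_blk),
    split_inf = any(gap_ok),
    split_spl = any(gap_spliced)
  ), by = .(boundary_id, aln_id)]
  calls[, verdict := factor(fcase(
    split_spl, "spliced",
    split_inf, "mis_spliced",
    exon_cov & intron_cov, "unspliced",
    default = "uninformative"), levels = verdict_levels)]
  aln_meta <- unique(as.data.table(alignments)[, .(aln_id, read_id, mate)])
  out <- aln_meta[calls, on = "aln_id"][
    , .(boundary_id, aln_id, read_id, mate, verdict)]
  setorder(out, boundary_id, aln_id)
  out[]
}

#' Classify one alignment at one boundary
#'
#' Convenience scalar form over the vectorised engine; see the package
#' overview for the verdict definitions.
#'
#' @param blocks data.frame of the alignment's aligned blocks with columns
#'   `chrom`, `block_start`, `block_end` (0-based half-open), sorted.
#' @param boundary One-row boundary table.
#' @param min_overlap Minimum aligned nt on each side of the junction
#'   (default 10).
#' @return One of `"spliced"`, `"unspliced"`, `"mis_spliced"`,
#'   `"uninformative"`.
#' @export
call_read <- function(blocks, boundary, min_overlap = 10L) {
  bl <- as.data.table(blocks)
  if (!nrow(bl)) return("uninformative")
  if (any(bl$chrom != boundary$chrom[1L])) return("uninformative")
  bl[, `:=`(aln_id = 1L, read_id = "r", mate = 1L)]
  calls <- read_calls(bl, boundary, min_overlap)
  if (nrow(calls) == 0L) "uninformative" else as.character(calls$verdict[1L])
}

## merge mate verdicts into fragment verdicts; conflicting informative mates
## are discarded.  Input: read_calls() output.  Returns
## (boundary_id, read_id, verdict) for informative fragments, with attribute
## n_conflict.
fragment_calls <- function(calls) {
  inf <- calls[verdict != "uninformative"]
  if (nrow(inf) == 0L) {
    out <- data.table(boundary_id = character(), read_id = character(),
                      verdict = factor(character(), levels = verdict_levels))
    setattr(out, "n_conflict", 0L)
    return(out)
  }
  frag <- inf[, .(nv = uniqueN(verdict), verdict = verdict[1L]),
              by = .(boundary_id, read_id)]
  n_conflict <- sum(frag$nv > 1L)
  out <- frag[nv == 1L, .(boundary_id, read_id, verdict)]
  setattr(out, "n_conflict", n_conflict)
  out[]
}

#' Tally fragment verdicts per boundary
#'
#' Groups alignments into fragments by read id, merges mate verdicts
#' (identical or one-sided verdicts stand; conflicting informative mates are
#' discarded and counted), and computes per-boundary retention.
#' `retention_pct = 100 * unspliced / (unspliced + spliced)`; mis-spliced
#' fragments are reported but excluded from the denominator.  A boundary is
#' `informative` when at least `min_fragments` informative fragments overlap
#' it.
#'
#' @param alignments A `ReadAlignments` object (or its blocks table).
#' @param boundaries Boundary table.
#' @param min_overlap Minimum aligned nt each side of the junction
#'   (default 10).
#' @param min_fragments Minimum informative fragments per boundary
#'   (default 10).
#' @return data.table with one row per boundary: `boundary_id`, `gene_id`,
#'   `intron_len`, counts `n_spliced`, `n_unspliced`, `n_mis_spliced`,
#'   `n_conflict`, `retention_pct` (NA when undefined) and `informative`.
#' @export
tally_boundaries <- function(alignments, boundaries, min_overlap = 10L,
                             min_fragments = 10L) {
  b <- copy(as.data.table(boundaries))
  b[, boundary_id := boundary_key(b)]
  calls <- read_calls(alignments, b, min_overlap)
  frags <- fragment_calls(calls)
  counts <- frags[, .(
    n_spliced = sum(verdict == "spliced"),
    n_unspliced = sum(verdict == "unspliced"),
    n_mis_spliced = sum(verdict == "mis_spliced")
  ), by = boundary_id]
  out <- counts[b[, .(boundary_id, gene_id, intron_len)],
                on = "boundary_id"]
  for (col in c("n_spliced", "n_unspliced", "n_mis_spliced")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, informative :=
        (n_spliced + n_unspliced + n_mis_spliced) >= min_fragments]
  out[, retention_pct := fifelse(
    informative & (n_spliced + n_unspliced) > 0L,
    100 * n_unspliced / (n_unspliced + n_spliced), NA_real_)]
  setattr(out, "n_conflict", attr(frags, "n_conflict"))
  setcolorder(out, c("boundary_id", "gene_id", "intron_len", "n_spliced",
                     "n_unspliced", "n_mis_spliced", "retention_pct",
                     "informative"))
  out[]
}

#' Tally one boundary
#'
#' Scalar wrapper around [tally_boundaries()] for a single boundary.
#'
#' @inheritParams tally_boundaries
#' @param boundary One-row boundary table.
#' @return One-row classification table (see [tally_boundaries()]).
#' @export
tally_boundary <- function(alignments, boundary, min_overlap = 10L,
                           min_fragments = 10L) {
  tally_boundaries(alignments, boundary, min_overlap, min_fragments)
}

five_num <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo <- min(x[x >= q[1L] - 1.5 * iqr])
  hi <- max(x[x <= q[3L] + 1.5 * iqr])
  list(lo = lo, q1 = q[1L], median = q[2L], q3 = q[3L], hi = hi)
}

#' Build the stratified retention table
#'
#' Joins gene class and intron-size bin onto every boundary tally and
#' summarises retention per (gene class x size bin) stratum with five-number
#' boxplot statistics (Tukey whiskers).  Boundaries whose gene has no class
#' record fall into the `unclassified` stratum with a warning; nothing is
#' silently dropped.
#'
#' @param tallies Output of [tally_boundaries()].
#' @param gene_classes data.table (gene_id, gene_class) from
#'   [classify_table()], or NULL to place everything in `unclassified`.
#' @return List of class `RetentionTable`: `rows` (per-boundary table with
#'   gene_class and size_bin) and `summaries` (per-stratum boxplot stats over
#'   informative boundaries with defined retention).
#' @export
build_retention_table <- function(tallies, gene_classes = NULL) {
  rows <- copy(as.data.table(tallies))
  if (is.null(gene_classes) || nrow(gene_classes) == 0L) {
    rows[, gene_class := factor("unclassified", levels = gene_class_levels)]
    if (nrow(rows) > 0L) {
      warning("no gene classes supplied; all boundaries unclassified")
    }
  } else {
    gc <- as.data.table(gene_classes)
    rows[gc, gene_class := i.gene_class, on = "gene_id"]
    n_miss <- sum(is.na(rows$gene_class))
    if (n_miss > 0L) {
      warning(n_miss, " boundary/ies with no expression record -> unclassified")
    }
    rows[is.na(gene_class), gene_class := "unclassified"]
    rows[, gene_class := factor(gene_class, levels = gene_class_levels)]
  }
  rows[, size_bin := bin_intron_size(intron_len)]
  summaries <- rows[informative & !is.na(retention_pct),
                    five_num(retention_pct),
                    by = .(gene_class, size_bin)]
  n_per <- rows[informative & !is.na(retention_pct), .(n = .N),
                by = .(gene_class, size_bin)]
  summaries <- n_per[summaries, on = c("gene_class", "size_bin")]
  setorder(summaries, gene_class, size_bin)
  structure(list(rows = rows[], summaries = summaries[]),
            class = "RetentionTable")
}

#' @export
print.RetentionTable <- function(x, ...) {
  cat("RetentionTable:", nrow(x$rows), "boundaries,",
      sum(x$rows$informative), "informative\n")
  print(x$summaries)
  invisible(x)
}

#' Write a retention table: per-boundary TSV plus JSON boxplot summaries
#' @param rt A `RetentionTable`.
#' @param path TSV output path; summaries go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_retention_table <- function(rt, path) {
  fwrite(rt$rows, path, sep = "\t")
  jsonlite::write_json(rt$summaries, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
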