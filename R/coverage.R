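## Normalised per-base coverage in a window centred on each 5' splice site.
## At each base the number of reads covering it is divided by the number of
## reads whose footprint intersects the window at all (partial overlaps
## count).  Orientation is transcript sense: positions -halfwidth .. -1 are
## exonic, 0 .. halfwidth-1 intronic.

#' Per-base coverage profile around one 5' splice site
#'
#' @param alignments A `ReadAlignments` object (or its blocks table).
#' @param boundary One-row boundary table; should have passed
#'   [filter_min_flank()] so the window stays within intron and flanking exon.
#' @param halfwidth Half window width in nt (default 50, i.e. a 100 bp
#'   window).
#' @param min_reads Minimum reads intersecting the window for the profile to
#'   be defined (default 50).
#' @return Numeric vector of length `2 * halfwidth` with values in [0, 1]
#'   (positions -halfwidth..halfwidth-1, exon side first), with attribute
#'   `n_window_reads`; or NULL when fewer than `min_reads` reads intersect
#'   the window.
#' @export
coverage_profile <- function(alignments, boundary, halfwidth = 50L,
                             min_reads = 50L) {
  prof <- coverage_profiles(alignments, boundary, halfwidth, min_reads)
  if (nrow(prof$profiles) == 0L) return(NULL)
  v <- prof$profiles$value
  structure(v, n_window_reads = prof$n_window_reads$n_reads[1L])
}

#' Coverage profiles for many boundaries
#'
#' Vectorised form of [coverage_profile()].
#'
#' @inheritParams coverage_profile
#' @param boundaries Boundary table (ideally the [filter_min_flank()]
#'   survivors).
#' @return List: `profiles`, a long data.table (boundary_id, gene_id,
#'   position, value) for boundaries meeting `min_reads`; `n_window_reads`,
#'   per-boundary read counts with a `defined` flag.
#' @export
coverage_profiles <- function(alignments, boundaries, halfwidth = 50L,
                              min_reads = 50L) {
  b <- copy(as.data.table(boundaries))
  b[, boundary_id := boundary_key(b)]
  b[, jxn := fifelse(strand == "+", intron_start, intron_end)]
  b[, `:=`(w0 = jxn - halfwidth, w1 = jxn + halfwidth)]
  bl <- copy(as.data.table(alignments))
  setkey(bl, chrom, block_start, block_end)
  ov <- foverlaps(b[, .(boundary_id, chrom, w0, w1)], bl,
                  by.x = c("chrom", "w0", "w1"), type = "any",
                  nomatch = NULL)
  ov <- ov[block_end > w0 & block_start < w1]
  nw <- ov[, .(n_reads = uniqueN(aln_id)), by = boundary_id]
  nw <- nw[b[, .(boundary_id)], on = "boundary_id"]
  nw[is.na(n_reads), n_reads := 0L]
  nw[, defined := n_reads >= min_reads]
  keep <- nw[defined == TRUE, boundary_id]
  profiles <- data.table(boundary_id = character(), gene_id = character(),
                         position = integer(), value = numeric())
  if (length(keep) > 0L) {
    ## denominators: all blocks of a counted read lie within one alignment,
    ## and within an alignment blocks are disjoint, so per-base counts from
    ## clipped blocks never double-count a read.
    ovk <- ov[boundary_id %in% keep]
    ovk <- b[, .(boundary_id, strand, w0j = w0)][ovk, on = "boundary_id"]
    ovk[, `:=`(c0 = pmax(block_start, w0) - w0j,
               c1 = pmin(block_end, w1) - w0j)]
    width <- 2L * halfwidth
    prof_list <- lapply(split(ovk, by = "boundary_id"), function(g) {
      delta <- numeric(width + 1L)
      for (i in seq_len(nrow(g))) {
        delta[g$c0[i] + 1L] <- delta[g$c0[i] + 1L] + 1
        delta[g$c1[i] + 1L] <- delta[g$c1[i] + 1L] - 1
      }
      cov <- cumsum(delta[seq_len(width)])
      if (g$strand[1L] == "-") cov <- rev(cov)
      data.table(boundary_id = g$boundary_id[1L],
                 position = seq.int(-halfwidth, halfwidth - 1L),
                 value = cov / nw[boundary_id == g$boundary_id[1L], n_reads])
    })
    profiles <- rbindlist(prof_list)
    profiles <- b[, .(boundary_id, gene_id)][profiles, on = "boundary_id"]
  }
  list(profiles = profiles[], n_window_reads = nw[])
}

#' Aggregate coverage profiles per gene class
#'
#' For each position and gene class, the five-number summary of profile
#' values across boundaries.
#'
#' @param profiles Long profile table from [coverage_profiles()].
#' @param gene_classes data.table (gene_id, gene_class), or NULL for a single
#'   `unclassified` stratum.
#' @return data.table (gene_class, position, lo, q1, median, q3, hi, n).
#' @export
aggregate_profiles <- function(profiles, gene_classes = NULL) {
  p <- copy(as.data.table(profiles))
  if (is.null(gene_classes) || nrow(gene_classes) == 0L) {
    p[, gene_class := factor("unclassified", levels = gene_class_levels)]
  } else {
    gc <- as.data.table(gene_classes)
    p[gc, gene_class := i.gene_class, on = "gene_id"]
    p[is.na(gene_class), gene_class := "unclassified"]
    p[, gene_class := factor(gene_class, levels = gene_class_levels)]
  }
  out <- p[, c(five_num(value), .(n = uniqueN(boundary_id))),
           by = .(gene_class, position)]
  setorder(out, gene_class, position)
  out[]
}

#' Write coverage outputs: long TSV plus per-class summary TSV
#' @param profiles Long profile table.
#' @param summaries Output of [aggregate_profiles()].
#' @param path Long-format TSV path; summaries go to `<path_summary>` if
#'   given, else `<path>` with a `_summary.tsv` suffix.
#' @param path_summary Optional summary TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(profiles, summaries, path, path_summary = NULL) {
  fwrite(profiles, path, sep = "\t")
  if (is.null(path_summary)) {
    path_summary <- sub("\\.tsv$", "", path)
    path_summary <- paste0(path_summary, "_summary.tsv")
  }
  fwrite(summaries, path_summary, sep = "\t")
  invisible(path)
}
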