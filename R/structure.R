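## Exon--intron gene-structure profile: each gene divided into n equal
## segments; a segment scores presence if any exon of any transcript of the
## gene intersects it.  The profile is the percentage of genes with presence
## per segment, 5' -> 3' in transcript sense.

#' Gene-structure exon-presence profile
#'
#' Divides each gene span into `n_segments` equal parts and reports, per
#' segment, the percentage of genes having exon sequence in that segment.
#' Genes on the minus strand are reversed so segment 1 is always the 5' end.
#' A set of intronless single-exon genes scores exactly 100 everywhere; under
#' random exon placement interior segments hover near 50.
#'
#' @param models A `GeneModelSet`.
#' @param n_segments Number of segments per gene (default 1000).
#' @return List of class `StructureProfile`: `freq` (percent per segment),
#'   `n_segments`, `n_genes` (genes used), `n_skipped` (genes shorter than
#'   `n_segments` nt, skipped with a warning).
#' @export
structure_profile <- function(models, n_segments = 1000L) {
  stopifnot(inherits(models, "GeneModelSet"), n_segments >= 1L)
  if (nrow(models$exons) == 0L) stop("empty gene-model set")
  spans <- gene_spans(models)
  spans[, tx_len := span_end - span_start]
  short <- spans[tx_len < n_segments]
  if (nrow(short) > 0L) {
    warning(nrow(short), " gene(s) shorter than ", n_segments,
            " nt skipped: ", paste(head(short$gene_id, 5L), collapse = ", "))
  }
  spans <- spans[tx_len >= n_segments]
  if (nrow(spans) == 0L) stop("no gene is at least ", n_segments, " nt long")
  ex <- models$exons[spans[, .(gene_id, span_start, tx_len)],
                     on = "gene_id", nomatch = NULL]
  n <- as.numeric(n_segments)
  ## segment s (0-based) covers gene-relative [s*L/n, (s+1)*L/n); an exon
  ## [e0,e1) intersects s iff s*L < e1*n and (s+1)*L > e0*n -- integer math
  ex[, `:=`(e0 = start - span_start, e1 = end - span_start)]
  ex[, `:=`(s_first = (e0 * n) %/% tx_len,
            s_last = (e1 * n - 1) %/% tx_len)]
  counts <- numeric(n_segments)
  for (g in split(ex, by = "gene_id")) {
    pres <- logical(n_segments)
    for (i in seq_len(nrow(g))) {
      pres[(g$s_first[i] + 1L):(g$s_last[i] + 1L)] <- TRUE
    }
    if (g$strand[1L] == "-") pres <- rev(pres)
    counts <- counts + pres
  }
  freq <- 100 * counts / nrow(spans)
  structure(list(freq = freq, n_segments = n_segments,
                 n_genes = nrow(spans), n_skipped = nrow(short)),
            class = "StructureProfile")
}

#' @export
print.StructureProfile <- function(x, ...) {
  cat("StructureProfile:", x$n_segments, "segments over", x$n_genes,
      "genes; mean exon presence", sprintf("%.1f%%", mean(x$freq)), "\n")
  invisible(x)
}

#' Write a structure profile as TSV (segment, freq)
#' @param profile A `StructureProfile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_profile <- function(profile, path) {
  fwrite(data.table(segment = seq_len(profile$n_segments),
                    freq = profile$freq), path, sep = "\t")
  invisible(path)
}
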