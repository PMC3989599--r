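## Splice boundaries: unique introns with flanking-exon context.
##
## A boundary table is a data.table with one row per unique intron
## (chrom, intron_start, intron_end, strand), 0-based half-open.  donor and
## acceptor are junction coordinates in transcript sense: on "+" the donor is
## intron_start (first intronic base) and the acceptor intron_end (first
## exonic base after the intron); on "-" they are mirrored.

boundary_cols <- c("chrom", "strand", "intron_start", "intron_end",
                   "donor", "acceptor", "gene_id", "intron_len",
                   "up_exon_len", "down_exon_len", "safe")

#' Extract unique exon--intron boundaries from gene models
#'
#' Introns are the gaps between consecutive exons of each transcript.
#' Boundaries are deduplicated by (chrom, intron coordinates, strand) across
#' transcripts and genes; the flanking exon lengths recorded for a shared
#' intron are the minima over the transcripts sharing it, so that downstream
#' length filters hold for every transcript context.  Intronless transcripts
#' contribute nothing.
#'
#' @param models A `GeneModelSet`.
#' @return data.table of boundaries with columns chrom, strand, intron_start,
#'   intron_end, donor, acceptor, gene_id, intron_len, up_exon_len (5' exon,
#'   transcript sense), down_exon_len, safe (NA until [filter_safe()] is run).
#' @export
extract_boundaries <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  ex <- copy(models$exons)
  empty <- data.table(chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      donor = integer(), acceptor = integer(),
                      gene_id = character(), intron_len = integer(),
                      up_exon_len = integer(), down_exon_len = integer(),
                      safe = logical())
  if (nrow(ex) == 0L) return(empty)
  setkey(ex, gene_id, transcript_id, start, end)
  intr <- ex[, if (.N > 1L) .(
    chrom = chrom[1L], strand = strand[1L],
    intron_start = head(end, -1L), intron_end = tail(start, -1L),
    left_exon_len = head(end - start, -1L),
    right_exon_len = tail(end - start, -1L),
    gene_id = gene_id[1L]
  ), by = .(transcript_id)]
  if (nrow(intr) == 0L) return(empty)
  stopifnot(all(intr$intron_end > intr$intron_start))
  ## transcript sense: upstream exon is genomic-left on "+", genomic-right on "-"
  intr[, `:=`(
    up_exon_len = fifelse(strand == "+", left_exon_len, right_exon_len),
    down_exon_len = fifelse(strand == "+", right_exon_len, left_exon_len))]
  b <- intr[, .(
    gene_id = sort(unique(gene_id))[1L],
    intron_len = intron_end[1L] - intron_start[1L],
    up_exon_len = min(up_exon_len),
    down_exon_len = min(down_exon_len)
  ), by = .(chrom, strand, intron_start, intron_end)]
  b[, `:=`(donor = fifelse(strand == "+", intron_start, intron_end),
           acceptor = fifelse(strand == "+", intron_end, intron_start),
           safe = NA)]
  setcolorder(b, boundary_cols)
  setkey(b, chrom, intron_start, intron_end, strand)
  b[]
}

#' Remove boundaries whose intron overlaps any annotated exon
#'
#' A boundary is dropped iff any exon of any transcript (any gene, either
#' strand) overlaps the intron interval.  Survivors are flagged `safe = TRUE`.
#'
#' @param boundaries Boundary table from [extract_boundaries()].
#' @param models The `GeneModelSet` the boundaries came from.
#' @return The safe subset of `boundaries` with `safe = TRUE`.
#' @export
filter_safe <- function(boundaries, models) {
  stopifnot(inherits(models, "GeneModelSet"))
  if (nrow(boundaries) == 0L) {
    b <- copy(boundaries); b[, safe := logical(0)]; return(b[])
  }
  ex <- models$exons
  igr <- GenomicRanges::GRanges(
    boundaries$chrom,
    IRanges::IRanges(start = boundaries$intron_start + 1L,
                     end = boundaries$intron_end))
  egr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(start = ex$start + 1L, end = ex$end))
  hit <- GenomicRanges::countOverlaps(igr, egr, ignore.strand = TRUE) > 0L
  out <- copy(boundaries)[!hit]
  out[, safe := TRUE]
  out[]
}

#' Keep boundaries whose intron and both flanking exons reach a minimum length
#'
#' Lengths strictly below `min_len` are excluded (a 49 nt intron goes, a 50 nt
#' intron stays).  Used by the coverage analysis.
#'
#' @param boundaries Boundary table.
#' @param min_len Minimum length in nt (default 50).
#' @return Filtered boundary table.
#' @export
filter_min_flank <- function(boundaries, min_len = 50L) {
  boundaries[intron_len >= min_len &
             up_exon_len >= min_len &
             down_exon_len >= min_len]
}

#' Assign a boundary to an intron-size bin
#'
#' Bins: `lt100` (< 100 bp), `100to500` (100--500 bp inclusive),
#' `gt500` (> 500 bp).
#'
#' @param intron_len Integer vector of intron lengths (> 0).
#' @return Factor with levels `lt100`, `100to500`, `gt500`.
#' @export
bin_intron_size <- function(intron_len) {
  stopifnot(all(intron_len > 0L))
  cut(intron_len, breaks = c(0L, 99L, 500L, Inf),
      labels = c("lt100", "100to500", "gt500"))
}

#' Write a boundary table as TSV
#' @param boundaries Boundary table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(boundaries, path) {
  fwrite(boundaries, path, sep = "\t")
  invisible(path)
}

#' Read a boundary table written by [write_boundaries()]
#' @param path TSV path.
#' @return Boundary data.table.
#' @export
read_boundaries <- function(path) {
  b <- fread(path, sep = "\t")
  setkey(b, chrom, intron_start, intron_end, strand)
  b[]
}

## stable key string for joining per-boundary results
boundary_key <- function(b) {
  paste(b$chrom, b$intron_start, b$intron_end, b$strand, sep = ":")
}
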