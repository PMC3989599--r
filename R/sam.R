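## SAM alignment input.  Alignments are reduced to their aligned genomic
## blocks (0-based half-open); gaps between consecutive blocks are the splice
## gaps reported by the aligner (CIGAR N operations).  Primary alignments
## only; the library is treated as unstranded, so FLAG strand bits are kept
## but unused downstream.

#' Read split alignments from a SAM file
#'
#' Parses primary mapped alignments into aligned genomic blocks.  CIGAR M, =,
#' X and D consume reference within a block; N splits blocks (a splice gap);
#' I, S, H, P consume no reference.  Unmapped, secondary and supplementary
#' records are skipped.
#'
#' @param path Path to a SAM text file.  A BAM file may be supplied if the
#'   Rsamtools package is installed (it is converted to SAM first).
#' @return A `ReadAlignments` object: a data.table of blocks with columns
#'   `aln_id`, `read_id`, `mate` (1 or 2), `chrom`, `block_start`,
#'   `block_end`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package; supply SAM instead")
    }
    path <- Rsamtools::asSam(path, tempfile())
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(data.table(
      aln_id = integer(), read_id = character(), mate = integer(),
      chrom = character(), block_start = integer(), block_end = integer()),
      class = c("ReadAlignments", "data.table", "data.frame")))
  }
  f <- tstrsplit(lines, "\t", fixed = TRUE, keep = c(1L, 2L, 3L, 4L, 6L),
                 names = c("read_id", "flag", "chrom", "pos", "cigar"))
  aln <- data.table(read_id = f$read_id, flag = as.integer(f$flag),
                    chrom = f$chrom, pos = as.integer(f$pos) - 1L,
                    cigar = f$cigar)
  keep <- bitwAnd(aln$flag, 0x4L) == 0L &       # mapped
    bitwAnd(aln$flag, 0x100L) == 0L &           # primary
    bitwAnd(aln$flag, 0x800L) == 0L             # not supplementary
  aln <- aln[keep]
  if (nrow(aln) == 0L) stop("no primary mapped alignments in ", path)
  aln[, mate := fifelse(bitwAnd(flag, 0x80L) != 0L, 2L, 1L)]
  aln[, aln_id := .I]
  blocks <- cigar_blocks(aln$cigar, aln$pos)
  blocks <- aln[, .(aln_id, read_id, mate, chrom)][blocks, on = "aln_id"]
  setcolorder(blocks, c("aln_id", "read_id", "mate", "chrom",
                        "block_start", "block_end"))
  setkey(blocks, chrom, block_start, block_end)
  structure(blocks, class = c("ReadAlignments", "data.table", "data.frame"))
}

## vectorised CIGAR -> aligned blocks (0-based half-open)
cigar_blocks <- function(cigar, pos0) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  toks <- regmatches(cigar, m)
  nt <- lengths(toks)
  if (any(nt == 0L)) stop("unparsable CIGAR: ", cigar[which(nt == 0L)[1L]])
  tok <- unlist(toks, use.names = FALSE)
  ops <- data.table(
    aln_id = rep(seq_along(cigar), nt),
    len = as.integer(sub("[MIDNSHP=X]$", "", tok)),
    op = substring(tok, nchar(tok), nchar(tok)))
  ops[, ref := op %chin% c("M", "D", "N", "=", "X")]
  ops[, off_end := cumsum(len * ref), by = aln_id]
  ops[, off_start := off_end - len * ref]
  ops[, block := cumsum(op == "N") + 1L, by = aln_id]
  bl <- ops[ref & op != "N",
            .(block_start = min(off_start), block_end = max(off_end)),
            by = .(aln_id, block)]
  bl[, `:=`(block_start = block_start + pos0[aln_id],
            block_end = block_end + pos0[aln_id])]
  bl[, block := NULL]
  bl[]
}

#' @export
print.ReadAlignments <- function(x, ...) {
  cat("ReadAlignments:", uniqueN(x$aln_id), "alignments,",
      uniqueN(x$read_id), "fragments,", nrow(x), "blocks\n")
  invisible(x)
}
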