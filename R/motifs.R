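## Splice-site motif matrices: base counts and per-position information
## content around donor and acceptor junctions, in transcript orientation.

ic_bits <- function(freq_col) {
  p <- freq_col[freq_col > 0]
  2 - sum(-p * log2(p))
}

motif_from_seqs <- function(seqs, n_dropped, width = 0L) {
  if (length(seqs) == 0L) {
    counts <- matrix(0L, nrow = 4L, ncol = width,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    return(structure(list(counts = counts,
                          info_content = rep(NA_real_, width),
                          n_seqs = 0L, n_dropped = n_dropped),
                     class = "MotifMatrix"))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::consensusMatrix(ss, baseOnly = TRUE)[c("A", "C", "G", "T"), , drop = FALSE]
  freq <- sweep(counts, 2L, colSums(counts), "/")
  ic <- apply(freq, 2L, ic_bits)
  structure(list(counts = counts, info_content = ic,
                 n_seqs = length(seqs), n_dropped = n_dropped),
            class = "MotifMatrix")
}

#' @export
print.MotifMatrix <- function(x, ...) {
  cat("MotifMatrix:", ncol(x$counts), "positions from", x$n_seqs,
      "sequences (", x$n_dropped, "dropped )\n")
  invisible(x)
}

#' Splice-site motif matrices from boundary flanks
#'
#' Extracts, for every boundary, the sequence around the donor junction
#' (`left_flank` exonic + `right_flank` intronic nt, transcript orientation;
#' minus-strand windows are reverse-complemented) and the mirrored acceptor
#' window (`right_flank` intronic + `left_flank` exonic nt), and tallies base
#' counts and per-position information content IC = 2 - H bits (Shannon, no
#' small-sample correction).  Sequences containing non-ACGT symbols, or whose
#' window falls off the end of the chromosome, are dropped and counted.
#'
#' With canonical introns the donor matrix shows G,T at the first two intronic
#' positions and the acceptor matrix A,G at the last two intronic positions,
#' each at IC = 2 bits.
#'
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param boundaries Boundary table from [extract_boundaries()].
#' @param left_flank Exonic nt kept on the exon side (default 3).
#' @param right_flank Intronic nt kept on the intron side (default 6).
#' @return List with `donor` and `acceptor` `MotifMatrix` objects.
#' @export
boundary_motifs <- function(genome, boundaries, left_flank = 3L,
                            right_flank = 6L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  missing_chr <- setdiff(unique(boundaries$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("chromosome(s) missing from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  if (nrow(boundaries) == 0L) stop("no boundaries supplied")
  chr_len <- setNames(Biostrings::width(genome), names(genome))
  chr_seq <- setNames(as.character(genome), names(genome))

  extract_side <- function(w0, w1) {
    ## w0/w1: 0-based half-open genomic window per boundary (already strand
    ## resolved); returns character vector in transcript orientation
    ok <- w0 >= 0L & w1 <= chr_len[boundaries$chrom]
    seqs <- rep(NA_character_, nrow(boundaries))
    if (any(ok)) {
      s <- substring(chr_seq[boundaries$chrom[ok]], w0[ok] + 1L, w1[ok])
      neg <- boundaries$strand[ok] == "-"
      s[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s[neg])))
      seqs[ok] <- s
    }
    valid <- !is.na(seqs) & !grepl("[^ACGT]", seqs)
    motif_from_seqs(seqs[valid], n_dropped = sum(!valid),
                    width = left_flank + right_flank)
  }

  b <- boundaries
  don_w0 <- fifelse(b$strand == "+", b$donor - left_flank,
                    b$donor - right_flank)
  don_w1 <- fifelse(b$strand == "+", b$donor + right_flank,
                    b$donor + left_flank)
  acc_w0 <- fifelse(b$strand == "+", b$acceptor - right_flank,
                    b$acceptor - left_flank)
  acc_w1 <- fifelse(b$strand == "+", b$acceptor + left_flank,
                    b$acceptor + right_flank)
  list(donor = extract_side(don_w0, don_w1),
       acceptor = extract_side(acc_w0, acc_w1))
}

#' Write a motif matrix as TSV (position, A, C, G, T, IC)
#' @param motif A `MotifMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(motif, path) {
  dt <- data.table(position = seq_len(ncol(motif$counts)),
                   A = motif$counts["A", ], C = motif$counts["C", ],
                   G = motif$counts["G", ], T = motif$counts["T", ],
                   IC = motif$info_content)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}
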