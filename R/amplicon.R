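## In-silico RT-PCR: product presence and size for primer pairs on spliced vs
## intron-retained templates.  Primer hybridisation is positional (segment id
## + offset + length); no thermodynamics.  Product size is the standard
## amplicon definition: both primer footprints included, i.e. distance from
## the forward primer 5' end to the reverse primer 5' end inclusive on the
## isoform sequence.

#' Build a transcript template
#'
#' @param kind Character vector of segment kinds, `"exon"` or `"intron"`, in
#'   transcript order.
#' @param length_nt Positive integer segment lengths.
#' @param id Segment ids (default E1/I1/E2/... numbering per kind).
#' @return data.table of class `TranscriptTemplate` with columns `id`,
#'   `kind`, `length_nt`.
#' @export
transcript_template <- function(kind, length_nt, id = NULL) {
  stopifnot(all(kind %in% c("exon", "intron")), all(length_nt > 0L),
            length(kind) == length(length_nt))
  if (is.null(id)) {
    id <- paste0(ifelse(kind == "exon", "E", "I"),
                 ave(seq_along(kind), kind, FUN = seq_along))
  }
  stopifnot(!anyDuplicated(id))
  structure(data.table(id = id, kind = kind, length_nt = as.integer(length_nt)),
            class = c("TranscriptTemplate", "data.table", "data.frame"))
}

#' Define a primer pair by positional placement
#'
#' @param fwd_segment,rev_segment Segment ids hosting the forward and reverse
#'   primer.
#' @param fwd_offset,rev_offset 0-based offset of the primer footprint start
#'   within its segment (on the sense strand).
#' @param fwd_len,rev_len Primer lengths in nt (default 20).
#' @return A `PrimerPair` list.
#' @export
primer_pair <- function(fwd_segment, fwd_offset, rev_segment, rev_offset,
                        fwd_len = 20L, rev_len = 20L) {
  stopifnot(fwd_offset >= 0L, rev_offset >= 0L, fwd_len > 0L, rev_len > 0L)
  structure(list(fwd = list(segment = fwd_segment, offset = fwd_offset,
                            len = fwd_len),
                 rev = list(segment = rev_segment, offset = rev_offset,
                            len = rev_len)),
            class = "PrimerPair")
}

## segment table for one isoform: spliced keeps exons only; retained keeps
## exons plus the named introns.  Positions are isoform coordinates.
isoform_segments <- function(template, retained_introns = character()) {
  stopifnot(inherits(template, "TranscriptTemplate"))
  unknown <- setdiff(retained_introns, template[kind == "intron", id])
  if (length(unknown) > 0L) {
    stop("retained intron id(s) not in template: ",
         paste(unknown, collapse = ", "))
  }
  seg <- template[kind == "exon" | id %in% retained_introns]
  seg <- copy(seg)
  seg[, gend := cumsum(length_nt)]
  seg[, gstart := gend - length_nt]
  seg[]
}

primer_span <- function(segments, placement) {
  row <- segments[id == placement$segment]
  if (nrow(row) == 0L) return(NULL)              # primer site spliced out
  if (placement$offset + placement$len > row$length_nt) {
    stop("primer exceeds segment ", placement$segment)
  }
  c(start = row$gstart + placement$offset,
    end = row$gstart + placement$offset + placement$len)   # half-open
}

#' Predicted RT-PCR product size on one isoform
#'
#' @param template A `TranscriptTemplate`.
#' @param pair A `PrimerPair`.
#' @param retained_introns Character vector of intron ids retained in the
#'   isoform (empty = fully spliced).
#' @return Product size in nt, or NA (no product: a primer site spliced out,
#'   or the reverse primer not downstream of the forward).
#' @export
product_size <- function(template, pair, retained_introns = character()) {
  seg <- isoform_segments(template, retained_introns)
  fwd <- primer_span(seg, pair$fwd)
  rv <- primer_span(seg, pair$rev)
  if (is.null(fwd) || is.null(rv)) return(NA_integer_)
  size <- rv[["end"]] - fwd[["start"]]
  if (rv[["start"]] < fwd[["end"]]) return(NA_integer_)  # reverse upstream
  as.integer(size)
}

#' Classify a primer pair by host segment kinds
#'
#' @inheritParams product_size
#' @return One of `"e-e"`, `"i-e"`, `"e-i"`, `"i-i"` (forward kind first).
#' @export
classify_primer_pair <- function(template, pair) {
  kinds <- setNames(template$kind, template$id)
  fk <- kinds[[pair$fwd$segment]]
  rk <- kinds[[pair$rev$segment]]
  if (is.null(fk) || is.null(rk)) stop("primer segment not in template")
  paste(substr(fk, 1L, 1L), substr(rk, 1L, 1L), sep = "-")
}

#' Amplicon report over isoforms
#'
#' Convenience sweep: product size of each named primer pair on the spliced
#' isoform and on a retained isoform.
#'
#' @param template A `TranscriptTemplate`.
#' @param pairs Named list of `PrimerPair`s.
#' @param retained_introns Intron ids kept in the retained isoform (default:
#'   all introns).
#' @return data.table (pair, pair_class, isoform, product_size).
#' @export
amplicon_report <- function(template, pairs,
                            retained_introns = template[kind == "intron", id]) {
  if (is.null(names(pairs))) names(pairs) <- paste0("pair", seq_along(pairs))
  rbindlist(lapply(names(pairs), function(nm) {
    p <- pairs[[nm]]
    data.table(
      pair = nm,
      pair_class = classify_primer_pair(template, p),
      isoform = c("spliced", "retained"),
      product_size = c(product_size(template, p),
                       product_size(template, p, retained_introns)))
  }))
}
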