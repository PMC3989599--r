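## Gene models: parse from GTF, validate, write back.
##
## A GeneModelSet is a light S3 wrapper around a single exon table
## (data.table: gene_id, transcript_id, chrom, strand, start, end) with all
## coordinates 0-based half-open.  GTF on disk is 1-based inclusive.

#' Construct a gene-model set from an exon table
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`; coordinates 0-based half-open.
#' @return A `GeneModelSet` object.
#' @export
gene_model_set <- function(exons) {
  exons <- as.data.table(exons)
  required <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L) {
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  exons <- exons[, required, with = FALSE]
  if (nrow(exons) > 0L) {
    if (!all(exons$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    if (any(exons$end <= exons$start)) {
      bad <- which(exons$end <= exons$start)[1L]
      stop("exon with end <= start at row ", bad)
    }
    ## collapse duplicate exon lines (same exon listed twice for a transcript)
    exons <- unique(exons)
    setkey(exons, gene_id, transcript_id, start, end)
    ## within a transcript exons must be disjoint
    ov <- exons[, any(head(end, -1L) > tail(start, -1L)),
                by = .(gene_id, transcript_id)]
    if (any(ov$V1)) {
      bad <- ov[which(V1)[1L]]
      stop("overlapping exons within transcript ", bad$transcript_id,
           " of gene ", bad$gene_id)
    }
    ## a transcript must live on one chrom/strand
    mix <- exons[, uniqueN(paste(chrom, strand)), by = transcript_id]
    if (any(mix$V1 > 1L)) {
      stop("transcript ", mix[which(V1 > 1L)[1L]]$transcript_id,
           " spans multiple chromosomes or strands")
    }
  }
  structure(list(exons = exons), class = "GeneModelSet")
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", uniqueN(x$exons$gene_id), "genes,",
      uniqueN(x$exons$transcript_id), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Number of genes in a gene-model set
#' @param models A `GeneModelSet`.
#' @return Integer count of distinct genes.
#' @export
n_genes <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  uniqueN(models$exons$gene_id)
}

gtf_attr <- function(attrs, key) {
  ## extract `key "value"` from a GTF attribute column
  m <- regmatches(attrs, regexpr(paste0(key, '\\s+"([^"]*)"'), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- nchar(m) > 0L & !is.na(m)
  out[seq_along(attrs) %in% which(hit)] <-
    sub(paste0(key, '\\s+"([^"]*)".*'), "\\1", m[nchar(m) > 0L])
  out
}

#' Parse gene models from GTF text
#'
#' Reads exon features from a GTF file (1-based inclusive coordinates),
#' converts to 0-based half-open, groups exons by transcript and gene, sorts
#' them and collapses duplicated exon lines.  Non-exon features and comment
#' lines are ignored.
#'
#' @param path Path to a GTF file (or a character vector of GTF lines via
#'   `text`).
#' @param text Optional character vector of GTF lines, used instead of `path`.
#' @return A `GeneModelSet`.
#' @export
parse_gene_models <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(gene_model_set(data.table(
      gene_id = character(), transcript_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields")
  }
  mat <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  is_exon <- mat[, 3L] == "exon"
  if (!any(is_exon)) {
    return(gene_model_set(data.table(
      gene_id = character(), transcript_id = character(),
      chrom = character(), strand = character(),
      start = integer(), end = integer())))
  }
  mat <- mat[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  start1 <- suppressWarnings(as.integer(mat[, 4L]))
  end1 <- suppressWarnings(as.integer(mat[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    stop("malformed GTF line ", lineno[which(is.na(start1) | is.na(end1))[1L]],
         ": non-numeric coordinates")
  }
  if (any(end1 < start1)) {
    stop("validation error at GTF line ", lineno[which(end1 < start1)[1L]],
         ": exon end < start")
  }
  gid <- gtf_attr(mat[, 9L], "gene_id")
  tid <- gtf_attr(mat[, 9L], "transcript_id")
  if (anyNA(gid) || anyNA(tid)) {
    stop("malformed GTF line ", lineno[which(is.na(gid) | is.na(tid))[1L]],
         ": exon feature lacking gene_id or transcript_id attribute")
  }
  gene_model_set(data.table(
    gene_id = gid, transcript_id = tid,
    chrom = mat[, 1L], strand = mat[, 7L],
    start = start1 - 1L, end = end1))   # 1-based inclusive -> 0-based half-open
}

#' Write gene models as GTF
#'
#' @param models A `GeneModelSet`.
#' @param path Output file path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "irquant") {
  stopifnot(inherits(models, "GeneModelSet"))
  ex <- models$exons
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, source, ex$start + 1L, ex$end, ex$strand,
    ex$gene_id, ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

## gene spans (min exon start .. max exon end over all transcripts)
gene_spans <- function(models) {
  models$exons[, .(chrom = chrom[1L], strand = strand[1L],
                   span_start = min(start), span_end = max(end)),
               by = gene_id]
}
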