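## End-to-end run: annotation -> boundaries -> classification -> retention,
## coverage, structure, motifs, with a JSON manifest of parameters and input
## checksums.  Intermediate artifacts are plain TSV with headers.

#' Run configuration for the end-to-end pipeline
#'
#' @param gtf,fasta,sam,expression Input paths (`expression` may be NULL:
#'   the retention table then reports every boundary as unclassified).
#' @param out_dir Output directory.
#' @param min_overlap Junction overlap for read classification (nt).
#' @param min_fragments Minimum informative fragments per boundary.
#' @param min_reads Minimum reads per coverage window.
#' @param min_flank Minimum intron/flanking-exon length for coverage (nt).
#' @param n_segments Segments in the gene-structure profile.
#' @param halfwidth Coverage half-window (nt).
#' @param motif_left,motif_right Exonic/intronic motif flank widths (nt).
#' @param classifier Thresholds from [classifier_params()].
#' @return A `RunConfig` list.
#' @export
run_config <- function(gtf, fasta, sam, expression = NULL, out_dir,
                       min_overlap = 10L, min_fragments = 10L,
                       min_reads = 50L, min_flank = 50L,
                       n_segments = 1000L, halfwidth = 50L,
                       motif_left = 3L, motif_right = 6L,
                       classifier = classifier_params()) {
  stopifnot(min_overlap > 0L, min_fragments > 0L, min_reads > 0L,
            min_flank >= 0L, n_segments > 0L, halfwidth > 0L)
  structure(list(gtf = gtf, fasta = fasta, sam = sam,
                 expression = expression, out_dir = out_dir,
                 min_overlap = as.integer(min_overlap),
                 min_fragments = as.integer(min_fragments),
                 min_reads = as.integer(min_reads),
                 min_flank = as.integer(min_flank),
                 n_segments = as.integer(n_segments),
                 halfwidth = as.integer(halfwidth),
                 motif_left = as.integer(motif_left),
                 motif_right = as.integer(motif_right),
                 classifier = classifier), class = "RunConfig")
}

#' Run the full pipeline
#'
#' Chains boundary extraction (with safety filter), gene classification,
#' fragment tallies with the retention table, coverage profiles (on the
#' min-length-filtered safe boundaries), the gene-structure profile and the
#' splice-site motif matrices, writing every product as TSV/JSON under
#' `cfg$out_dir` together with a manifest recording parameters and input
#' checksums.
#'
#' @param cfg A `RunConfig` from [run_config()].
#' @return Invisibly, a list with every in-memory product and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[irquant %s] ",
                                             format(Sys.time(), "%H:%M:%S")),
                                     ...)
  log_stage("parsing annotation ", cfg$gtf)
  models <- parse_gene_models(cfg$gtf)
  genome <- Biostrings::readDNAStringSet(cfg$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  log_stage("reading alignments ", cfg$sam)
  alignments <- read_alignments(cfg$sam)
  shared <- intersect(unique(models$exons$chrom), unique(alignments$chrom))
  if (length(shared) == 0L) {
    stop("no chromosome shared between GTF (",
         paste(unique(models$exons$chrom), collapse = ","), ") and SAM (",
         paste(unique(alignments$chrom), collapse = ","), ")")
  }

  log_stage("extracting boundaries")
  boundaries <- extract_boundaries(models)
  safe <- filter_safe(boundaries, models)
  write_boundaries(safe, file.path(cfg$out_dir, "boundaries.tsv"))

  gene_classes <- NULL
  if (!is.null(cfg$expression) && file.exists(cfg$expression %||% "")) {
    log_stage("classifying genes")
    classified <- classify_table(read_expression_table(cfg$expression),
                                 cfg$classifier)
    gene_classes <- classified$classes
    write_gene_classes(classified,
                       file.path(cfg$out_dir, "gene_classes.tsv"))
  } else {
    warning("no expression table; all boundaries reported unclassified")
  }

  log_stage("tallying fragments at ", nrow(safe), " safe boundaries")
  tallies <- tally_boundaries(alignments, safe, cfg$min_overlap,
                              cfg$min_fragments)
  retention <- suppressWarnings(
    build_retention_table(tallies, gene_classes))
  write_retention_table(retention, file.path(cfg$out_dir, "retention.tsv"))

  log_stage("coverage profiles")
  cov_b <- filter_min_flank(safe, cfg$min_flank)
  cov <- coverage_profiles(alignments, cov_b, cfg$halfwidth, cfg$min_reads)
  cov_sum <- aggregate_profiles(cov$profiles, gene_classes)
  write_coverage(cov$profiles, cov_sum,
                 file.path(cfg$out_dir, "coverage.tsv"))

  log_stage("structure profile")
  structure_p <- withCallingHandlers(
    structure_profile(models, cfg$n_segments),
    warning = function(w) {
      log_stage("structure: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_structure_profile(structure_p,
                          file.path(cfg$out_dir, "structure.tsv"))

  log_stage("splice-site motifs")
  motifs <- boundary_motifs(genome, safe, cfg$motif_left, cfg$motif_right)
  write_motif_matrix(motifs$donor, file.path(cfg$out_dir, "motif_donor.tsv"))
  write_motif_matrix(motifs$acceptor,
                     file.path(cfg$out_dir, "motif_acceptor.tsv"))

  inputs <- c(gtf = cfg$gtf, fasta = cfg$fasta, sam = cfg$sam,
              expression = cfg$expression %||% NA_character_)
  manifest <- list(
    package = "irquant",
    version = as.character(utils::packageVersion("irquant")),
    parameters = cfg[setdiff(names(cfg), c("gtf", "fasta", "sam",
                                           "expression", "out_dir"))],
    inputs = lapply(inputs[!is.na(inputs)], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_boundaries = nrow(boundaries), n_safe = nrow(safe),
    n_informative = sum(tallies$informative),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done in ", sprintf("%.1f s", manifest$elapsed_sec))
  invisible(list(models = models, boundaries = boundaries, safe = safe,
                 gene_classes = gene_classes, tallies = tallies,
                 retention = retention, coverage = cov,
                 coverage_summary = cov_sum, structure = structure_p,
                 motifs = motifs, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
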