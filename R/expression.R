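## Maternal / early-zygotic gene classification from stage expression units.
##
## Rule (strict thresholds, evaluated in order):
##   excluded_high : max(expr_0_2, expr_2_4) > 1000 expression units
##   early_zygotic : expr_2_4 > 10 and expr_2_4 >= 5 * expr_0_2
##   maternal      : expr_0_2 > 50
##   unclassified  : everything else

#' Default classifier thresholds
#'
#' @param zygotic_min_units Minimum 2--4 hr expression for an early-zygotic
#'   call (strict >; default 10).
#' @param zygotic_fold Minimum 2--4 hr / 0--2 hr fold change (>=; default 5).
#' @param maternal_min_units Minimum 0--2 hr expression for a maternal call
#'   (strict >; default 50).
#' @param exclusion_max_units Genes with either stage above this are excluded
#'   as extremely high expressed (strict >; default 1000).
#' @return Named list of thresholds.
#' @export
classifier_params <- function(zygotic_min_units = 10, zygotic_fold = 5,
                              maternal_min_units = 50,
                              exclusion_max_units = 1000) {
  stopifnot(zygotic_min_units > 0, zygotic_fold > 1,
            maternal_min_units > 0, exclusion_max_units > 0)
  list(zygotic_min_units = zygotic_min_units, zygotic_fold = zygotic_fold,
       maternal_min_units = maternal_min_units,
       exclusion_max_units = exclusion_max_units)
}

gene_class_levels <- c("early_zygotic", "maternal", "excluded_high",
                       "unclassified")

#' Classify genes by stage expression
#'
#' Vectorised over genes.  A gene with 2--4 hr expression above
#' `zygotic_min_units` and at least `zygotic_fold` times its 0--2 hr
#' expression (whatever that value, including zero) is early zygotic; a gene
#' that is not early zygotic but exceeds `maternal_min_units` at 0--2 hr is
#' maternal.  Genes exceeding `exclusion_max_units` at either stage are
#' excluded outright, taking precedence over both rules.
#'
#' @param expr_0_2,expr_2_4 Nonnegative finite expression units at the two
#'   stages.
#' @param params Thresholds from [classifier_params()].
#' @return Factor of labels (`early_zygotic`, `maternal`, `excluded_high`,
#'   `unclassified`), one per gene.
#' @export
classify_gene <- function(expr_0_2, expr_2_4, params = classifier_params()) {
  if (length(expr_0_2) != length(expr_2_4)) {
    stop("stage vectors differ in length")
  }
  bad <- !is.finite(expr_0_2) | !is.finite(expr_2_4) |
    expr_0_2 < 0 | expr_2_4 < 0
  if (any(bad)) {
    stop("negative or non-finite expression units at record ",
         which(bad)[1L])
  }
  label <- rep("unclassified", length(expr_0_2))
  label[expr_0_2 > params$maternal_min_units] <- "maternal"
  zyg <- expr_2_4 > params$zygotic_min_units &
    expr_2_4 >= params$zygotic_fold * expr_0_2
  label[zyg] <- "early_zygotic"
  label[pmax(expr_0_2, expr_2_4) > params$exclusion_max_units] <-
    "excluded_high"
  factor(label, levels = gene_class_levels)
}

#' Classify an expression table
#'
#' @param table data.frame with columns `gene_id`, `expr_0_2`, `expr_2_4`
#'   (extra columns ignored); gene_ids must be unique.
#' @param params Thresholds from [classifier_params()].
#' @return List with `classes` (data.table gene_id, gene_class) and `summary`
#'   (named counts per label, summing to the number of genes).
#' @export
classify_table <- function(table, params = classifier_params()) {
  tab <- as.data.table(table)
  stopifnot(all(c("gene_id", "expr_0_2", "expr_2_4") %in% names(tab)))
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  }
  cls <- classify_gene(tab$expr_0_2, tab$expr_2_4, params)
  classes <- data.table(gene_id = tab$gene_id, gene_class = cls)
  list(classes = classes,
       summary = as.list(table(cls)))
}

#' Read an expression table TSV (gene_id, expr_0_2, expr_2_4, ...)
#' @param path TSV path with header.
#' @return data.table.
#' @export
read_expression_table <- function(path) {
  fread(path, sep = "\t")
}

#' Write a gene-class table as TSV plus a JSON summary
#' @param classified Result of [classify_table()].
#' @param path TSV output path; the JSON summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_gene_classes <- function(classified, path) {
  fwrite(classified$classes, path, sep = "\t")
  jsonlite::write_json(classified$summary, paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
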