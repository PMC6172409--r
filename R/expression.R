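#' Construct an expression matrix for one omics layer
#'
#' A thin validated container: a nonnegative numeric matrix with genes as
#' rows (IDs namespaced by layer, e.g. `mrna:G0001`), samples as columns,
#' and a `layer` attribute identifying the omics layer. Values are expected
#' on a linear abundance scale (FPKM-like for mRNA/lncRNA, RPM-like for
#' miRNA); log transforms are applied internally by the stages that need
#' them.
#'
#' @param x numeric matrix, genes x samples, finite and >= 0, with unique
#'   row and column names.
#' @param layer one of `"mrna"`, `"mirna"`, `"lncrna"`.
#' @return the matrix with class `expr_matrix` and a `layer` attribute.
#' @export
expr_matrix <- function(x, layer = c("mrna", "mirna", "lncrna")) {
  layer <- match.arg(layer)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("expression matrix is empty")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(x))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(x))) stop("duplicate sample IDs")
  if (any(!is.finite(x))) stop("expression values must be finite")
  if (any(x < 0)) stop("expression values must be nonnegative")
  structure(x, layer = layer, class = c("expr_matrix", class(x)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> layer=%s: %d genes x %d samples\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  invisible(x)
}

#' Layer tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return the layer string.
#' @export
expr_layer <- function(x) attr(x, "layer")

# strip container attributes; used before matrix algebra that drops them anyway
as_plain_matrix <- function(x) {
  attr(x, "layer") <- NULL
  class(x) <- "matrix"
  unclass(x)[, , drop = FALSE]
}

#' Read / write the expression TSV dialect
#'
#' Genes as rows, first column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @param layer omics layer tag for the returned `expr_matrix`.
#' @return `read_expression_tsv`: an [expr_matrix()].
#' @export
read_expression_tsv <- function(path, layer = c("mrna", "mirna", "lncrna")) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expr_matrix(m, match.arg(layer))
}

#' @rdname read_expression_tsv
#' @param x an `expr_matrix` (or plain matrix with dimnames) to write.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), as_plain_matrix(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample annotation TSV
#'
#' One row per sample: `sample`, `group` (tumor/normal), `subtype`
#' (NA for normals), `time`, `event`, plus any clinical covariates.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_annotation_tsv
#' @param ann annotation data.frame.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(names(gene_sets)) || any(names(gene_sets) == ""))
    stop("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
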