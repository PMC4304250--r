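#' Read / write expression matrices, clinical tables and GMT gene sets
#'
#' Expression travels as tab-separated text with gene ids in the first
#' column and sample ids in the header; clinical tables as CSV; gene sets
#' as standard GMT (set name, description, tab-separated members).
#'
#' @param path File path.
#' @param expression Numeric matrix, genes x samples, with dimnames.
#' @name io
NULL

#' @rdname io
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname io
#' @param clinical Clinical data.frame as produced by [simulate_cohort()].
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname io
#' @param collection Named list of character vectors.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
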