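#' Construct an expression matrix
#'
#' A validated container for log2 expression intensities: genes in rows,
#' samples in columns, with unique identifiers on both axes and an
#' optional per-gene official gene symbol annotation (symbols may repeat
#' across probes; probe collapse resolves them).
#'
#' @param values numeric matrix, genes x samples, all values finite.
#' @param gene_ids character vector of unique gene/probe identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @param gene_symbols optional character vector of gene symbols, one per
#'   row; `NA` marks probes without annotation.
#' @return An object of class `expression_matrix`: a list with fields
#'   `values`, `gene_ids`, `sample_ids`, `gene_symbols`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length (", length(sample_ids),
         ") does not match column count (", ncol(values), ")")
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) {
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gene_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  if (!is.null(gene_symbols)) {
    gene_symbols <- as.character(gene_symbols)
    if (length(gene_symbols) != nrow(values)) {
      stop("gene_symbols length does not match row count")
    }
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, gene_symbols = gene_symbols),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples", if (!is.null(x$gene_symbols)) " (with gene symbols)",
      "\n", sep = "")
  invisible(x)
}

# Subset keeping class and symbol annotation; indices or ids.
em_subset <- function(x, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else resolve_idx(genes, x$gene_ids, "gene")
  si <- if (is.null(samples)) seq_along(x$sample_ids) else resolve_idx(samples, x$sample_ids, "sample")
  expression_matrix(x$values[gi, si, drop = FALSE],
                    gene_ids = x$gene_ids[gi],
                    sample_ids = x$sample_ids[si],
                    gene_symbols = if (is.null(x$gene_symbols)) NULL else x$gene_symbols[gi])
}

resolve_idx <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      stop("unknown ", what, " id(s): ",
           paste(idx[is.na(pos)], collapse = ", "))
    }
    pos
  } else {
    idx <- as.integer(idx)
    if (any(idx < 1L | idx > length(ids))) stop(what, " index out of range")
    idx
  }
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids and an
#' optional second column `gene_symbol`. Values are log2 intensities.
#'
#' @param path file path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene id column plus samples")
  has_symbols <- length(header) >= 2 &&
    tolower(header[2]) %in% c("gene_symbol", "symbol", "ogs")
  first_data <- if (has_symbols) 3L else 2L
  sample_ids <- header[first_data:length(header)]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup) > 0) {
    stop("duplicate sample id(s) in header: ", paste(unique(dup), collapse = ", "))
  }
  gene_ids <- df[[1]]
  raw <- as.matrix(df[, first_data:ncol(df), drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(vals) & raw != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric expression value '", raw[bad[1, 1], bad[1, 2]],
         "' at row ", bad[1, 1], " (gene '", gene_ids[bad[1, 1]],
         "'), column ", bad[1, 2], " (sample '", sample_ids[bad[1, 2]], "')")
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop("missing expression value at row ", bad[1, 1], ", column ", bad[1, 2])
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = sample_ids,
                    gene_symbols = if (has_symbols) df[[2]] else NULL)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: round-trips identifiers, symbols and
#' values (modulo float formatting).
#'
#' @param x an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(x$gene_symbols)) df$gene_symbol <- x$gene_symbols
  df <- cbind(df, as.data.frame(x$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
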