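#' Construct a bicluster
#'
#' @param id positive integer identifier.
#' @param sample_ids non-empty character vector of member samples.
#' @param gene_ids non-empty character vector of member genes.
#' @param score coherence score (lower is more coherent).
#' @return An object of class `bicluster`.
#' @export
bicluster <- function(id, sample_ids, gene_ids, score = NA_real_) {
  id <- as.integer(id)
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) == 0) stop("bicluster ", id, ": empty sample set")
  if (length(gene_ids) == 0) stop("bicluster ", id, ": empty gene set")
  structure(list(id = id, sample_ids = sample_ids, gene_ids = gene_ids,
                 score = as.numeric(score)),
            class = "bicluster")
}

#' Construct a set of biclusters
#'
#' Bicluster ids must be unique and contiguous from 1. Samples and genes
#' may belong to more than one bicluster.
#'
#' @param biclusters list of [bicluster()] objects.
#' @param config optional `run_config` snapshot recording provenance.
#' @return An object of class `bicluster_set`.
#' @export
bicluster_set <- function(biclusters, config = NULL) {
  stopifnot(is.list(biclusters))
  ids <- vapply(biclusters, function(b) b$id, integer(1))
  if (!identical(sort(ids), seq_along(ids))) {
    stop("bicluster ids must be unique and contiguous from 1 (got: ",
         paste(ids, collapse = ", "), ")")
  }
  biclusters <- biclusters[order(ids)]
  structure(list(biclusters = biclusters, config = config),
            class = "bicluster_set")
}

#' @export
length.bicluster_set <- function(x) length(x$biclusters)

#' @export
print.bicluster_set <- function(x, ...) {
  ns <- vapply(x$biclusters, function(b) length(b$sample_ids), integer(1))
  ng <- vapply(x$biclusters, function(b) length(b$gene_ids), integer(1))
  cat("bicluster_set with ", length(ns), " biclusters; samples per bicluster ",
      min(ns), "-", max(ns), " (mean ", round(mean(ns), 1), "), genes ",
      min(ng), "-", max(ng), "\n", sep = "")
  invisible(x)
}

#' Write a bicluster set to a record file
#'
#' One TSV record per bicluster: id, coherence score, member counts, and
#' comma-joined sample and gene id lists. Lossless round-trip with
#' [read_biclusters()]. An empty set writes just the header.
#'
#' @param bcs a `bicluster_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(bcs, path) {
  stopifnot(inherits(bcs, "bicluster_set"))
  df <- data.frame(
    id = vapply(bcs$biclusters, function(b) b$id, integer(1)),
    score = vapply(bcs$biclusters, function(b) b$score, numeric(1)),
    n_samples = vapply(bcs$biclusters, function(b) length(b$sample_ids), integer(1)),
    n_genes = vapply(bcs$biclusters, function(b) length(b$gene_ids), integer(1)),
    sample_ids = vapply(bcs$biclusters, function(b) paste(b$sample_ids, collapse = ","), character(1)),
    gene_ids = vapply(bcs$biclusters, function(b) paste(b$gene_ids, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bicluster set from a record file
#'
#' @param path file written by [write_biclusters()].
#' @param expression optional `expression_matrix`; when given, every
#'   sample and gene id is validated against it and unknown ids raise a
#'   referential error.
#' @return A `bicluster_set`.
#' @export
read_biclusters <- function(path, expression = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  needed <- c("id", "score", "sample_ids", "gene_ids")
  if (!all(needed %in% names(df))) {
    stop("bicluster record file must have columns: ",
         paste(needed, collapse = ", "))
  }
  bcl <- lapply(seq_len(nrow(df)), function(i) {
    bicluster(as.integer(df$id[i]),
              strsplit(df$sample_ids[i], ",", fixed = TRUE)[[1]],
              strsplit(df$gene_ids[i], ",", fixed = TRUE)[[1]],
              as.numeric(df$score[i]))
  })
  bcs <- bicluster_set(bcl)
  if (!is.null(expression)) {
    for (b in bcs$biclusters) {
      unk_s <- setdiff(b$sample_ids, expression$sample_ids)
      if (length(unk_s) > 0) {
        stop("bicluster ", b$id, " references unknown sample id(s): ",
             paste(unk_s, collapse = ", "))
      }
      unk_g <- setdiff(b$gene_ids, expression$gene_ids)
      if (length(unk_g) > 0) {
        stop("bicluster ", b$id, " references unknown gene id(s): ",
             paste(unk_g, collapse = ", "))
      }
    }
  }
  bcs
}

#' Binary membership matrix of a bicluster set
#'
#' @param truth a `bicluster_set` (e.g. planted truth from
#'   [simulate_dataset()]).
#' @param sample_ids sample universe defining the rows; defaults to the
#'   union of member samples in order of first appearance.
#' @return Binary matrix, samples x biclusters; entry 1 iff the sample
#'   belongs to the bicluster.
#' @export
true_membership_matrix <- function(truth, sample_ids = NULL) {
  stopifnot(inherits(truth, "bicluster_set"))
  if (is.null(sample_ids)) {
    sample_ids <- unique(unlist(lapply(truth$biclusters, `[[`, "sample_ids")))
  }
  m <- matrix(0L, nrow = length(sample_ids), ncol = length(truth),
              dimnames = list(sample_ids,
                              paste0("bc", seq_len(length(truth)))))
  for (b in truth$biclusters) {
    pos <- match(b$sample_ids, sample_ids)
    if (anyNA(pos)) {
      stop("bicluster ", b$id, " contains sample(s) outside the universe: ",
           paste(b$sample_ids[is.na(pos)], collapse = ", "))
    }
    m[pos, b$id] <- 1L
  }
  m
}

#' Mean best-match sample Jaccard between found and planted biclusters
#'
#' For every truth bicluster, the maximum Jaccard index between its
#' sample set and any found bicluster's sample set; averaged over the
#' truth set. 1 means perfect recovery, 0 disjoint.
#'
#' @param found,truth `bicluster_set` objects over the same sample
#'   universe.
#' @return A number in \[0, 1\].
#' @export
recovery_jaccard <- function(found, truth) {
  stopifnot(inherits(found, "bicluster_set"), inherits(truth, "bicluster_set"))
  if (length(truth) == 0) stop("truth bicluster set is empty")
  if (length(found) == 0) stop("found bicluster set is empty")
  per_truth <- vapply(truth$biclusters, function(tb) {
    max(vapply(found$biclusters, function(fb) {
      inter <- length(intersect(tb$sample_ids, fb$sample_ids))
      inter / (length(tb$sample_ids) + length(fb$sample_ids) - inter)
    }, numeric(1)))
  }, numeric(1))
  mean(per_truth)
}
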