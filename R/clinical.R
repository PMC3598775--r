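# Controlled vocabularies for the categorical clinical covariates.
clinical_vocab <- list(
  ln_status = c("LN+", "LN-"),
  er_status = c("ER+", "ER-"),
  pgr_status = c("PgR+", "PgR-"),
  grade = c("G1", "G2", "G3"),
  subtype = c("Basal", "Her2", "LumA", "LumB", "Normal", "None")
)

clinical_columns <- c("sample_id", "cohort", "ln_status", "er_status",
                      "pgr_status", "grade", "subtype", "size_mm",
                      "age_years", "dfs_time_years", "dfs_event")

#' Construct a clinical annotation table
#'
#' One row per sample: cohort, lymph-node status, hormone-receptor
#' status (ER, PgR), histological grade, molecular subtype, tumour size
#' (mm), patient age (years), plus disease-free survival time (years)
#' and the relapse event indicator. Missing clinical values are `NA`;
#' categorical values are checked against their vocabularies.
#'
#' @param df data.frame with columns `sample_id`, `cohort`, `ln_status`,
#'   `er_status`, `pgr_status`, `grade`, `subtype`, `size_mm`,
#'   `age_years`, `dfs_time_years`, `dfs_event`.
#' @return The validated data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  missing_cols <- setdiff(clinical_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup) > 0) {
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  }
  df$cohort <- as.character(df$cohort)
  for (col in names(clinical_vocab)) {
    v <- as.character(df[[col]])
    bad <- !is.na(v) & !(v %in% clinical_vocab[[col]])
    if (any(bad)) {
      stop("sample '", df$sample_id[which(bad)[1]], "': ", col, " value '",
           v[which(bad)[1]], "' not in allowed vocabulary {",
           paste(clinical_vocab[[col]], collapse = ", "), "}")
    }
    df[[col]] <- v
  }
  for (col in c("size_mm", "age_years", "dfs_time_years")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  neg <- !is.na(df$size_mm) & df$size_mm < 0
  if (any(neg)) {
    stop("sample '", df$sample_id[which(neg)[1]], "': size_mm must be >= 0")
  }
  neg <- !is.na(df$age_years) & df$age_years < 0
  if (any(neg)) {
    stop("sample '", df$sample_id[which(neg)[1]], "': age_years must be >= 0")
  }
  if (anyNA(df$dfs_time_years)) {
    stop("dfs_time_years must be present for every sample")
  }
  if (any(df$dfs_time_years < 0)) {
    stop("sample '", df$sample_id[which(df$dfs_time_years < 0)[1]],
         "': dfs_time_years must be >= 0")
  }
  df$dfs_event <- as.integer(df$dfs_event)
  if (anyNA(df$dfs_event) || !all(df$dfs_event %in% c(0L, 1L))) {
    stop("dfs_event must be 0 or 1 for every sample")
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical annotation table from CSV
#'
#' Missing values are encoded as `NA`. Unknown categorical tokens raise
#' an error listing the allowed vocabulary.
#'
#' @param path CSV file path.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                 check.names = FALSE)
  clinical_table(df)
}

#' Write a clinical annotation table to CSV
#' @param ct a `clinical_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(ct, path) {
  stopifnot(inherits(ct, "clinical_table"))
  write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}
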