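#' Read a miRNA Ct matrix from TSV
#'
#' Dialect: tab-delimited, UTF-8, header row of sample ids, first column the
#' miRNA id, numeric cells, empty cell = undetected reaction (read as `NA`).
#'
#' @param path file path.
#' @return numeric matrix, miRNAs x samples, `NA` for undetected.
#' @export
read_ct_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Read an expression matrix (genes or miRNAs x samples) from TSV
#'
#' Same dialect as [read_ct_matrix()]; values are on a log-like additive
#' scale with larger = more expressed.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_expression_matrix <- read_ct_matrix

#' Write a feature x sample matrix as TSV
#'
#' Inverse of [read_ct_matrix()]: first column `feature_id`, then one column
#' per sample; `NA` serialises as an empty cell (the undetected sentinel).
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @param id_col name for the id column (default `"feature_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a miRNA target prediction database from TSV
#'
#' Dialect: two columns `mirna_id`, `gene_symbol`, one predicted pair per
#' row (a flattened TargetScan-style family-to-gene map).
#'
#' @param path file path.
#' @param source_label free-text provenance label attached as an attribute.
#' @return named list mapping miRNA id to a character vector of unique gene
#'   symbols.
#' @export
read_target_db <- function(path, source_label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna_id", "gene_symbol") %in% names(df)))
  db <- lapply(split(df$gene_symbol, df$mirna_id), unique)
  attr(db, "source_label") <- source_label
  db
}

#' Write a target database as a two-column TSV
#'
#' @param db named list, miRNA id -> gene symbols.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_target_db <- function(db, path) {
  # header-only file is valid for an empty database
  df <- data.frame(
    mirna_id = if (length(db)) rep(names(db), lengths(db)) else character(),
    gene_symbol = if (length(db)) unlist(db, use.names = FALSE)
                  else character(),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene-set collections from a GMT file
#'
#' @param path GMT file (term, description, tab-separated genes per line).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene-set collections to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of term descriptions,
#'   recycled; defaults to `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Expected columns: `sample_id`, `subtype` (IBC / non-IBC), `t_status`
#' (low / high), `n_status` (pos / neg), `m_status` (M0 / M+), `stage`
#' (I..IV), `grade` (well / moderate / poor), `er` (pos / neg), `her2`
#' (pos / neg), optional `age` in years.
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_sample_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df), !anyDuplicated(df$sample_id))
  df
}

#' Read a survival table from TSV
#'
#' Expected columns: `sample_id`, `dataset_id`, `endpoint` (DMFS / RFS / OS),
#' `time` (months, >= 0), `event` (0/1).
#'
#' @param path file path.
#' @return data.frame, one row per sample.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "dataset_id", "endpoint", "time", "event")
                %in% names(df)),
            all(df$time >= 0), all(df$event %in% c(0, 1)))
  df
}
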