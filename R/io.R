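#' Write a count matrix in Matrix Market format with TSV sidecars
#'
#' Writes `matrix.mtx`, `features.tsv` (gene identifiers) and `barcodes.tsv`
#' (cell identifiers) into a directory, the conventional on-disk layout for
#' single-cell UMI matrices.
#'
#' @param counts genes x cells sparse matrix with dimnames.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  .assert_counts(.as_sparse(counts))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(.as_sparse(counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return genes x cells sparse dgCMatrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  m <- .as_sparse(Matrix::readMM(paths[1L]))
  rownames(m) <- readLines(paths[2L])
  colnames(m) <- readLines(paths[3L])
  m
}

#' Write a simulated dataset to disk
#'
#' Writes the count matrix (Matrix Market + sidecars), per-cell metadata and
#' ground truth (labels, doublet flags, pseudotime, branch probabilities) as
#' TSV, and the generating configuration as JSON.
#'
#' @param sim An `hspc_sim` from [generate_reference()]/[generate_query()].
#' @param dir Output directory.
#' @param config Optional [sim_config()] to record alongside the data.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, config = NULL) {
  stopifnot(inherits(sim, "hspc_sim"))
  write_counts_mtx(sim$counts, dir)
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  tr <- sim$truth
  truth_df <- data.frame(cell_id = tr$cell_ids,
                         label = unname(tr$cell_labels),
                         doublet = unname(tr$doublet_flags),
                         pseudotime = unname(tr$pseudotime),
                         stringsAsFactors = FALSE)
  truth_df <- cbind(truth_df, as.data.frame(tr$branch_probabilities,
                                            row.names = NULL))
  write_tsv(truth_df, file.path(dir, "truth.tsv"))
  if (!is.null(config))
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a data frame as TSV
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
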