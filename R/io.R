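#' Write a cohort as MatrixMarket + TSV sidecars
#'
#' Emits `matrix.mtx` (genes x cells, sparse), `genes.tsv`, `barcodes.tsv`
#' and `annotations.tsv` (cell_id, patient_id, malignant) into a directory,
#' the dialect [read_expression()] consumes.
#'
#' @param cohort List with `matrix` and `annotations` (from
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_mtx <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(cohort$matrix, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cohort$matrix), file.path(dir, "genes.tsv"))
  writeLines(colnames(cohort$matrix), file.path(dir, "barcodes.tsv"))
  utils::write.table(cohort$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an expression matrix
#'
#' Accepts either a directory containing `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv`, a path to an `.mtx` file with sidecars in its directory,
#' or a dense TSV (genes in rows, first column gene names).
#'
#' @param path Directory, `.mtx` path, or dense TSV path.
#' @return A gene x cell matrix (dense, base matrix).
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "matrix.mtx")
  if (grepl("\\.mtx$", path)) {
    d <- dirname(path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(file.path(d, "genes.tsv"))
    colnames(m) <- readLines(file.path(d, "barcodes.tsv"))
    return(m)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Read a cell annotation table
#'
#' TSV with columns `cell_id`, `patient_id`, `malignant` (0/1).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "patient_id", "malignant")
  if (!all(need %in% names(ann)))
    stop("annotations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  ann$malignant <- as.integer(ann$malignant)
  ann
}
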