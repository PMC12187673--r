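#' Write a labeled dataset in 10x-style Matrix Market layout
#'
#' Writes `matrix.mtx` (genes x cells, the 10x orientation), `genes.tsv`,
#' `barcodes.tsv` and `labels.tsv` (header `barcode<TAB>label`) into `dir`.
#'
#' @param dataset A `synthetic_dataset` or a list with `counts` (cells x
#'   genes) and `labels`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset_10x <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- dataset$counts
  m <- Matrix::Matrix(t(counts), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(barcode = rownames(counts), label = as.character(dataset$labels)),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Read a labeled dataset from 10x-style Matrix Market layout
#'
#' Counterpart of [write_dataset_10x()]; also accepts a dense
#' `counts.csv` (cells x genes, row names = barcodes) with `labels.tsv`.
#'
#' @param dir Directory holding `matrix.mtx` + `genes.tsv` + `barcodes.tsv`
#'   or `counts.csv`, plus `labels.tsv`.
#' @return A list with `counts` (cells x genes integer matrix) and `labels`
#'   (factor).
#' @export
read_dataset_10x <- function(dir) {
  lab_path <- file.path(dir, "labels.tsv")
  if (!file.exists(lab_path)) stopf("invalid_input", "missing %s", lab_path)
  lab <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
  if (file.exists(file.path(dir, "matrix.mtx"))) {
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    genes <- readLines(file.path(dir, "genes.tsv"))
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(barcodes, genes)
  } else if (file.exists(file.path(dir, "counts.csv"))) {
    counts <- as.matrix(utils::read.csv(file.path(dir, "counts.csv"), row.names = 1))
  } else {
    stopf("invalid_input", "no matrix.mtx or counts.csv in %s", dir)
  }
  storage.mode(counts) <- "integer"
  lab <- lab[match(rownames(counts), lab$barcode), ]
  if (anyNA(lab$label)) stopf("invalid_input", "labels.tsv does not cover all barcodes")
  list(counts = counts, labels = factor(lab$label))
}
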