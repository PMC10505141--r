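#' Annotated single-cell corpus
#'
#' Bundles a genes x cells expression matrix with a per-cell annotation
#' table carrying patient of origin and a three-level cell-type label
#' hierarchy (major / minor / subset). This is the substrate of every
#' stage of the benchmarking pipeline: raw counts go in, CP10K-normalized
#' and SMOTE-augmented corpora come out, and mixtures are sampled from it.
#'
#' @param counts genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   non-negative values with gene rownames and cell-id colnames.
#' @param cell_table data.frame with one row per cell and columns
#'   `cell_id`, `patient`, `major`, `minor`, `subset`, `is_synthesized`
#'   (logical), in the same order as the columns of `counts`. A column
#'   `subtype` (molecular subtype of the patient) is optional but carried
#'   through when present.
#' @return an object of class `annotated_corpus`.
#' @export
annotated_corpus <- function(counts, cell_table) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (!"is_synthesized" %in% names(cell_table)) cell_table$is_synthesized <- FALSE
  obj <- structure(list(counts = counts, cell_table = cell_table),
                   class = "annotated_corpus")
  validate_corpus(obj)
  obj
}

#' Validate an annotated corpus
#'
#' Checks the structural invariants: matching dimensions, unique cell
#' ids, non-negative expression, and label nesting (each minor label
#' belongs to exactly one major, each subset to exactly one minor).
#'
#' @param corpus an `annotated_corpus`.
#' @return the corpus, invisibly; stops with a message on violation.
#' @export
validate_corpus <- function(corpus) {
  ct <- corpus$cell_table
  need <- c("cell_id", "patient", "major", "minor", "subset", "is_synthesized")
  miss <- setdiff(need, names(ct))
  if (length(miss)) stop("cell_table missing columns: ", paste(miss, collapse = ", "))
  if (ncol(corpus$counts) != nrow(ct))
    stop("counts has ", ncol(corpus$counts), " cells but cell_table has ", nrow(ct))
  if (anyDuplicated(ct$cell_id)) stop("duplicate cell ids")
  if (!identical(colnames(corpus$counts), as.character(ct$cell_id)))
    stop("counts colnames do not match cell_table$cell_id")
  if (any(corpus$counts@x < 0)) stop("negative expression values")
  # nesting: a child label may appear under exactly one parent
  bad_minor <- unique(ct[, c("major", "minor")])
  if (anyDuplicated(bad_minor$minor))
    stop("minor labels not nested: ",
         paste(bad_minor$minor[duplicated(bad_minor$minor)], collapse = ", "))
  bad_sub <- unique(ct[, c("minor", "subset")])
  if (anyDuplicated(bad_sub$subset))
    stop("subset labels not nested: ",
         paste(bad_sub$subset[duplicated(bad_sub$subset)], collapse = ", "))
  invisible(corpus)
}

#' @export
print.annotated_corpus <- function(x, ...) {
  ct <- x$cell_table
  cat("annotated_corpus:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("  patients:", length(unique(ct$patient)),
      " major types:", length(unique(ct$major)),
      " minor:", length(unique(ct$minor)),
      " subset:", length(unique(ct$subset)), "\n")
  n_syn <- sum(ct$is_synthesized)
  if (n_syn > 0) cat("  synthesized cells:", n_syn, "\n")
  invisible(x)
}

#' Cell-type labels at a lineage level
#'
#' @param corpus an `annotated_corpus`.
#' @param level "major", "minor", "subset", or any other label column
#'   present in the cell table (e.g. the mixed-granularity column built
#'   by [simulate_lineage_set()]).
#' @return character vector of per-cell labels at that granularity.
#' @export
labels_at_level <- function(corpus, level = "major") {
  if (!level %in% names(corpus$cell_table))
    stop("no label column '", level, "' in the cell table")
  as.character(corpus$cell_table[[level]])
}

#' Subset a corpus by cell index or logical mask
#'
#' Expression values are untouched; only membership changes.
#'
#' @param corpus an `annotated_corpus`.
#' @param keep integer or logical index over cells.
#' @return the subsetted `annotated_corpus`.
#' @export
subset_cells <- function(corpus, keep) {
  ct <- corpus$cell_table[keep, , drop = FALSE]
  rownames(ct) <- NULL
  annotated_corpus(corpus$counts[, keep, drop = FALSE], ct)
}

#' Write a corpus as Matrix Market + TSV sidecars
#'
#' Lays out `matrix.mtx` (genes x cells), `genes.tsv`, `barcodes.tsv`
#' and `cells.tsv` (the full annotation table) under `dir`, the plain-text
#' exchange layout used by droplet single-cell pipelines.
#'
#' @param corpus an `annotated_corpus`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(corpus$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(corpus$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(corpus$counts), file.path(dir, "barcodes.tsv"))
  write.table(corpus$cell_table, file.path(dir, "cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and `cells.tsv`.
#' @return an `annotated_corpus`.
#' @export
read_corpus <- function(dir) {
  m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  ct <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  ct$is_synthesized <- as.logical(ct$is_synthesized)
  annotated_corpus(m, ct)
}

#' Read a tiny dense corpus from CSV
#'
#' Convenience reader for hand-written test matrices: a genes x cells CSV
#' with gene ids in the first column, plus a cell annotation TSV/CSV.
#'
#' @param counts_csv path to the dense genes x cells CSV.
#' @param cells_file path to the annotation table (TSV or CSV by
#'   extension).
#' @return an `annotated_corpus`.
#' @export
read_corpus_csv <- function(counts_csv, cells_file) {
  m <- as.matrix(read.csv(counts_csv, row.names = 1, check.names = FALSE))
  sep <- if (grepl("\\.csv$", cells_file)) "," else "\t"
  ct <- read.delim(cells_file, sep = sep, stringsAsFactors = FALSE)
  annotated_corpus(m, ct)
}
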