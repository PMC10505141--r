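#' Build a single-cell reference profile (original cells only)
#'
#' Reference-based deconvolution must not see SMOTE-synthesized cells:
#' the reference keeps only cells with `is_synthesized = FALSE` and
#' projects their labels to the requested lineage level. Construction is
#' deterministic (no RNG).
#'
#' @param corpus an augmented (or plain) `annotated_corpus` carrying
#'   `is_synthesized` flags.
#' @param level label granularity of the reference ("major", "minor",
#'   "subset", or another label column).
#' @param required_types optional character vector of types the
#'   reference must cover (e.g. the truth columns of the mixtures it will
#'   deconvolve); a required type with zero original cells is an error.
#' @return a `reference_profile`: list with `expression` (genes x cells),
#'   `labels`, `patients`, `level`.
#' @export
build_reference <- function(corpus, level = "major", required_types = NULL) {
  ct <- corpus$cell_table
  if (!"is_synthesized" %in% names(ct) || anyNA(ct$is_synthesized))
    stop("corpus carries no is_synthesized flags")
  keep <- !ct$is_synthesized
  if (!any(keep)) stop("no original cells in corpus")
  lab <- labels_at_level(corpus, level)[keep]
  if (!is.null(required_types)) {
    missing <- setdiff(required_types, unique(lab))
    if (length(missing))
      stop("required types with zero original cells: ",
           paste(missing, collapse = ", "))
  }
  structure(list(expression = corpus$counts[, keep, drop = FALSE],
                 labels = lab,
                 patients = as.character(ct$patient[keep]),
                 level = level),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("reference_profile:", nrow(x$expression), "genes x",
      ncol(x$expression), "original cells,",
      length(unique(x$labels)), "types at level", x$level, "\n")
  invisible(x)
}

#' Build a per-type mean signature matrix
#'
#' Column `t` is the mean CP10K expression over reference cells labelled
#' `t`. Optionally restricted to the union of each type's `top_markers`
#' genes ranked by fold-change between the type's mean and the mean of
#' all other types (pseudocount 1e-8 guards zero denominators). Columns
#' follow the sorted canonical type order used by truth tables.
#'
#' @param ref a `reference_profile`.
#' @param top_markers optional integer; if set, keep only the union of
#'   per-type top marker rows.
#' @return a genes x types `signature_matrix` (dense matrix with a
#'   class attribute).
#' @export
build_signature <- function(ref, top_markers = NULL) {
  types <- sort(unique(ref$labels))
  if (length(types) < 2) stop("need at least two types for a signature")
  sig <- do.call(cbind, lapply(types, function(ty) {
    cols <- ref$labels == ty
    if (!any(cols)) stop("type with zero cells: ", ty)
    Matrix::rowMeans(ref$expression[, cols, drop = FALSE])
  }))
  dimnames(sig) <- list(rownames(ref$expression), types)
  if (!is.null(top_markers)) {
    keep <- unique(unlist(lapply(types, function(ty) {
      others <- rowMeans(sig[, colnames(sig) != ty, drop = FALSE])
      fc <- (sig[, ty] + 1e-8) / (others + 1e-8)
      rownames(sig)[order(-fc)[seq_len(min(top_markers, nrow(sig)))]]
    })))
    sig <- sig[sort(keep), , drop = FALSE]
  }
  structure(sig, class = c("signature_matrix", class(sig)))
}

#' Write a signature matrix as TSV
#'
#' @param sig a `signature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  write.table(unclass(sig), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
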