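#' Non-negative least-squares deconvolution baseline
#'
#' A fully in-repo reference-regression baseline so the framework runs
#' end-to-end without external tools: for each mixture `b`, solves
#' `min || S w - b ||^2` subject to `w >= 0` (Lawson-Hanson NNLS) over
#' the gene intersection of bulk and signature, and reports
#' `w / sum(w) * 100` as predicted percentages. Because signature
#' columns are per-cell means on a common CP10K scale, the weights carry
#' cell-count semantics and normalize directly to proportions.
#'
#' @param bulk mixtures x genes matrix of pseudobulk expression (or a
#'   `pseudobulk_set`, whose `$expression` is used).
#' @param sig a genes x types [build_signature()] matrix.
#' @return a `prediction_table`: mixtures x types matrix of percentages
#'   (rows sum to 100) with attributes `method` and `provenance`.
#' @export
nnls_deconvolve <- function(bulk, sig) {
  if (inherits(bulk, "pseudobulk_set")) {
    if (is.null(bulk$expression)) stop("pseudobulk set has no expression")
    bulk <- bulk$expression
  }
  bulk <- as.matrix(bulk)
  genes <- intersect(colnames(bulk), rownames(sig))
  if (length(genes) < ncol(sig))
    stop("bulk and signature share only ", length(genes),
         " genes; need at least ", ncol(sig))
  S <- unclass(sig)[genes, , drop = FALSE]
  dup <- duplicated(t(S))
  if (any(dup))
    stop("signature is rank-deficient: identical columns ",
         paste(colnames(S)[dup], collapse = ", "))
  B <- bulk[, genes, drop = FALSE]
  # tiny Tikhonov rows keep the active-set solver stable when the bulk is
  # an exact non-negative combination of signature columns (zero
  # residual); the bias on recovered weights is O(1e-12), far below the
  # reporting precision
  ridge <- 1e-6 * norm(S, "2")
  S_aug <- rbind(S, diag(ridge, ncol(S)))
  zero_tail <- rep(0, ncol(S))
  pred <- t(apply(B, 1, function(b) {
    w <- pracma::lsqnonneg(S_aug, c(as.numeric(b), zero_tail))$x
    if (sum(w) <= 0) {
      warning("all-zero NNLS solution; reporting uniform proportions")
      w <- rep(1, ncol(S))
    }
    w / sum(w) * 100
  }))
  dimnames(pred) <- list(rownames(bulk), colnames(S))
  as_prediction_table(pred, method = "nnls",
                      provenance = list(backend = "pracma::lsqnonneg",
                                        n_genes = length(genes)))
}

#' Coerce a raw prediction matrix into the prediction contract
#'
#' Enforces the simplex contract every scorer relies on: negative or
#' non-finite entries are clipped to 0 (counts logged in provenance),
#' missing truth-type columns can be added as zeros, and every row is
#' renormalized to sum to 100.
#'
#' @param pred mixtures x types numeric matrix (any non-negative scale).
#' @param method method name recorded on the table.
#' @param types optional canonical type order; missing columns are
#'   zero-filled with a warning and columns are reordered to match.
#' @param provenance optional list stored on the result.
#' @return a `prediction_table`.
#' @export
as_prediction_table <- function(pred, method, types = NULL,
                                provenance = list()) {
  pred <- as.matrix(pred)
  n_bad <- sum(!is.finite(pred) | pred < 0)
  if (n_bad > 0) {
    pred[!is.finite(pred) | pred < 0] <- 0
    provenance$clipped_entries <- n_bad
  }
  if (!is.null(types)) {
    extra <- setdiff(colnames(pred), types)
    if (length(extra))
      stop("prediction types not mappable to canonical order: ",
           paste(extra, collapse = ", "))
    missing <- setdiff(types, colnames(pred))
    if (length(missing)) {
      warning("prediction lacks types, zero-filled: ",
              paste(missing, collapse = ", "))
      pred <- cbind(pred, matrix(0, nrow(pred), length(missing),
                                 dimnames = list(NULL, missing)))
      provenance$zero_filled <- missing
    }
    pred <- pred[, types, drop = FALSE]
  }
  rs <- rowSums(pred)
  if (any(rs <= 0)) stop("prediction rows with zero total mass")
  if (any(abs(rs - 100) > 1e-6)) provenance$renormalized <- TRUE
  pred <- pred / rs * 100
  structure(pred, class = c("prediction_table", "matrix", "array"),
            method = method, provenance = provenance)
}

#' Run an external deconvolution method through the adapter contract
#'
#' The nine benchmarked methods stay out of this package; each is reached
#' through a declared adapter: the bulk matrix and reference are
#' materialized on disk in the adapter's input dialect (linear CP10K or
#' `log2(x + 1)`, the convention hspe expects), the external command is
#' invoked out-of-process with path placeholders substituted, and its
#' TSV output (mixtures x types) is parsed and pushed through
#' [as_prediction_table()] — clipping, zero-filling missing types, and
#' renormalizing rows to 100.
#'
#' @param bulk mixtures x genes matrix (or `pseudobulk_set`).
#' @param ref a `reference_profile` (written as expression TSV +
#'   labels TSV), or `NULL` for reference-free methods.
#' @param config adapter configuration list (or path to a YAML file)
#'   with fields `name`, `command` (template containing `{bulk}`,
#'   `{ref_expr}`, `{ref_labels}`, `{out}`), `input_dialect`
#'   (`"linear"` or `"log2p1"`), and optionally `types` (canonical
#'   column order for the output).
#' @param workdir scratch directory for materialized files (a temporary
#'   directory by default).
#' @return a `prediction_table`.
#' @export
run_adapter <- function(bulk, ref, config, workdir = tempfile("adapter_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$name), !is.null(config$command))
  dialect <- match.arg(config$input_dialect %||% "linear",
                       c("linear", "log2p1"))
  if (inherits(bulk, "pseudobulk_set")) bulk <- bulk$expression
  bulk <- as.matrix(bulk)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  tx <- function(m) if (dialect == "log2p1") log2(m + 1) else m
  paths <- list(bulk = file.path(workdir, "bulk.tsv"),
                ref_expr = file.path(workdir, "ref_expr.tsv"),
                ref_labels = file.path(workdir, "ref_labels.tsv"),
                out = file.path(workdir, "predictions.tsv"))
  write.table(tx(bulk), paths$bulk, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(ref)) {
    write.table(tx(as.matrix(ref$expression)), paths$ref_expr,
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(cell_id = colnames(ref$expression),
                           label = ref$labels, patient = ref$patients),
                paths$ref_labels, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cmd <- config$command
  for (k in names(paths)) cmd <- gsub(paste0("{", k, "}"), paths[[k]],
                                      cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0 || !file.exists(paths$out))
    stop("adapter '", config$name, "' failed (exit ", status, "): ", cmd)
  pred <- as.matrix(read.delim(paths$out, row.names = 1, check.names = FALSE))
  as_prediction_table(pred, method = config$name, types = config$types,
                      provenance = list(adapter = config$name,
                                        dialect = dialect, command = cmd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
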