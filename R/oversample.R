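#' SMOTE-balance one patient's cell types
#'
#' Within a single patient, brings every retained cell type (at `level`)
#' up to the cell count of that patient's most abundant type by SMOTE
#' interpolation: each synthesized cell is
#' `x_new = x_i + lambda * (x_j - x_i)` with `x_i`, `x_j` two distinct
#' original cells of the same patient and type and `lambda ~ U[0,1]`.
#' Original cells are untouched; synthesized cells carry
#' `is_synthesized = TRUE`, the two parent ids, and the drawn `lambda`,
#' so any synthesized cell can be replayed exactly.
#'
#' Rare types (< 10 cells) are expected to have been removed upstream by
#' [filter_rare_celltypes()]; a type with fewer than two cells makes the
#' interpolation degenerate and is an error here.
#'
#' @param corpus a CP10K-normalized, rare-filtered `annotated_corpus`.
#' @param patient patient id to balance.
#' @param seed integer seed for partner and lambda draws.
#' @param level lineage level defining the types to balance.
#' @return list with `corpus` (the input corpus plus this patient's
#'   synthesized cells) and `report` (data.frame: patient, type,
#'   original_count, synthesized_count, target_count, seed).
#' @export
smote_patient <- function(corpus, patient, seed,
                          level = c("major", "minor", "subset")) {
  level <- match.arg(level)
  ct <- corpus$cell_table
  if (!patient %in% ct$patient) stop("unknown patient: ", patient)
  in_pat <- ct$patient == patient & !ct$is_synthesized
  lab <- labels_at_level(corpus, level)
  counts_by_type <- table(lab[in_pat])
  if (any(counts_by_type < 2))
    stop("patient ", patient, " has types with < 2 cells at level ", level,
         " (filter rare types first): ",
         paste(names(counts_by_type)[counts_by_type < 2], collapse = ", "))
  target <- max(counts_by_type)
  report <- data.frame(patient = patient,
                       type = names(counts_by_type),
                       original_count = as.integer(counts_by_type),
                       target_count = as.integer(target),
                       seed = as.integer(seed),
                       stringsAsFactors = FALSE)
  report$synthesized_count <- report$target_count - report$original_count

  new_cols <- list(); new_rows <- list()
  with_seed(seed, {
    for (ty in names(counts_by_type)) {
      need <- target - counts_by_type[[ty]]
      if (need == 0) next
      idx <- which(in_pat & lab == ty)
      pool <- corpus$counts[, idx, drop = FALSE]
      ids <- colnames(pool)
      i <- sample.int(length(idx), need, replace = TRUE)
      # partner: uniform over the other same-type cells of this patient
      j <- vapply(i, function(a) {
        b <- sample.int(length(idx) - 1L, 1L)
        if (b >= a) b + 1L else b
      }, integer(1))
      lam <- runif(need)
      syn <- pool[, i, drop = FALSE] %*% Matrix::Diagonal(x = 1 - lam) +
        pool[, j, drop = FALSE] %*% Matrix::Diagonal(x = lam)
      syn_ids <- sprintf("%s_%s_syn%05d", patient, gsub("[^A-Za-z0-9]", ".", ty),
                         seq_len(need))
      colnames(syn) <- syn_ids
      tmpl <- ct[idx[i], c("patient", "major", "minor", "subset",
                           intersect("subtype", names(ct))), drop = FALSE]
      rows <- data.frame(cell_id = syn_ids, tmpl,
                         is_synthesized = TRUE,
                         parent_i = ids[i], parent_j = ids[j], lambda = lam,
                         row.names = NULL, stringsAsFactors = FALSE)
      new_cols[[ty]] <- syn
      new_rows[[ty]] <- rows
    }
  })
  if (length(new_cols)) {
    ct_out <- ct
    for (nm in c("parent_i", "parent_j", "lambda")) {
      if (!nm %in% names(ct_out))
        ct_out[[nm]] <- if (nm == "lambda") NA_real_ else NA_character_
    }
    add <- do.call(rbind, new_rows)
    ct_out <- rbind(ct_out[, names(ct_out)],
                    add[, names(ct_out), drop = FALSE])
    rownames(ct_out) <- NULL
    out <- annotated_corpus(cbind(corpus$counts, do.call(cbind, new_cols)),
                            ct_out)
  } else {
    out <- corpus
  }
  list(corpus = out, report = report[, c("patient", "type", "original_count",
                                         "synthesized_count", "target_count",
                                         "seed")])
}

#' SMOTE-balance every patient in a cohort
#'
#' Runs [smote_patient()] independently for each patient — synthesized
#' cells are built only from that patient's own original cells, so a type
#' absent in a patient stays absent. Per-patient seeds are derived
#' deterministically from the cohort seed and the patient id.
#'
#' @param corpus a CP10K-normalized, rare-filtered `annotated_corpus`.
#' @param seed cohort-level integer seed.
#' @param level lineage level defining the types to balance.
#' @return list with `corpus` (all patients' originals + synthesized
#'   cells) and `report` (row-bound per-patient reports).
#' @export
oversample_cohort <- function(corpus, seed, level = c("major", "minor", "subset")) {
  level <- match.arg(level)
  reports <- list()
  out <- corpus
  for (p in unique(corpus$cell_table$patient)) {
    res <- smote_patient(out, p, seed = derive_seed(seed, p), level = level)
    out <- res$corpus
    reports[[p]] <- res$report
  }
  list(corpus = out, report = do.call(rbind, c(reports, make.row.names = FALSE)))
}

#' Replay a synthesized cell from its provenance
#'
#' Recomputes `x_i + lambda * (x_j - x_i)` from the stored parent ids and
#' lambda; used to verify that augmentation is exactly reproducible.
#'
#' @param corpus an augmented `annotated_corpus`.
#' @param cell_id id of a synthesized cell.
#' @return numeric vector of the replayed expression values.
#' @export
replay_synthesized <- function(corpus, cell_id) {
  ct <- corpus$cell_table
  r <- ct[ct$cell_id == cell_id, ]
  if (nrow(r) != 1 || !isTRUE(r$is_synthesized))
    stop(cell_id, " is not a synthesized cell")
  xi <- corpus$counts[, r$parent_i]
  xj <- corpus$counts[, r$parent_j]
  # same floating-point form the augmentation uses, so replay is bit-exact
  as.numeric((1 - r$lambda) * xi + r$lambda * xj)
}
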