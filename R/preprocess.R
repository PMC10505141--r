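#' Counts-per-10,000 normalization
#'
#' Scales each cell's expression so the column total is exactly 10,000,
#' with no log transform. Within-cell relative abundances are preserved
#' (ratios between any two genes are unchanged), and the operation is
#' idempotent.
#'
#' @param corpus an `annotated_corpus` of raw (or already normalized)
#'   non-negative values.
#' @return the corpus with normalized expression.
#' @export
cp10k_normalize <- function(corpus) {
  tot <- Matrix::colSums(corpus$counts)
  if (any(tot == 0))
    stop("cells with zero total counts: ",
         paste(head(colnames(corpus$counts)[tot == 0], 5), collapse = ", "))
  out <- corpus
  out$counts <- corpus$counts %*% Matrix::Diagonal(x = 10000 / tot)
  dimnames(out$counts) <- dimnames(corpus$counts)
  out
}

#' Drop rare cell types per patient
#'
#' Removes, for each patient separately, every cell whose type at the
#' chosen lineage level has fewer than `min_cells` cells in that patient.
#' Applied before SMOTE so interpolation always has a reasonable pool of
#' original cells; types with at least `min_cells` cells are retained.
#'
#' @param corpus an `annotated_corpus`.
#' @param level lineage level at which to count ("major", "minor",
#'   "subset").
#' @param min_cells minimum per-patient cell count for a type to be kept
#'   (default 10; a type with exactly `min_cells` is kept).
#' @return the filtered corpus, with attribute `removed`: a data.frame
#'   (patient, type, n_removed) logging what was dropped.
#' @export
filter_rare_celltypes <- function(corpus, level = c("major", "minor", "subset"),
                                  min_cells = 10L) {
  level <- match.arg(level)
  lab <- labels_at_level(corpus, level)
  pat <- corpus$cell_table$patient
  tab <- table(pat, lab)
  keep <- rep(TRUE, length(lab))
  removed <- list()
  for (p in rownames(tab)) {
    rare <- colnames(tab)[tab[p, ] > 0 & tab[p, ] < min_cells]
    for (ty in rare) {
      idx <- pat == p & lab == ty
      keep[idx] <- FALSE
      removed[[length(removed) + 1L]] <-
        data.frame(patient = p, type = ty, n_removed = sum(idx))
    }
  }
  out <- subset_cells(corpus, keep)
  attr(out, "removed") <- if (length(removed)) do.call(rbind, removed) else
    data.frame(patient = character(), type = character(), n_removed = integer())
  out
}

#' Train/test split plan over patients
#'
#' @param train_patients,test_patients disjoint, non-empty character
#'   vectors of patient ids.
#' @return a `split_plan`.
#' @export
split_plan <- function(train_patients, test_patients) {
  if (!length(train_patients) || !length(test_patients))
    stop("both sides of the split must be non-empty")
  if (length(intersect(train_patients, test_patients)))
    stop("train and test patient sets overlap: ",
         paste(intersect(train_patients, test_patients), collapse = ", "))
  structure(list(train = unique(train_patients), test = unique(test_patients)),
            class = "split_plan")
}

#' Split a corpus into train and test by patient
#'
#' Deconvolution methods must be blind to test donors, so whole patients
#' are assigned to one side. Unless `override = TRUE`, the split is
#' validated so that every major cell type and every molecular subtype
#' present in the corpus occurs on both sides.
#'
#' @param corpus an `annotated_corpus` (with a `subtype` column in its
#'   cell table for the subtype check; skipped if absent).
#' @param plan a [split_plan()].
#' @param override skip the representation check.
#' @return list with elements `train` and `test`, both
#'   `annotated_corpus`.
#' @export
split_by_patient <- function(corpus, plan, override = FALSE) {
  stopifnot(inherits(plan, "split_plan"))
  ct <- corpus$cell_table
  unknown <- setdiff(c(plan$train, plan$test), unique(ct$patient))
  if (length(unknown))
    stop("plan names patients absent from the corpus: ",
         paste(unknown, collapse = ", "))
  sides <- list(train = ct$patient %in% plan$train,
                test = ct$patient %in% plan$test)
  if (!override) {
    offenders <- character()
    for (what in c("major", "subtype")) {
      if (!what %in% names(ct)) next
      all_lv <- unique(ct[[what]])
      for (s in names(sides)) {
        missing <- setdiff(all_lv, unique(ct[[what]][sides[[s]]]))
        if (length(missing))
          offenders <- c(offenders, paste0(what, " '", missing,
                                           "' absent from ", s))
      }
    }
    if (length(offenders))
      stop("representation check failed:\n  ",
           paste(offenders, collapse = "\n  "))
  }
  list(train = subset_cells(corpus, sides$train),
       test = subset_cells(corpus, sides$test))
}

#' Restrict corpora to their common gene set
#'
#' For cross-corpus runs only the genes measured in every corpus are
#' meaningful; retained genes keep their expression values unchanged and
#' are re-ordered lexicographically so outputs are bit-stable.
#'
#' @param corpora list of at least two `annotated_corpus` objects.
#' @return list of corpora over the identical sorted intersection.
#' @export
intersect_genes <- function(corpora) {
  if (length(corpora) < 2) stop("need at least two corpora")
  common <- Reduce(intersect, lapply(corpora, function(x) rownames(x$counts)))
  if (!length(common)) stop("gene intersection is empty")
  common <- sort(common)
  lapply(corpora, function(x) {
    x$counts <- x$counts[common, , drop = FALSE]
    x
  })
}

#' Collapse or drop cell-type labels
#'
#' Relabels cells according to `mapping` at one lineage level — e.g.
#' grouping dendritic cells and tumour-associated macrophages into
#' "myeloid" for cross-dataset harmonization. Labels mapped to the
#' reserved token `"DROP"` are removed entirely (e.g. pericytes absent
#' from the reference annotation). Unmapped labels pass through. Child
#' levels of a collapsed label are set to the new label so hierarchy
#' nesting remains valid.
#'
#' @param corpus an `annotated_corpus`.
#' @param mapping named character vector, old label -> new label (or
#'   "DROP").
#' @param level lineage level whose labels the mapping keys refer to.
#' @return the relabeled corpus.
#' @export
collapse_labels <- function(corpus, mapping,
                            level = c("major", "minor", "subset")) {
  level <- match.arg(level)
  ct <- corpus$cell_table
  unknown <- setdiff(names(mapping), unique(ct[[level]]))
  if (length(unknown))
    stop("mapping keys not present at level ", level, ": ",
         paste(unknown, collapse = ", "))
  lab <- as.character(ct[[level]])
  hit <- lab %in% names(mapping)
  new_lab <- lab
  new_lab[hit] <- unname(mapping[lab[hit]])
  drop <- new_lab == "DROP"
  if (all(drop)) stop("mapping removes every cell")
  levels_below <- list(major = c("minor", "subset"), minor = "subset",
                       subset = character())[[level]]
  ct[[level]] <- new_lab
  for (lv in levels_below) ct[[lv]][hit] <- new_lab[hit]
  out <- corpus
  out$cell_table <- ct
  out <- subset_cells(out, !drop)
  validate_corpus(out)
  out
}
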