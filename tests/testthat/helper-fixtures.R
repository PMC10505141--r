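# Shared builders for small synthetic corpora used across the suite.

temp_dir <- function() {
  d <- tempfile("pm_")
  dir.create(d)
  d
}

# A compact 3-level hierarchy: `n_major` majors, two minors each, one
# subset per minor.
test_hierarchy <- function(n_major = 4) {
  majors <- c("cancer_epithelial", "t_cell", "myeloid", "b_cell",
              "endothelial", "caf")[seq_len(n_major)]
  do.call(rbind, lapply(majors, function(mj) {
    mins <- paste0(mj, c("_m1", "_m2"))
    data.frame(major = mj, minor = mins, subset = paste0(mins, "_s"))
  }))
}

# Uniform abundance table: every (patient, leaf) gets `n_per_leaf` cells
# unless overridden via `overrides` (data.frame patient/subset/n).
test_abundance <- function(patients, hierarchy, n_per_leaf = 30,
                           overrides = NULL) {
  ab <- expand.grid(patient = patients, subset = hierarchy$subset,
                    stringsAsFactors = FALSE)
  ab$n <- n_per_leaf
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      hit <- ab$patient == overrides$patient[i] &
        ab$subset == overrides$subset[i]
      ab$n[hit] <- overrides$n[i]
    }
  }
  ab
}

test_config <- function(n_patients = 3, n_major = 4, n_per_leaf = 30,
                        n_genes = 120, markers_per_type = 5,
                        marker_fold = 8, seed = 7, overrides = NULL, ...) {
  hier <- test_hierarchy(n_major)
  patients <- paste0("P", seq_len(n_patients))
  subtype <- setNames(rep(c("ER+", "HER2+", "TNBC"),
                          length.out = n_patients), patients)
  corpus_config(patients, subtype, hier,
                test_abundance(patients, hier, n_per_leaf, overrides),
                n_genes = n_genes, markers_per_type = markers_per_type,
                marker_fold = marker_fold, seed = seed, ...)
}

# A corpus with zero within-type variance: every cell of a leaf type is
# exactly the type's profile, so per-type means are exact and NNLS
# recovery should be perfect after CP10K.
mean_value_corpus <- function(types = c("A", "B", "C"), n_genes = 30,
                              cells_per_type = 40, patient = "P1",
                              seed = 5) {
  set.seed(seed)
  profiles <- vapply(types, function(t) rpois(n_genes, 20) + 1,
                     numeric(n_genes))
  genes <- sprintf("g%03d", seq_len(n_genes))
  rownames(profiles) <- genes
  counts <- profiles[, rep(seq_along(types), each = cells_per_type)]
  ids <- sprintf("%s_%s_c%03d", patient,
                 rep(types, each = cells_per_type),
                 seq_len(ncol(counts)))
  colnames(counts) <- ids
  ct <- data.frame(cell_id = ids, patient = patient, subtype = "ER+",
                   major = rep(types, each = cells_per_type),
                   minor = rep(types, each = cells_per_type),
                   subset = rep(types, each = cells_per_type),
                   is_synthesized = FALSE)
  annotated_corpus(counts, ct)
}

# Prepared small pipeline input: normalized, filtered, SMOTE-balanced.
balanced_test_corpus <- function(config = test_config(), seed = 11,
                                 level = "major") {
  corpus <- cp10k_normalize(generate_corpus(config))
  corpus <- filter_rare_celltypes(corpus, level = level)
  oversample_cohort(corpus, seed = seed, level = level)$corpus
}

# Writes a tiny external "deconvolution method" as an Rscript; it reads
# the materialized bulk matrix and emits per-mixture proportions
# proportional to fixed weights over `types` (optionally dropping one
# column or emitting rows that do not sum to 100).
write_fake_adapter <- function(path, types, drop_type = NULL,
                               row_total = 100) {
  drop_txt <- if (is.null(drop_type)) "character(0)" else
    sprintf('"%s"', drop_type)
  lines <- c(
    "#!/usr/bin/env Rscript",
    "a <- commandArgs(trailingOnly = TRUE)",
    "bulk <- as.matrix(read.delim(a[1], row.names = 1, check.names = FALSE))",
    sprintf("types <- c(%s)",
            paste(sprintf('"%s"', types), collapse = ", ")),
    sprintf("types <- setdiff(types, %s)", drop_txt),
    "w <- seq_along(types); w <- w / sum(w)",
    sprintf("p <- matrix(rep(w * %s, each = nrow(bulk)), nrow(bulk))",
            row_total),
    "dimnames(p) <- list(rownames(bulk), types)",
    "write.table(p, a[2], sep = '\\t', quote = FALSE, col.names = NA)")
  writeLines(lines, path)
  path
}
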