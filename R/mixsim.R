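#' Draw sparse cell-type fractions for one mixture
#'
#' Implements the free-range sampling scheme: a random number of cell
#' types `k` between `min_types` and the number of available types is
#' included (uniform over that range); one randomly chosen included type
#' — the free-range type — gets a fraction drawn `U(0,1)` scaled into the
#' unconstrained budget, and the remaining included types split the rest
#' proportionally to i.i.d. `U(0,1)` draws. With a fixed label (e.g. a
#' tumour-purity constraint) that label is always included, keeps its
#' fraction exactly, and the free-range draw is scaled into the residual
#' `1 - purity` budget. Fractions of unchosen types are 0 and the vector
#' sums to 1.
#'
#' When fewer than `min_types` types are available the range degenerates
#' to all available types (logged via attribute `degenerate`).
#'
#' @param available_types character vector of types available for the
#'   donor (post-filter).
#' @param fixed optional `list(label =, fraction =)` pinning one type's
#'   fraction; fraction must lie in (0, 1).
#' @param min_types lower bound of the included-type count (default 5).
#' @return named numeric vector of fractions over `available_types`
#'   (zeros for unchosen types), with attribute `free_type`.
#' @export
draw_sparse_fractions <- function(available_types, fixed = NULL,
                                  min_types = 5L) {
  n_avail <- length(available_types)
  if (n_avail == 0) stop("no available cell types")
  if (!is.null(fixed)) {
    if (!fixed$label %in% available_types)
      stop("fixed label '", fixed$label, "' not among available types")
    if (fixed$fraction <= 0 || fixed$fraction >= 1)
      stop("fixed fraction must lie strictly in (0, 1)")
  }
  lo <- min(min_types, n_avail)
  # need the fixed type plus at least one free type
  if (!is.null(fixed)) lo <- max(lo, 2L)
  k <- if (lo >= n_avail) n_avail else sample(lo:n_avail, 1L)
  if (is.null(fixed)) {
    chosen <- sample(available_types, k)
  } else {
    others <- setdiff(available_types, fixed$label)
    chosen <- c(fixed$label, sample(others, k - 1L))
  }
  non_fixed <- if (is.null(fixed)) chosen else setdiff(chosen, fixed$label)
  if (!length(non_fixed))
    stop("a fixed label requires at least one other available type")
  free_type <- if (length(non_fixed) == 1L) non_fixed else sample(non_fixed, 1L)
  budget <- if (is.null(fixed)) 1 else 1 - fixed$fraction
  f <- setNames(numeric(n_avail), available_types)
  if (!is.null(fixed)) f[fixed$label] <- fixed$fraction
  f_free <- runif(1) * budget
  f[free_type] <- f_free
  rest <- setdiff(non_fixed, free_type)
  if (length(rest)) {
    r <- runif(length(rest))
    f[rest] <- r / sum(r) * (budget - f_free)
  } else {
    # no other types to absorb the residual: free type takes the budget
    f[free_type] <- budget
  }
  attr(f, "free_type") <- free_type
  attr(f, "degenerate") <- lo >= n_avail
  f
}

#' Assemble one pseudobulk mixture from a mixture spec
#'
#' Samples, for each included type, the required number of cells without
#' replacement from the donor's pool (original plus synthesized cells)
#' and sums their CP10K expression vectors. No cell is used twice within
#' one mixture. The ground-truth row is the realized integer counts as
#' percentages of the 500-cell total.
#'
#' @param corpus an augmented, CP10K-normalized `annotated_corpus`.
#' @param spec a `mixture_spec` as produced inside the `simulate_*`
#'   drivers: list with `id`, `donor`, `counts` (named integer vector
#'   summing to the mixture size), `seed`, `level`.
#' @return list with `expression` (named numeric vector over genes),
#'   `truth` (named percent vector over the types in `spec$counts`) and
#'   `cells` (the selected cell ids, the provenance of the mixture).
#' @export
assemble_mixture <- function(corpus, spec) {
  lab <- labels_at_level(corpus, spec$level)
  pat <- corpus$cell_table$patient
  sel <- character(0)
  with_seed(spec$seed, {
    for (ty in names(spec$counts)) {
      n <- spec$counts[[ty]]
      if (n == 0) next
      pool <- corpus$cell_table$cell_id[pat == spec$donor & lab == ty]
      if (length(pool) < n)
        stop("donor ", spec$donor, " type '", ty, "': need ", n,
             " cells, have ", length(pool))
      sel <- c(sel, sample(pool, n))
    }
  })
  expr <- Matrix::rowSums(corpus$counts[, sel, drop = FALSE])
  truth <- spec$counts / sum(spec$counts) * 100
  list(expression = expr, truth = truth, cells = sel)
}

# Shared driver: build specs (and optionally expression) for a batch of
# mixtures. fixed_for(donor) returns NULL or list(label, fraction).
simulate_batch <- function(corpus, donors, n_per_donor, level, seed,
                           fixed_for = function(donor) NULL,
                           exclude_types = NULL, min_types = 5L,
                           total_cells = 500L, assemble = TRUE,
                           design = "sparse", tag = "") {
  lab <- labels_at_level(corpus, level)
  pat <- corpus$cell_table$patient
  missing_donors <- setdiff(donors, unique(pat))
  if (length(missing_donors))
    stop("donors absent from corpus: ", paste(missing_donors, collapse = ", "))
  avail_by_donor <- lapply(setNames(donors, donors), function(d) {
    av <- sort(unique(lab[pat == d]))
    setdiff(av, exclude_types)
  })
  all_types <- sort(unique(unlist(avail_by_donor)))
  specs <- vector("list", length(donors) * n_per_donor)
  truth <- matrix(0, nrow = length(specs), ncol = length(all_types),
                  dimnames = list(NULL, all_types))
  exprs <- if (assemble)
    matrix(0, nrow = length(specs), ncol = nrow(corpus$counts),
           dimnames = list(NULL, rownames(corpus$counts)))
  else NULL
  m <- 0L
  for (d in donors) {
    avail <- avail_by_donor[[d]]
    fixed <- fixed_for(d)
    for (r in seq_len(n_per_donor)) {
      m <- m + 1L
      id <- sprintf("mix_%s%s_%05d", tag, d, r)
      sub_seed <- derive_seed(seed, id)
      f <- with_seed(sub_seed,
                     draw_sparse_fractions(avail, fixed = fixed,
                                           min_types = min_types))
      counts <- fractions_to_counts(f, total = total_cells)
      spec <- list(id = id, donor = d, level = level,
                   fractions = f, counts = counts,
                   free_type = attr(f, "free_type"),
                   purity = if (is.null(fixed)) NA_real_ else fixed$fraction,
                   seed = derive_seed(sub_seed, "cells"))
      truth[m, names(counts)] <- counts / total_cells * 100
      if (assemble) {
        asm <- assemble_mixture(corpus, spec)
        exprs[m, ] <- asm$expression
        spec$cells <- asm$cells
      }
      specs[[m]] <- spec
    }
  }
  ids <- vapply(specs, `[[`, character(1), "id")
  rownames(truth) <- ids
  if (assemble) rownames(exprs) <- ids
  structure(list(expression = exprs, truth = truth, specs = specs,
                 metadata = list(design = design, level = level,
                                 donors = donors, n_per_donor = n_per_donor,
                                 total_cells = total_cells, seed = seed)),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat("pseudobulk_set:", nrow(x$truth), "mixtures x", ncol(x$truth),
      "cell types (design:", x$metadata$design, ")\n")
  if (is.null(x$expression)) cat("  specs-only (no expression assembled)\n")
  invisible(x)
}

#' Simulate sparse training mixtures
#'
#' Generates `per_donor` fully sparse 500-cell mixtures per training
#' donor via [draw_sparse_fractions()] with no fixed label — the design
#' used to train learning-based deconvolution methods.
#'
#' @param corpus augmented, CP10K-normalized `annotated_corpus`.
#' @param donors training patient ids.
#' @param per_donor mixtures per donor (default 5000, the full-scale
#'   design).
#' @param level lineage level of the mixture labels.
#' @param seed integer seed.
#' @param total_cells cells per mixture (default 500, the published
#'   design; reduce only for desk-scale demos).
#' @param assemble if `FALSE`, only specs and ground truth are produced
#'   (design bookkeeping without expression sums).
#' @return a `pseudobulk_set`.
#' @export
simulate_training_set <- function(corpus, donors, per_donor = 5000L,
                                  level = "major", seed = 1L,
                                  total_cells = 500L, assemble = TRUE) {
  simulate_batch(corpus, donors, per_donor, level, seed,
                 total_cells = total_cells,
                 assemble = assemble, design = "training_sparse", tag = "tr_")
}

#' Simulate the fixed-tumour-purity test series
#'
#' For each donor and each purity level in `purity_grid`, generates
#' `per_donor_per_level` mixtures whose cancer-epithelial fraction is
#' pinned exactly at the level while all other included types are
#' randomized. The default grid is the 19 values 5%, 10%, ..., 95%; on
#' that grid `purity * 500` is integral, so the recorded cancer truth
#' equals the grid value exactly.
#'
#' @param corpus augmented, CP10K-normalized `annotated_corpus`.
#' @param donors test patient ids (each must carry the cancer label).
#' @param cancer_label the cancer-epithelial label at `level`.
#' @param purity_grid numeric purity levels in (0, 1).
#' @param per_donor_per_level mixtures per (donor, level) cell
#'   (default 250).
#' @param level,seed,assemble as in [simulate_training_set()].
#' @return a `pseudobulk_set`; `truth` carries all donors and levels,
#'   and each spec records its purity.
#' @export
simulate_purity_series <- function(corpus, donors,
                                   cancer_label = "cancer_epithelial",
                                   purity_grid = seq(0.05, 0.95, by = 0.05),
                                   per_donor_per_level = 250L,
                                   level = "major", seed = 1L,
                                   total_cells = 500L, assemble = TRUE) {
  lab <- labels_at_level(corpus, level)
  pat <- corpus$cell_table$patient
  for (d in donors)
    if (!cancer_label %in% lab[pat == d])
      stop("donor ", d, " has no '", cancer_label, "' cells")
  parts <- lapply(purity_grid, function(p) {
    simulate_batch(corpus, donors, per_donor_per_level, level,
                   seed = derive_seed(seed, sprintf("purity_%g", p)),
                   fixed_for = function(d) list(label = cancer_label,
                                                fraction = p),
                   total_cells = total_cells,
                   assemble = assemble, design = "purity_series",
                   tag = sprintf("p%02d_", round(p * 100)))
  })
  out <- parts[[1]]
  all_types <- sort(unique(unlist(lapply(parts, function(x) colnames(x$truth)))))
  pad <- function(m) {
    full <- matrix(0, nrow(m), length(all_types),
                   dimnames = list(rownames(m), all_types))
    full[, colnames(m)] <- m
    full
  }
  out$truth <- do.call(rbind, lapply(parts, function(x) pad(x$truth)))
  out$expression <- if (assemble)
    do.call(rbind, lapply(parts, `[[`, "expression")) else NULL
  out$specs <- do.call(c, lapply(parts, `[[`, "specs"))
  out$metadata <- c(parts[[1]]$metadata[c("level", "donors", "total_cells")],
                    list(design = "purity_series", purity_grid = purity_grid,
                         per_donor_per_level = per_donor_per_level,
                         seed = seed))
  out
}

#' Simulate lineage-granular mixtures
#'
#' Mixtures over a mixed-granularity label set: each major type is either
#' kept at major level or replaced by its minor/subset children, per
#' `level_config`. Used for the normal-epithelial-lineage design (normal
#' epithelial split into its three minor subtypes, optionally excluded
#' entirely) and the immune-lineage designs (T/B/myeloid at minor or
#' subset granularity), optionally with tumour purity fixed (the
#' published design uses 50%).
#'
#' @param corpus augmented, CP10K-normalized `annotated_corpus`.
#' @param donors patient ids.
#' @param level_config named character vector mapping each major label to
#'   `"major"`, `"minor"` or `"subset"` — the granularity at which that
#'   major's cells are labelled. Majors not named stay at major level.
#' @param per_donor mixtures per donor (default 250, the test design).
#' @param fixed_purity optional cancer fraction fixed for every mixture.
#' @param cancer_label label carrying the purity constraint.
#' @param exclude_types labels removed from the pool before drawing.
#' @param seed,assemble as in [simulate_training_set()].
#' @return a `pseudobulk_set` whose truth columns are the expanded label
#'   union.
#' @export
simulate_lineage_set <- function(corpus, donors, level_config = character(),
                                 per_donor = 250L, fixed_purity = NULL,
                                 cancer_label = "cancer_epithelial",
                                 exclude_types = NULL, seed = 1L,
                                 total_cells = 500L, assemble = TRUE) {
  ct <- corpus$cell_table
  bad <- setdiff(names(level_config), unique(ct$major))
  if (length(bad))
    stop("level_config names unknown major types: ", paste(bad, collapse = ", "))
  mixed <- as.character(ct$major)
  for (mj in names(level_config)) {
    lv <- match.arg(level_config[[mj]], c("major", "minor", "subset"))
    if (lv != "major") {
      idx <- ct$major == mj
      mixed[idx] <- as.character(ct[[lv]][idx])
    }
  }
  # requested child labels must exist somewhere among the donors
  lab_donors <- unique(mixed[ct$patient %in% donors])
  work <- corpus
  work$cell_table$mixed <- mixed
  fixed_for <- if (is.null(fixed_purity)) function(d) NULL else {
    if (!cancer_label %in% lab_donors)
      stop("cancer label '", cancer_label, "' absent from donors")
    function(d) list(label = cancer_label, fraction = fixed_purity)
  }
  out <- simulate_batch(work, donors, per_donor, "mixed", seed,
                        fixed_for = fixed_for, exclude_types = exclude_types,
                        total_cells = total_cells,
                        assemble = assemble, design = "lineage", tag = "ln_")
  out$metadata$level_config <- level_config
  out$metadata$exclude_types <- exclude_types
  out$metadata$fixed_purity <- fixed_purity
  out
}

#' Write a pseudobulk set as plain-text files
#'
#' Writes `expression.tsv` (mixtures x genes; omitted for specs-only
#' sets), `truth.tsv` (mixtures x types, percent) and `specs.jsonl`
#' (one JSON record per mixture with fractions, counts, purity, seed and
#' selected-cell provenance).
#'
#' @param pbs a `pseudobulk_set`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pseudobulk <- function(pbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(pbs$expression))
    write.table(pbs$expression, file.path(dir, "expression.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
  write.table(pbs$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  con <- file(file.path(dir, "specs.jsonl"), "w")
  on.exit(close(con))
  for (s in pbs$specs) {
    s$fractions <- as.list(s$fractions)
    s$counts <- as.list(s$counts)
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(dir)
}
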