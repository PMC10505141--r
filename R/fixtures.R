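#' Configuration for a synthetic annotated corpus
#'
#' Describes the structure of a synthetic breast-tumour scRNA-seq corpus:
#' patients with molecular subtypes, a three-level cell-type hierarchy,
#' per-(patient, leaf-type) cell abundances (zero means the type is
#' absent in that patient), and a negative-binomial expression model with
#' disjoint marker-gene blocks per leaf type and a per-patient
#' multiplicative effect.
#'
#' @param patients character vector of patient ids.
#' @param patient_subtype named character vector mapping each patient to
#'   a molecular subtype label (`ER+`, `HER2+`, `TNBC`).
#' @param hierarchy data.frame with columns `major`, `minor`, `subset`;
#'   one row per leaf (subset-level) type. Minor labels must nest under a
#'   single major, subsets under a single minor.
#' @param abundance data.frame with columns `patient`, `subset`, `n`
#'   giving the cell count of each leaf type in each patient; pairs not
#'   listed default to 0. Every leaf must have > 0 cells in at least one
#'   patient.
#' @param n_genes number of genes.
#' @param markers_per_type number of marker genes reserved for each leaf
#'   type; blocks are disjoint, so `n_genes` must be at least
#'   `markers_per_type * nrow(hierarchy)`.
#' @param baseline_mean negative-binomial mean of a non-marker gene.
#' @param marker_fold multiplicative up-weighting of a cell's own marker
#'   genes.
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param patient_effect_sd sd of the per-(patient, gene) log-normal
#'   factor modelling donor heterogeneity; 0 disables it.
#' @param seed integer seed making generation fully reproducible.
#' @return a `corpus_config` list.
#' @export
corpus_config <- function(patients, patient_subtype, hierarchy, abundance,
                          n_genes = 2000L, markers_per_type = 10L,
                          baseline_mean = 0.2, marker_fold = 8,
                          dispersion = 0.5, patient_effect_sd = 0.15,
                          seed = 1L) {
  stopifnot(length(patients) >= 1, n_genes >= 1, markers_per_type >= 1)
  if (baseline_mean <= 0 || marker_fold <= 0 || dispersion <= 0)
    stop("baseline_mean, marker_fold and dispersion must be positive")
  if (patient_effect_sd < 0) stop("patient_effect_sd must be non-negative")
  if (!all(names(patient_subtype) %in% patients) ||
      !all(patients %in% names(patient_subtype)))
    stop("patient_subtype must cover exactly the listed patients")
  if (anyDuplicated(hierarchy$subset)) stop("leaf (subset) labels must be unique")
  if (n_genes < markers_per_type * nrow(hierarchy))
    stop("need n_genes >= markers_per_type * number of leaf types for disjoint markers")
  if (!all(abundance$subset %in% hierarchy$subset))
    stop("abundance refers to unknown leaf types")
  if (!all(abundance$patient %in% patients))
    stop("abundance refers to unknown patients")
  if (any(abundance$n < 0)) stop("abundances must be non-negative")
  present <- tapply(abundance$n, abundance$subset, sum)
  absent <- setdiff(hierarchy$subset, names(present)[present > 0])
  if (length(absent))
    stop("leaf types with zero cells in every patient: ",
         paste(absent, collapse = ", "))
  structure(list(patients = patients, patient_subtype = patient_subtype,
                 hierarchy = hierarchy, abundance = abundance,
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 baseline_mean = baseline_mean, marker_fold = marker_fold,
                 dispersion = dispersion,
                 patient_effect_sd = patient_effect_sd,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Desk-scale demo configuration
#'
#' Mirrors the shape of the published breast-cancer corpora at a size a
#' laptop handles: 6 patients (2 per molecular subtype), 9 major cell
#' types with 2-3 minor children each (immune majors further split into
#' subsets), 2000 genes, and skewed per-patient abundances between 0 and
#' 1500 cells with some (patient, type) pairs absent — exercising the
#' rare-type filtering and absent-type code paths.
#'
#' @param n_genes,seed overrides for the corresponding
#'   [corpus_config()] fields.
#' @param max_abundance upper cap on any single (patient, leaf) cell
#'   count.
#' @return a `corpus_config`.
#' @export
demo_config <- function(n_genes = 2000L, seed = 42L, max_abundance = 1500L) {
  majors <- list(
    cancer_epithelial = c("cancer_basal", "cancer_luminal", "cancer_cycling"),
    normal_epithelial = c("luminal_progenitor", "mature_luminal", "myoepithelial"),
    t_cell      = c("cd4_t", "cd8_t", "cycling_t"),
    b_cell      = c("naive_b", "memory_b"),
    myeloid     = c("macrophage", "dc", "monocyte"),
    plasmablast = c("plasmablast_igg", "plasmablast_iga"),
    endothelial = c("endo_vascular", "endo_lymphatic"),
    caf         = c("caf_myl", "caf_infl"),
    pvl         = c("pvl_immature", "pvl_mature")
  )
  hier <- do.call(rbind, lapply(names(majors), function(mj) {
    mins <- majors[[mj]]
    data.frame(major = mj, minor = mins, subset = paste0(mins, "_s"))
  }))
  patients <- paste0("P", 1:6)
  subtype <- setNames(rep(c("ER+", "HER2+", "TNBC"), each = 2), patients)
  # skewed abundances, deterministic in `seed`; ~15% absent pairs
  ab <- with_seed(derive_seed(seed, "abundance"), {
    grid <- expand.grid(patient = patients, subset = hier$subset,
                        stringsAsFactors = FALSE)
    n <- pmin(round(rlnorm(nrow(grid), meanlog = log(80), sdlog = 1.1)),
              max_abundance)
    drop <- runif(nrow(grid)) < 0.15
    # keep every type present in >= 1 patient: never drop the first patient's entry
    drop[grid$patient == patients[1]] <- FALSE
    n[drop] <- 0L
    grid$n <- as.integer(n)
    grid
  })
  corpus_config(patients, subtype, hier, ab, n_genes = n_genes, seed = seed)
}

#' Generate a synthetic annotated corpus
#'
#' Draws raw counts for every cell from a negative-binomial model: gene
#' means are `baseline_mean`, multiplied by `marker_fold` on the cell's
#' own leaf-type marker block and by a per-(patient, gene) log-normal
#' factor. Cell counts per (patient, leaf type) follow `config$abundance`
#' exactly, all cells are flagged as original (not synthesized), and the
#' result is bit-reproducible from `config$seed`.
#'
#' @param config a [corpus_config()].
#' @return an `annotated_corpus` of raw integer counts, with attribute
#'   `markers` (named list: leaf type -> its marker gene ids).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  ab <- config$abundance[config$abundance$n > 0, , drop = FALSE]
  if (sum(ab$n) == 0) stop("configuration yields zero total cells")
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  leaves <- config$hierarchy$subset
  markers <- setNames(lapply(seq_along(leaves), function(i) {
    genes[((i - 1) * config$markers_per_type + 1):(i * config$markers_per_type)]
  }), leaves)

  with_seed(config$seed, {
    pat_fx <- lapply(setNames(config$patients, config$patients), function(p) {
      if (config$patient_effect_sd > 0)
        rlnorm(config$n_genes, 0, config$patient_effect_sd)
      else rep(1, config$n_genes)
    })
    blocks <- list(); tabs <- list(); cell_no <- 0L
    for (p in config$patients) {
      for (leaf in leaves) {
        n <- ab$n[ab$patient == p & ab$subset == leaf]
        if (length(n) == 0 || n == 0) next
        mu <- config$baseline_mean * pat_fx[[p]]
        mu[genes %in% markers[[leaf]]] <- mu[genes %in% markers[[leaf]]] *
          config$marker_fold
        m <- matrix(rnbinom(config$n_genes * n, mu = rep(mu, n),
                            size = 1 / config$dispersion),
                    nrow = config$n_genes, ncol = n)
        ids <- sprintf("%s_%s_c%06d", p, leaf, cell_no + seq_len(n))
        cell_no <- cell_no + n
        colnames(m) <- ids
        rownames(m) <- genes
        hrow <- config$hierarchy[config$hierarchy$subset == leaf, ]
        blocks[[length(blocks) + 1L]] <- as(m, "CsparseMatrix")
        tabs[[length(tabs) + 1L]] <- data.frame(
          cell_id = ids, patient = p,
          subtype = unname(config$patient_subtype[p]),
          major = hrow$major, minor = hrow$minor, subset = hrow$subset,
          is_synthesized = FALSE, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, blocks)
    corpus <- annotated_corpus(counts, do.call(rbind, tabs))
    attr(corpus, "markers") <- markers
    corpus
  })
}
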