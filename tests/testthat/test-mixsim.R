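test_that("sparse fraction draws sum to 1 and honour a fixed purity", {
  types <- paste0("t", 1:9)
  set.seed(1)
  for (i in 1:200) {
    f <- draw_sparse_fractions(types)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_true(all(f >= 0))
    expect_gte(sum(f > 0), 5)  # at least min_types included
  }
  for (p in c(0.05, 0.5, 0.95)) {
    f <- draw_sparse_fractions(types,
                               fixed = list(label = "t1", fraction = p))
    expect_equal(unname(f["t1"]), p)
    expect_equal(sum(f[-1]), 1 - p, tolerance = 1e-9)
  }
  expect_error(draw_sparse_fractions(character(0)), "no available")
  expect_error(draw_sparse_fractions(types,
                                     fixed = list(label = "t1", fraction = 1)),
               "strictly")
})

test_that("free-range draws span a wider range than plain normalization", {
  types <- paste0("t", 1:9)
  set.seed(42)
  n <- 2000
  free <- replicate(n, {
    f <- draw_sparse_fractions(types)
    f[attr(f, "free_type")]
  })
  # baseline: normalize i.i.d. uniforms over k = 9 types (no free range)
  base <- replicate(n, {
    r <- runif(9)
    (r / sum(r))[1]
  })
  expect_gt(stats::sd(free), 2 * stats::sd(base))
  expect_gt(max(free), 0.9)     # free-range fractions reach near 1
  expect_lt(max(base), 0.75)    # plain normalization clusters near 1/k
  expect_gt(mean(free > 0.5), 0.2)
})

test_that("largest-remainder rounding reproduces hand-computed counts", {
  expect_equal(fractions_to_counts(c(a = 0.5, b = 0.3, c = 0.2)),
               c(a = 250L, b = 150L, c = 100L))
  # floors (166,166,167), remainders (.5,.5,0), tie -> earliest position
  expect_equal(fractions_to_counts(c(a = 0.333, b = 0.333, c = 0.334)),
               c(a = 167L, b = 166L, c = 167L))
  # a negligible fraction rounds to an absent type
  f <- c(a = 0.0001, b = 0.9999)
  expect_equal(unname(fractions_to_counts(f)), c(0L, 500L))
  expect_error(fractions_to_counts(c(a = -0.1, b = 1.1)), "non-negative")
  set.seed(3)
  for (i in 1:100) {
    r <- runif(7); r <- r / sum(r)
    expect_equal(sum(fractions_to_counts(r)), 500L)
  }
})

test_that("assembled mixtures conserve CP10K mass and cell provenance", {
  corpus <- balanced_test_corpus(test_config(n_patients = 1,
                                             n_per_leaf = 40, n_genes = 60))
  spec <- list(id = "m1", donor = "P1", level = "major",
               counts = c(cancer_epithelial = 30, t_cell = 50, myeloid = 20),
               seed = 17)
  asm <- assemble_mixture(corpus, spec)
  expect_equal(sum(asm$expression), 100 * 10000, tolerance = 1e-3)
  expect_equal(unname(asm$truth), c(30, 50, 20))
  expect_equal(length(unique(asm$cells)), 100)  # no cell reused
  # linearity oracle: recompute from stored provenance
  expect_equal(asm$expression,
               Matrix::rowSums(corpus$counts[, asm$cells]), tolerance = 1e-9)
  # same counts, different seed -> different cells
  asm2 <- assemble_mixture(corpus, modifyList(spec, list(seed = 18)))
  expect_equal(asm2$truth, asm$truth)
  expect_false(setequal(asm$cells, asm2$cells) &&
                 identical(sort(asm$cells), sort(asm2$cells)))
  # pool shortfall names donor, type, need, have
  big <- modifyList(spec, list(counts = c(t_cell = 5000)))
  expect_error(assemble_mixture(corpus, big), "t_cell.*need 5000")
})

test_that("single-type mixture is the plain sum of its cells", {
  corpus <- balanced_test_corpus(test_config(n_patients = 1,
                                             n_per_leaf = 30, n_genes = 40))
  spec <- list(id = "m1", donor = "P1", level = "major",
               counts = c(t_cell = 50), seed = 2)
  asm <- assemble_mixture(corpus, spec)
  expect_equal(unname(asm$truth), 100)
  expect_equal(asm$expression,
               Matrix::rowSums(corpus$counts[, asm$cells]))
})

test_that("training-set bookkeeping counts donors times per-donor", {
  corpus <- balanced_test_corpus(test_config(n_patients = 2,
                                             n_per_leaf = 20, n_genes = 50))
  pbs <- simulate_training_set(corpus, c("P1", "P2"), per_donor = 10,
                               seed = 1, total_cells = 30)
  expect_equal(nrow(pbs$truth), 20)
  expect_true(all(abs(rowSums(pbs$truth) - 100) < 1e-6))
  lab <- labels_at_level(corpus, "major")
  for (s in pbs$specs) {
    avail <- unique(lab[corpus$cell_table$patient == s$donor])
    expect_true(all(names(s$counts)[s$counts > 0] %in% avail))
    expect_equal(sum(s$counts), 30)
  }
  # determinism of the whole set
  pbs2 <- simulate_training_set(corpus, c("P1", "P2"), per_donor = 10,
                                seed = 1, total_cells = 30)
  expect_identical(pbs$truth, pbs2$truth)
  expect_identical(pbs$expression, pbs2$expression)
})

test_that("purity series pins the cancer fraction exactly on the grid", {
  corpus <- balanced_test_corpus(test_config(n_patients = 2,
                                             n_per_leaf = 25, n_genes = 50))
  pbs <- simulate_purity_series(corpus, c("P1", "P2"),
                                purity_grid = c(0.2, 0.4),
                                per_donor_per_level = 4, seed = 6,
                                assemble = FALSE)
  expect_equal(nrow(pbs$truth), 2 * 2 * 4)
  expect_true(all(abs(rowSums(pbs$truth) - 100) < 1e-6))
  purities <- vapply(pbs$specs, `[[`, numeric(1), "purity")
  cancer <- pbs$truth[, "cancer_epithelial"]
  expect_equal(unname(cancer), purities * 100)
  # at level 0.40 the cancer count is exactly 0.4 * 500 = 200
  counts40 <- vapply(pbs$specs[purities == 0.4],
                     function(s) s$counts[["cancer_epithelial"]], numeric(1))
  expect_true(all(counts40 == 200))
  # default grid is the 19 values 5..95%
  expect_equal(eval(formals(simulate_purity_series)$purity_grid),
               seq(0.05, 0.95, by = 0.05))
  expect_error(
    simulate_purity_series(corpus, "P1", cancer_label = "nosuch",
                           per_donor_per_level = 1, assemble = FALSE),
    "no 'nosuch' cells")
})

test_that("lineage sets expand majors to children and honour exclusions", {
  cfg <- test_config(n_patients = 2, n_major = 4, n_per_leaf = 25,
                     n_genes = 60)
  corpus <- balanced_test_corpus(cfg, level = "minor")
  # expand t_cell and myeloid to minors, keep the rest at major level
  pbs <- simulate_lineage_set(corpus, c("P1", "P2"),
                              level_config = c(t_cell = "minor",
                                               myeloid = "minor"),
                              per_donor = 5, seed = 2, assemble = FALSE)
  expect_equal(nrow(pbs$truth), 10)
  want <- c("cancer_epithelial", "b_cell",
            paste0("t_cell_m", 1:2), paste0("myeloid_m", 1:2))
  expect_setequal(colnames(pbs$truth), want)
  # exclusion removes mass entirely
  pbs2 <- simulate_lineage_set(corpus, c("P1", "P2"),
                               level_config = c(t_cell = "minor"),
                               exclude_types = paste0("t_cell_m", 1:2),
                               per_donor = 5, seed = 2, assemble = FALSE)
  expect_false(any(paste0("t_cell_m", 1:2) %in% colnames(pbs2$truth)))
  # fixed 50% purity flows through
  pbs3 <- simulate_lineage_set(corpus, c("P1", "P2"),
                               level_config = c(t_cell = "minor"),
                               fixed_purity = 0.5, per_donor = 5,
                               seed = 2, assemble = FALSE)
  expect_true(all(pbs3$truth[, "cancer_epithelial"] == 50))
  expect_error(simulate_lineage_set(corpus, "P1",
                                    level_config = c(nosuch = "minor"),
                                    assemble = FALSE),
               "unknown major")
})

test_that("pseudobulk sets round-trip through their plain-text layout", {
  corpus <- balanced_test_corpus(test_config(n_patients = 1,
                                             n_per_leaf = 20, n_genes = 60))
  pbs <- simulate_training_set(corpus, "P1", per_donor = 3, seed = 8,
                               total_cells = 40)
  dir <- temp_dir()
  write_pseudobulk(pbs, dir)
  expect_true(all(file.exists(file.path(
    dir, c("expression.tsv", "truth.tsv", "specs.jsonl")))))
  truth <- as.matrix(read.delim(file.path(dir, "truth.tsv"), row.names = 1,
                                check.names = FALSE))
  expect_equal(truth, pbs$truth)
  specs <- lapply(readLines(file.path(dir, "specs.jsonl")),
                  jsonlite::fromJSON)
  expect_equal(length(specs), 3)
  expect_equal(specs[[1]]$id, pbs$specs[[1]]$id)
  expect_equal(sort(unlist(specs[[1]]$cells)), sort(pbs$specs[[1]]$cells))
})
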