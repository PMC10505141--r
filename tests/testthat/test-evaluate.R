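test_that("Bray-Curtis matches hand-computed values and its invariants", {
  expect_equal(bray_curtis(c(30, 70), c(30, 70)), 0)
  # prediction mass entirely on types truth lacks -> 1
  expect_equal(bray_curtis(c(100, 0), c(0, 100)), 1)
  # min-sum 50; 1 - 2*50/200 = 0.5
  expect_equal(bray_curtis(c(50, 50, 0), c(25, 25, 50)), 0.5)
  # symmetry and fixed-total count equivalence (percent vs 500-cell counts)
  set.seed(8)
  for (i in 1:50) {
    a <- runif(6); a <- a / sum(a) * 100
    b <- runif(6); b <- b / sum(b) * 100
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
    expect_equal(bray_curtis(a, b), bray_curtis(a * 5, b * 5))
    expect_gte(bray_curtis(a, b), 0)
    expect_lte(bray_curtis(a, b), 1)
  }
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(21)
  for (i in 1:20) {
    a <- runif(8) * 100
    b <- runif(8) * 100
    expect_equal(bray_curtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("CLR transform matches hand evaluation and sums to zero", {
  expect_equal(clr(c(50, 50)), c(0, 0))
  expect_equal(clr(c(80, 20)), c(log(2), -log(2)), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:50) {
    x <- runif(7) * 100
    x[sample(7, 2)] <- 0            # zeros handled by pseudocount policy
    expect_lt(abs(sum(clr(x))), 1e-9)
  }
  expect_error(clr(c(0, 0)), "all-zero")
  expect_error(clr(c(-1, 2)), "negative")
})

test_that("Aitchison distance matches hand values and metric properties", {
  expect_equal(aitchison_distance(c(40, 60), c(40, 60)), 0)
  expect_equal(aitchison_distance(c(50, 50), c(80, 20)),
               sqrt(2 * log(2)^2), tolerance = 1e-9)
  # perturbation invariance: element-wise scaling then re-closure
  set.seed(12)
  for (i in 1:30) {
    a <- runif(5) + 0.05; a <- a / sum(a) * 100
    b <- runif(5) + 0.05; b <- b / sum(b) * 100
    p <- runif(5, 0.5, 2)
    ap <- a * p / sum(a * p) * 100
    bp <- b * p / sum(b * p) * 100
    expect_equal(aitchison_distance(a, b), aitchison_distance(ap, bp),
                 tolerance = 1e-6)
    # symmetry and triangle inequality on random triples
    c0 <- runif(5) + 0.05; c0 <- c0 / sum(c0) * 100
    expect_equal(aitchison_distance(a, b), aitchison_distance(b, a))
    expect_lte(aitchison_distance(a, b),
               aitchison_distance(a, c0) + aitchison_distance(c0, b) + 1e-9)
  }
})

test_that("error tables carry raw errors and RPE per the definitions", {
  truth <- rbind(m1 = c(A = 2, B = 30, C = 68),
                 m2 = c(A = 0, B = 50, C = 50))
  pred <- rbind(m1 = c(A = 7, B = 35, C = 58),
                m2 = c(A = 5, B = 45, C = 50))
  et <- error_table(pred, truth)
  expect_equal(nrow(et), 6)
  # RPE on a 5-point miss of a 2% truth is 2.5; of a 30% truth ~ 0.1667
  expect_equal(et$rpe[et$mixture == "m1" & et$type == "A"], 2.5)
  expect_equal(et$rpe[et$mixture == "m1" & et$type == "B"], 5 / 30)
  expect_true(is.na(et$rpe[et$mixture == "m2" & et$type == "A"]))
  expect_equal(et$raw_error[et$mixture == "m1" & et$type == "C"], -10)
  # rpe summaries count undefined entries separately
  rt <- rpe_table(et)
  expect_equal(rt$n_undefined[rt$type == "A"], 1)
  expect_equal(rt$median_rpe[rt$type == "A"], 2.5)
  expect_equal(rt$median_rpe[rt$type == "C"],
               median(c(10 / 68, 0)))
})

test_that("per-type accuracy matches closed-form cases", {
  set.seed(9)
  truth <- matrix(runif(40, 10, 90), 20, 2,
                  dimnames = list(paste0("m", 1:20), c("A", "B")))
  truth <- truth / rowSums(truth) * 100
  # perfect prediction: rmse 0, r 1
  et <- error_table(truth, truth)
  acc <- per_type_accuracy(et)
  expect_equal(acc$summary$median_rmse, c(0, 0))
  expect_equal(acc$summary$median_pearson_r, c(1, 1))
  # constant +5 offset: rmse 5, r 1
  pred <- truth + 5
  acc5 <- per_type_accuracy(error_table(pred, truth))
  expect_equal(acc5$by_group$rmse, c(5, 5))
  expect_equal(acc5$by_group$pearson_r, c(1, 1), tolerance = 1e-12)
  # truth identically zero: rmse = sqrt(mean(pred^2)), r undefined
  t0 <- cbind(truth, Z = 0)
  p0 <- cbind(truth - 2, Z = 6)
  acc0 <- per_type_accuracy(error_table(p0, t0))
  expect_equal(acc0$by_group$rmse[acc0$by_group$type == "Z"], 6)
  expect_true(is.na(acc0$summary$median_pearson_r[acc0$summary$type == "Z"]))
  expect_equal(acc0$summary$n_undefined_r[acc0$summary$type == "Z"], 1)
  # grouped medians: rmse computed within group, median across groups
  grp <- data.frame(donor = rep(c("d1", "d2"), each = 10))
  pred_g <- truth
  pred_g[1:10, "A"] <- truth[1:10, "A"] + 2   # d1 off by 2 on A
  pred_g[11:20, "A"] <- truth[11:20, "A"] + 8 # d2 off by 8 on A
  accg <- per_type_accuracy(error_table(pred_g, truth, groups = grp),
                            group_by = "donor")
  expect_equal(sort(accg$by_group$rmse[accg$by_group$type == "A"]), c(2, 8))
  expect_equal(accg$summary$median_rmse[accg$summary$type == "A"],
               median(c(2, 8)))
})

test_that("confusion analysis reproduces the hand-worked example", {
  truth <- rbind(m1 = c(X = 0, Y = 0.5, Z = 99.5),
                 m2 = c(X = 0, Y = 5, Z = 95))
  pred <- rbind(m1 = c(X = 0.5, Y = 0.05, Z = 99.45),
                m2 = c(X = 0.05, Y = 5, Z = 94.95))
  # components: truths (0, 0.5, 99.5, 0, 5, 95), preds (.5, .05, 99.45, .05, 5, 94.95)
  cs <- confusion_analysis(error_table(pred, truth))
  ov <- cs$overall
  expect_equal(ov$FP, 1)   # X in m1, predicted 0.5 -> bin [0.1, 1)
  expect_equal(ov$TN, 1)   # X in m2
  expect_equal(ov$FN, 1)   # Y in m1, truth 0.5 -> bin [0.1, 1)
  expect_equal(ov$TP, 3)
  expect_equal(ov$fp_rate, 1 / 2)
  expect_equal(ov$fn_rate, 1 / 4)
  expect_equal(ov$fp_bin_0.1_1, 1)
  expect_equal(ov$fn_bin_0.1_1, 1)
  expect_equal(ov$TP + ov$TN + ov$FP + ov$FN, 6)
  # histogram totals equal FP (resp. FN)
  expect_equal(ov$fp_bin_0.1_1 + ov$fp_bin_1_10 + ov$fp_bin_gt10, ov$FP)
  expect_equal(ov$fn_bin_0.1_1 + ov$fn_bin_1_10 + ov$fn_bin_gt10, ov$FN)
  # perfect predictions produce no FP/FN
  cs0 <- confusion_analysis(error_table(truth, truth))
  expect_equal(cs0$overall$FP + cs0$overall$FN, 0)
  # excluding the fixed-purity label removes its components
  cs_ex <- confusion_analysis(error_table(pred, truth), exclude_types = "Z")
  expect_equal(cs_ex$overall$n, 4)
  expect_false("Z" %in% cs_ex$by_type$type)
})

test_that("severity bins are lower-inclusive half-open intervals", {
  truth <- rbind(m = c(A = 0, B = 0, C = 0, D = 100))
  pred <- rbind(m = c(A = 0.1, B = 1, C = 10, D = 88.9))
  cs <- confusion_analysis(error_table(pred, truth))
  ov <- cs$overall
  expect_equal(ov$FP, 3)
  expect_equal(ov$fp_bin_0.1_1, 1)  # 0.1 falls in [0.1, 1)
  expect_equal(ov$fp_bin_1_10, 1)   # 1 falls in [1, 10)
  expect_equal(ov$fp_bin_gt10, 1)   # 10 falls in [10, Inf)
})

test_that("evaluation reports rank methods and emit all artifacts", {
  set.seed(30)
  truth <- matrix(runif(60, 1, 60), 15, 4,
                  dimnames = list(paste0("m", 1:15), c("A", "B", "T", "Cn")))
  truth <- truth / rowSums(truth) * 100
  good <- as_prediction_table(truth + matrix(runif(60, 0, 2), 15, 4),
                              method = "good")
  bad <- as_prediction_table(truth + matrix(runif(60, 0, 30), 15, 4),
                             method = "bad")
  out <- temp_dir()
  rep <- evaluate_predictions(list(good = good, bad = bad), truth,
                              groups = data.frame(
                                donor = rep(c("d1", "d2", "d3"), each = 5)),
                              group_by = "donor",
                              immune_types = c("T", "B"),
                              exclude_types = "Cn", out_dir = out)
  expect_equal(rep$ranking$method, c("good", "bad"))  # smaller BC first
  expect_equal(rep$ranking$rank, 1:2)
  expect_true(all(c("mixture_metrics.tsv", "per_type_accuracy.tsv",
                    "rpe.tsv", "ranking.tsv", "confusion.json") %in%
                    list.files(out)))
  expect_true(all(is.finite(rep$mixture_metrics$aitchison_immune)))
  expect_false("Cn" %in% rep$confusion$good$by_type$type)
  # a mixture with zero immune truth mass is NA in the immune variant
  truth0 <- truth
  truth0[1, ] <- c(50, 0, 0, 50)[c(1, 2, 3, 4)]
  truth0[1, c("T", "B")] <- 0
  truth0[1, ] <- truth0[1, ] / sum(truth0[1, ]) * 100
  rep0 <- evaluate_predictions(list(good = good), truth0,
                               immune_types = c("T", "B"))
  expect_true(is.na(rep0$mixture_metrics$aitchison_immune[1]))
  # mixture id mismatch is an error
  pred_miss <- good[-1, ]
  expect_error(evaluate_predictions(list(as_prediction_table(
    pred_miss, method = "x")), truth), "missing mixtures")
})
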