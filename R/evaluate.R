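#' Bray-Curtis dissimilarity between predicted and true compositions
#'
#' `1 - 2 * sum_i min(pred_i, truth_i) / (sum(pred) + sum(truth))`: one
#' minus twice the shared mass over the total mass. Defined on counts,
#' but because every mixture holds exactly 500 cells, percentages and
#' counts give the same value. Lies in [0, 1], is symmetric, and is 0
#' iff the compositions are equal.
#'
#' @param pred,truth non-negative numeric vectors of equal length (same
#'   type order), on the percent (or count) scale.
#' @return dissimilarity in [0, 1].
#' @export
bray_curtis <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length")
  if (any(pred < 0) || any(truth < 0)) stop("negative entries")
  tot <- sum(pred) + sum(truth)
  if (tot == 0) stop("both compositions are all-zero")
  1 - 2 * sum(pmin(pred, truth)) / tot
}

#' Centred log-ratio transform of a composition
#'
#' Maps a composition to zero-sum real space: `log(x_i / g(x))` with
#' `g` the geometric mean. Compositional zeros (legitimate in both
#' truths and predictions) are handled by the zero policy: closure to
#' the unit simplex, additive pseudocount `delta` on zero parts, and
#' re-closure.
#'
#' @param x non-negative vector with positive sum.
#' @param delta pseudocount applied on the [0, 1] simplex scale
#'   (default 1e-6).
#' @return numeric vector summing to 0 (within rounding).
#' @export
clr <- function(x, delta = 1e-6) {
  if (any(x < 0)) stop("negative entries")
  if (sum(x) <= 0) stop("all-zero composition")
  p <- x / sum(x)
  if (any(p == 0)) {
    p[p == 0] <- delta
    p <- p / sum(p)
  }
  lg <- log(p)
  lg - mean(lg)
}

#' Aitchison distance between predicted and true compositions
#'
#' Euclidean distance between the CLR transforms — the natural metric of
#' compositional data, used to compare performance across lineage
#' granularities.
#'
#' @inheritParams bray_curtis
#' @param delta pseudocount forwarded to [clr()].
#' @return non-negative real.
#' @export
aitchison_distance <- function(pred, truth, delta = 1e-6) {
  if (length(pred) != length(truth))
    stop("pred and truth differ in length")
  sqrt(sum((clr(pred, delta) - clr(truth, delta))^2))
}

#' Long-format error table from prediction and truth matrices
#'
#' One record per (mixture, cell type): predicted and true percentages,
#' the signed raw error `pred - truth` (never averaged — only
#' distributions are meaningful, since signed errors cancel), and the
#' Relative Proportion Error `|pred - truth| / truth`, defined only
#' where truth > 0.
#'
#' @param pred a `prediction_table` (or plain matrix) mixtures x types.
#' @param truth truth matrix, same mixtures and types (percent scale).
#' @param groups optional data.frame of per-mixture grouping keys
#'   (donor, purity level, subtype, ...), rownames or order matching the
#'   mixtures.
#' @return data.frame with columns mixture, type, pred, truth,
#'   raw_error, rpe, plus any group columns; class `error_table`.
#' @export
error_table <- function(pred, truth, groups = NULL) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!is.null(rownames(pred)) && !is.null(rownames(truth))) {
    miss <- setdiff(rownames(truth), rownames(pred))
    if (length(miss))
      stop("mixtures missing from predictions: ",
           paste(head(miss, 5), collapse = ", "))
    pred <- pred[rownames(truth), , drop = FALSE]
  }
  if (!identical(dim(pred), dim(truth)))
    stop("prediction and truth dimensions differ")
  if (!is.null(colnames(pred)) && !is.null(colnames(truth)))
    pred <- pred[, colnames(truth), drop = FALSE]
  df <- data.frame(
    mixture = rep(rownames(truth) %||% seq_len(nrow(truth)), ncol(truth)),
    type = rep(colnames(truth), each = nrow(truth)),
    pred = as.vector(pred), truth = as.vector(truth),
    stringsAsFactors = FALSE)
  df$raw_error <- df$pred - df$truth
  df$rpe <- ifelse(df$truth > 0, abs(df$pred - df$truth) / df$truth, NA_real_)
  if (!is.null(groups)) {
    groups <- as.data.frame(groups)
    if (nrow(groups) != nrow(truth))
      stop("groups must have one row per mixture")
    df <- cbind(df, groups[rep(seq_len(nrow(truth)), ncol(truth)), ,
                           drop = FALSE])
    rownames(df) <- NULL
  }
  class(df) <- c("error_table", "data.frame")
  df
}

#' Per-cell-type RMSE and Pearson correlation
#'
#' Within each (type, group) stratum, RMSE on the percent scale and
#' Pearson's r between predicted and true proportions; the per-type
#' summary is the median across groups. Strata with zero truth variance
#' yield undefined r and are excluded from the r medians (their count is
#' reported).
#'
#' @param errors an [error_table()].
#' @param group_by character vector of group columns in `errors`
#'   (default none: one stratum per type).
#' @return list with `by_group` (type, group, n, rmse, pearson_r) and
#'   `summary` (type, median_rmse, median_pearson_r,
#'   n_undefined_r).
#' @export
per_type_accuracy <- function(errors, group_by = character()) {
  stopifnot(all(group_by %in% names(errors)))
  key <- interaction(errors[c("type", group_by)], drop = TRUE, sep = "\r")
  parts <- split(errors, key)
  by_group <- do.call(rbind, lapply(parts, function(d) {
    if (nrow(d) == 0) stop("empty stratum")
    r <- if (nrow(d) >= 2 && stats::sd(d$truth) > 0 && stats::sd(d$pred) > 0)
      cor(d$pred, d$truth) else NA_real_
    cbind(d[1, c("type", group_by), drop = FALSE],
          data.frame(n = nrow(d),
                     rmse = sqrt(mean((d$pred - d$truth)^2)),
                     pearson_r = r))
  }))
  rownames(by_group) <- NULL
  summ <- do.call(rbind, lapply(split(by_group, by_group$type), function(d) {
    data.frame(type = d$type[1],
               median_rmse = median(d$rmse),
               median_pearson_r = if (all(is.na(d$pearson_r))) NA_real_
                 else median(d$pearson_r, na.rm = TRUE),
               n_undefined_r = sum(is.na(d$pearson_r)))
  }))
  rownames(summ) <- NULL
  list(by_group = by_group, summary = summ)
}

#' Relative Proportion Error summaries
#'
#' RPE (`|pred - truth| / truth`) normalizes an error by the size of the
#' true proportion, so a 5-point miss on a 2% population (RPE 2.5) is
#' flagged as much worse than on a 30% one (RPE 0.17). Computed only
#' where truth > 0; undefined entries are counted, not imputed.
#'
#' @param errors an [error_table()].
#' @param group_by character vector of group columns.
#' @return data.frame (type, group, n_defined, n_undefined, median_rpe,
#'   max_rpe).
#' @export
rpe_table <- function(errors, group_by = character()) {
  key <- interaction(errors[c("type", group_by)], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(errors, key), function(d) {
    def <- d$rpe[!is.na(d$rpe)]
    cbind(d[1, c("type", group_by), drop = FALSE],
          data.frame(n_defined = length(def),
                     n_undefined = sum(is.na(d$rpe)),
                     median_rpe = if (length(def)) median(def) else NA_real_,
                     max_rpe = if (length(def)) max(def) else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' False-positive / false-negative confusion analysis
#'
#' A (mixture, type) component with truth below the presence threshold
#' (0.1%) is an actual negative: predicting below the threshold is a
#' true negative, otherwise a false positive, binned by the predicted
#' value into [0.1, 1), [1, 10) and [10, Inf) percent. A component with
#' truth at or above the threshold is an actual positive: predicting
#' below the threshold is a false negative, binned by the true value
#' into the same intervals, otherwise a true positive. Rates are
#' `FP / (FP + TN)` and `FN / (FN + TP)`. Types whose proportion is
#' fixed by design (e.g. the cancer label in the fixed-purity series)
#' can be excluded before counting.
#'
#' @param errors an [error_table()].
#' @param presence_threshold percent below which a component counts as
#'   absent (default 0.1).
#' @param exclude_types types removed before counting.
#' @return a `confusion_summary`: list with `by_type` (per-type counts,
#'   rates and severity bins) and `overall`.
#' @export
confusion_analysis <- function(errors, presence_threshold = 0.1,
                               exclude_types = NULL) {
  if (presence_threshold <= 0) stop("presence_threshold must be positive")
  d <- errors[!(errors$type %in% exclude_types), , drop = FALSE]
  bins <- c(presence_threshold, 1, 10, Inf)
  bin_names <- c("0.1-1%", "1-10%", ">10%")
  classify <- function(d) {
    act_neg <- d$truth < presence_threshold
    pred_neg <- d$pred < presence_threshold
    tn <- act_neg & pred_neg
    fp <- act_neg & !pred_neg
    fn <- !act_neg & pred_neg
    tp <- !act_neg & !pred_neg
    fp_bins <- table(cut(d$pred[fp], bins, right = FALSE, labels = bin_names))
    fn_bins <- table(cut(d$truth[fn], bins, right = FALSE, labels = bin_names))
    data.frame(n = nrow(d), TP = sum(tp), TN = sum(tn),
               FP = sum(fp), FN = sum(fn),
               fp_rate = if (sum(fp) + sum(tn) > 0)
                 sum(fp) / (sum(fp) + sum(tn)) else NA_real_,
               fn_rate = if (sum(fn) + sum(tp) > 0)
                 sum(fn) / (sum(fn) + sum(tp)) else NA_real_,
               fp_bin_0.1_1 = fp_bins[[1]], fp_bin_1_10 = fp_bins[[2]],
               fp_bin_gt10 = fp_bins[[3]],
               fn_bin_0.1_1 = fn_bins[[1]], fn_bin_1_10 = fn_bins[[2]],
               fn_bin_gt10 = fn_bins[[3]])
  }
  by_type <- do.call(rbind, lapply(split(d, d$type), classify))
  by_type <- cbind(type = rownames(by_type), by_type)
  rownames(by_type) <- NULL
  structure(list(by_type = by_type, overall = classify(d),
                 presence_threshold = presence_threshold,
                 exclude_types = exclude_types),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("confusion_summary (threshold", x$presence_threshold, "%):\n")
  print(x$overall)
  invisible(x)
}

#' Subcomposition Aitchison distance (e.g. immune-only)
#'
#' Restricts both vectors to `keep_types`, re-closes each to 100 and
#' computes the Aitchison distance. Mixtures with zero truth (or
#' predicted) mass on the subcomposition are undefined and return NA.
#'
#' @inheritParams bray_curtis
#' @param types full type order of the vectors.
#' @param keep_types subcomposition labels.
#' @param delta pseudocount forwarded to [clr()].
#' @return non-negative real or NA.
#' @export
subcomposition_aitchison <- function(pred, truth, types, keep_types,
                                     delta = 1e-6) {
  idx <- types %in% keep_types
  p <- pred[idx]; t <- truth[idx]
  if (sum(t) == 0 || sum(p) == 0) return(NA_real_)
  aitchison_distance(p / sum(p) * 100, t / sum(t) * 100, delta = delta)
}

#' Full evaluation report over one or more methods
#'
#' For each prediction table: per-mixture Bray-Curtis and Aitchison
#' distances (optionally also the immune-only subcomposition variant),
#' per-type RMSE / Pearson / RPE summaries, and the FP/FN confusion
#' analysis. Methods are ranked by median Bray-Curtis (smaller is
#' better). When `out_dir` is given, writes `mixture_metrics.tsv`,
#' `per_type_accuracy.tsv`, `rpe.tsv`, `ranking.tsv` and
#' `confusion.json`.
#'
#' @param predictions named list of `prediction_table`s (names are
#'   method labels; unnamed entries use their `method` attribute).
#' @param truth truth matrix (mixtures x types, percent).
#' @param groups optional per-mixture grouping data.frame (see
#'   [error_table()]).
#' @param group_by group columns used for accuracy strata.
#' @param exclude_types types excluded from confusion counting.
#' @param immune_types optional labels defining the immune
#'   subcomposition.
#' @param out_dir optional directory for report files.
#' @return an `evaluation_report` list: `mixture_metrics` (long
#'   data.frame), `accuracy`, `rpe`, `confusion`, `ranking`.
#' @export
evaluate_predictions <- function(predictions, truth, groups = NULL,
                                 group_by = character(),
                                 exclude_types = NULL, immune_types = NULL,
                                 out_dir = NULL) {
  if (inherits(predictions, "prediction_table"))
    predictions <- list(predictions)
  nms <- names(predictions) %||% rep("", length(predictions))
  for (i in seq_along(predictions))
    if (!nzchar(nms[i]))
      nms[i] <- attr(predictions[[i]], "method") %||% paste0("method", i)
  names(predictions) <- nms
  truth <- as.matrix(truth)

  mixture_metrics <- list(); accuracy <- list(); rpe <- list()
  confusion <- list()
  for (nm in nms) {
    pred <- as.matrix(predictions[[nm]])
    miss <- setdiff(rownames(truth), rownames(pred))
    if (length(miss))
      stop("method ", nm, ": predictions missing mixtures: ",
           paste(head(miss, 5), collapse = ", "))
    pred <- pred[rownames(truth), colnames(truth), drop = FALSE]
    bc <- vapply(seq_len(nrow(truth)),
                 function(i) bray_curtis(pred[i, ], truth[i, ]), numeric(1))
    ad <- vapply(seq_len(nrow(truth)),
                 function(i) aitchison_distance(pred[i, ], truth[i, ]),
                 numeric(1))
    mm <- data.frame(method = nm, mixture = rownames(truth),
                     bray_curtis = bc, aitchison = ad,
                     stringsAsFactors = FALSE)
    if (!is.null(immune_types)) {
      mm$aitchison_immune <- vapply(seq_len(nrow(truth)), function(i)
        subcomposition_aitchison(pred[i, ], truth[i, ], colnames(truth),
                                 immune_types), numeric(1))
    }
    if (!is.null(groups)) mm <- cbind(mm, as.data.frame(groups))
    mixture_metrics[[nm]] <- mm
    et <- error_table(pred, truth, groups = groups)
    acc <- per_type_accuracy(et, group_by = group_by)
    accuracy[[nm]] <- cbind(method = nm, acc$summary)
    rpe[[nm]] <- cbind(method = nm, rpe_table(et, group_by = group_by))
    confusion[[nm]] <- confusion_analysis(et, exclude_types = exclude_types)
  }
  mixture_metrics <- do.call(rbind, c(mixture_metrics, make.row.names = FALSE))
  ranking <- do.call(rbind, lapply(nms, function(nm) {
    m <- mixture_metrics[mixture_metrics$method == nm, ]
    data.frame(method = nm,
               median_bray_curtis = median(m$bray_curtis),
               median_aitchison = median(m$aitchison))
  }))
  ranking <- ranking[order(ranking$median_bray_curtis), ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  rep_out <- structure(list(mixture_metrics = mixture_metrics,
                            accuracy = do.call(rbind, c(accuracy,
                                                        make.row.names = FALSE)),
                            rpe = do.call(rbind, c(rpe,
                                                   make.row.names = FALSE)),
                            confusion = confusion, ranking = ranking),
                       class = "evaluation_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(mixture_metrics, "mixture_metrics.tsv")
    wt(rep_out$accuracy, "per_type_accuracy.tsv")
    wt(rep_out$rpe, "rpe.tsv")
    wt(ranking, "ranking.tsv")
    jsonlite::write_json(
      lapply(confusion, function(cs)
        list(by_type = cs$by_type, overall = cs$overall,
             presence_threshold = cs$presence_threshold)),
      file.path(out_dir, "confusion.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep_out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report over", nrow(x$ranking), "method(s)\n")
  print(x$ranking)
  invisible(x)
}
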