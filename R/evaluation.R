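# Evaluation: ROC/AUROC (rank-based, ties counted half), repeated seeded
# runs, dropout-zero injection into raw counts, and the neighbor-count and
# dropout-robustness sweeps run as full retrain-per-condition procedures.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by
#' `positives x negatives`; tied scores contribute 1/2. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop_grn("length mismatch")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) {
    stop_grn("AUROC undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' ROC curve
#'
#' @param scores,labels As in [auroc()].
#' @return Object of class `"roc_result"`: data.frame of `threshold`, `fpr`,
#'   `tpr` (non-decreasing from 0 to 1) with attribute `auroc`, the
#'   trapezoidal area (identical to [auroc()]).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop_grn("ROC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied thresholds
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]; fp <- cumsum(1L - y)[last]
  df <- data.frame(threshold = c(Inf, s[last]),
                   fpr = c(0, fp / N), tpr = c(0, tp / P))
  area <- sum(diff(df$fpr) * (utils::head(df$tpr, -1) + utils::tail(df$tpr, -1)) / 2)
  structure(df, class = c("roc_result", "data.frame"), auroc = area)
}

#' Inject dropout zeros into a count matrix
#'
#' Mimics technical dropout by zeroing a fixed percentage of the eligible
#' entries: non-zero counts strictly below `count_threshold`. Exactly
#' `round(pct/100 * #eligible)` positions, drawn uniformly without
#' replacement with the given seed, are set to zero; all other entries are
#' untouched.
#'
#' @param expr An [expression_matrix()] of raw counts.
#' @param pct Percentage in (0, 100).
#' @param count_threshold Eligibility threshold on the raw count; default 200.
#' @param seed Integer seed.
#' @return A new [expression_matrix()].
#' @export
inject_dropout <- function(expr, pct, count_threshold = 200, seed = 1L) {
  check_scalar_num(pct, "pct", lower = 0, upper = 100, open_lower = TRUE,
                   open_upper = TRUE)
  check_scalar_num(count_threshold, "count_threshold", lower = 0,
                   open_lower = TRUE)
  vals <- expr$values
  eligible <- which(vals > 0 & vals < count_threshold)
  if (!length(eligible)) {
    warning("no eligible entries; matrix returned unchanged", call. = FALSE)
    return(expr)
  }
  n_zero <- round(pct / 100 * length(eligible))
  if (n_zero > 0) {
    hit <- with_seed(seed, sample(eligible, n_zero))
    vals[hit] <- 0
  }
  expression_matrix(vals, expr$gene_ids, expr$cell_ids)
}

#' Repeated seeded runs of a pipeline
#'
#' Runs `pipeline(seed)` for each seed and summarizes the returned AUROCs
#' (median and interquartile range), boxplot-ready.
#'
#' @param pipeline Function of one argument (the seed) returning an AUROC.
#' @param seeds Vector of distinct integer seeds (the reference protocol
#'   uses 10).
#' @return List with `runs` (data.frame seed/auroc), `median`, `iqr`.
#' @export
repeated_runs <- function(pipeline, seeds) {
  if (anyDuplicated(seeds)) stop_grn("seeds must be distinct")
  auc <- vapply(seeds, function(s) as.numeric(pipeline(s)), numeric(1L))
  list(runs = data.frame(seed = seeds, auroc = auc),
       median = stats::median(auc),
       iqr = stats::IQR(auc))
}

#' Neighbor-count sweep
#'
#' Retrains and cross-validates the full pipeline for each neighbor count
#' `n` and tabulates the held-out AUROC, quantifying how much the
#' neighbor-image context contributes. `n = 0` is the primary +
#' self-images-only baseline.
#'
#' @param dataset A [simulate_dataset()] result (or any list with elements
#'   `matrix`, `truth`, `tfs`).
#' @param n_values Ascending neighbor counts to test.
#' @param ... Passed to [grnimage()] (model/head/training configs, seeds...).
#' @return Data.frame with columns `n`, `pooled_auroc`, `mean_accuracy`.
#' @export
neighbor_sweep <- function(dataset, n_values, ...) {
  if (is.unsorted(n_values)) stop_grn("n_values must be ascending")
  rows <- lapply(n_values, function(nv) {
    fit <- grnimage(dataset$matrix, dataset$truth, dataset$tfs,
                    n_neighbors = nv, ...)
    data.frame(n = nv, pooled_auroc = fit$cv$pooled_auroc,
               mean_accuracy = fit$cv$mean_accuracy)
  })
  do.call(rbind, rows)
}

#' Dropout-robustness sweep
#'
#' For each injection percentage, draws `replicates` seeded dropout-zero
#' injections into the raw counts, reruns the whole pipeline (preprocessing,
#' imaging, training from scratch) on each perturbed matrix, and records the
#' held-out AUROC. `pct = 0` rows are the unperturbed pipeline.
#'
#' @param dataset As in [neighbor_sweep()].
#' @param pcts Injection percentages (the reference protocol uses
#'   `seq(10, 90, 10)`).
#' @param replicates Seeded replicates per level; default 10.
#' @param count_threshold Raw-count eligibility bound; default 200.
#' @param seed Base seed; replicate `r` of level `p` uses a distinct offset.
#' @param ... Passed to [grnimage()].
#' @return Data.frame with columns `pct`, `replicate`, `pooled_auroc`.
#' @export
dropout_sweep <- function(dataset, pcts, replicates = 10,
                          count_threshold = 200, seed = 1L, ...) {
  rows <- list()
  for (p in pcts) {
    reps <- if (p == 0) 1L else as.integer(replicates)
    for (r in seq_len(reps)) {
      inj_seed <- seed + 7919L * match(p, pcts) + r
      m <- if (p == 0) dataset$matrix else {
        inject_dropout(dataset$matrix, p, count_threshold, seed = inj_seed)
      }
      fit <- grnimage(m, dataset$truth, dataset$tfs, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        pct = p, replicate = r, pooled_auroc = fit$cv$pooled_auroc)
    }
  }
  do.call(rbind, rows)
}
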