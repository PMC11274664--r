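# Applying trained models: scoring all candidate TF -> gene pairs into a
# directed prediction table, thresholding it into an edge list, and
# comparing predicted networks.

#' Score all candidate TF -> gene pairs
#'
#' One score per `(tf, candidate)` pair with `tf != candidate`. When several
#' models are supplied (the cross-validation folds), their evaluation-mode
#' scores are averaged.
#'
#' @param models A `"grn_classifier"` or a list of them.
#' @param prep A [preprocess_expression()] result. If the models carry a
#'   preprocessing manifest it must match.
#' @param tfs,candidates Gene ids present in the matrix.
#' @param n Neighbor count; must equal the models' `n`.
#' @param within Candidate set for neighbor ranking; defaults to the HVG
#'   set plus the TFs.
#' @return Data.frame `tf`, `target`, `score` in \[0, 1\], sorted by
#'   decreasing score.
#' @export
predict_edges <- function(models, prep, tfs, candidates, n, within = NULL) {
  if (inherits(models, "grn_classifier")) models <- list(models)
  for (m in models) {
    if (m$n != n) {
      stop_grn("model expects n = %d but n = %d requested", m$n, n)
    }
    if (!is.null(m$manifest) && !identical(m$manifest, prep$manifest)) {
      stop_grn(paste("preprocessing manifest mismatch: model trained under",
                     m$manifest, "but matrix preprocessed under",
                     prep$manifest))
    }
  }
  bad <- c(tfs, candidates)[is.na(match_ids(c(tfs, candidates),
                                            prep$gene_ids))]
  if (length(bad)) {
    stop_grn("unknown gene id(s): %s", paste(unique(bad), collapse = ", "))
  }
  within <- within %||% union(prep$hvg_ids,
                              prep$gene_ids[match_ids(tfs, prep$gene_ids)])
  pairs <- expand.grid(tf = tfs, target = candidates,
                       stringsAsFactors = FALSE)
  pairs <- pairs[toupper(pairs$tf) != toupper(pairs$target), , drop = FALSE]
  pairs <- pairs[order(pairs$tf, pairs$target), , drop = FALSE]
  stacks <- build_stacks(pairs, prep, n, within = within)
  score <- rowMeans(vapply(models, function(m) score_stacks(m, stacks),
                           numeric(nrow(pairs))))
  out <- data.frame(tf = pairs$tf, target = pairs$target, score = score,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$tf, out$target), ]
}

#' Threshold a prediction table into a directed network
#'
#' @param table Prediction table (`tf`, `target`, `score`).
#' @param cutoff Score cutoff in \[0, 1\]; edges with `score >= cutoff` are
#'   kept, ordered by descending score.
#' @return An [edge_list()].
#' @export
threshold_network <- function(table, cutoff) {
  check_scalar_num(cutoff, "cutoff", lower = 0, upper = 1)
  table <- validate_predictions(table)
  keep <- table[table$score >= cutoff, , drop = FALSE]
  keep <- keep[order(-keep$score), , drop = FALSE]
  edge_list(keep$tf, keep$target)
}

#' Compare two directed networks
#'
#' Exact partition of the directed pairs into those only in `a`, only in
#' `b`, and common to both.
#'
#' @param a,b [edge_list()]s.
#' @return List of three edge lists: `only_a`, `only_b`, `common`.
#' @export
compare_networks <- function(a, b) {
  ka <- paste(toupper(a$tf), toupper(a$target), sep = "\r")
  kb <- paste(toupper(b$tf), toupper(b$target), sep = "\r")
  list(only_a = a[!(ka %in% kb), , drop = FALSE],
       only_b = b[!(kb %in% ka), , drop = FALSE],
       common = a[ka %in% kb, , drop = FALSE])
}
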