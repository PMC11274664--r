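# The user-facing fitting function in the classic modelling idiom: one call
# wires preprocessing, labeled-pair construction, image-stack building and
# cross-validated training, returning a classed object with
# print/summary/predict/plot methods.

#' Fit an image-based gene-regulatory-network classifier
#'
#' Runs the full supervised pipeline on a raw count matrix and a known
#' TF -> target edge list: per-cell normalization and log transform, HVG
#' selection, per-gene winsorization, balanced labeled-pair construction,
#' joint-histogram image-stack encoding with `n_neighbors` positive-
#' covariance neighbor images per gene, and k-fold cross-validated training
#' of the twin-tower convolutional classifier.
#'
#' @param expr An [expression_matrix()] of raw counts (or a plain matrix
#'   with gene/cell dimnames).
#' @param edges An [edge_list()] of known TF -> target interactions.
#' @param tfs Character vector of TF ids.
#' @param n_neighbors Neighbor images per gene; default 100, the point past
#'   which added context stops paying for its cost on real data. Use small
#'   values (3-10) for small matrices.
#' @param hvg_count,size_factor,clip_fraction Preprocessing parameters; see
#'   [preprocess_expression()].
#' @param tower,head,training Configurations; see [tower_config()],
#'   [head_config()], [training_config()].
#' @param folds Number of cross-validation folds; default 3.
#' @param group_by_tf Keep each TF's pairs in one fold; default `TRUE`.
#' @param max_tfs Optional cap: randomly subsample this many TFs (seeded)
#'   before building pairs.
#' @param n_restarts Independently initialized models per fold, averaged at
#'   scoring time; default 1. See [cross_validate()].
#' @param augment Number of cell-bootstrap training copies per pair
#'   (default 0, off): each copy is the pair's image stack rebuilt from a
#'   seeded random 70% subset of cells under the full-data bin edges.
#'   Copies only ever augment the training side of a fold, never its
#'   held-out evaluation. At small sample sizes this breaks the
#'   memorize-the-exact-image shortcut while preserving the co-expression
#'   structure the classifier should learn.
#' @param seed Integer seed governing sampling, fold assignment, weight
#'   initialization and SGD.
#' @return Object of class `"grnimage"`: list with the preprocessed matrix
#'   (`prep`), labeled pairs (`pairs`), fold split, fitted per-fold models
#'   and metrics (`cv`), and all configurations. Use [predict.grnimage()] to
#'   score candidate pairs and [plot.grnimage()] for training curves.
#' @export
grnimage <- function(expr, edges, tfs, n_neighbors = 100L, hvg_count = 500L,
                     size_factor = 1e4, clip_fraction = 0.05,
                     tower = tower_config("tiny"), head = head_config(),
                     training = training_config(), folds = 3L,
                     group_by_tf = TRUE, max_tfs = NULL, seed = 1L,
                     n_restarts = 1L, augment = 0L) {
  if (!inherits(expr, "expression_matrix")) {
    expr <- expression_matrix(as.matrix(expr))
  }
  missing_tfs <- tfs[is.na(match_ids(tfs, expr$gene_ids))]
  if (length(missing_tfs)) {
    warning(sprintf("TF id(s) not in matrix, dropped: %s",
                    paste(missing_tfs, collapse = ", ")), call. = FALSE)
    tfs <- setdiff(tfs, missing_tfs)
  }
  if (!length(tfs)) stop_grn("no TF id matches the expression matrix")
  if (!is.null(max_tfs) && max_tfs < length(tfs)) {
    tfs <- with_seed(seed, sample(tfs, max_tfs))
  }
  prep <- preprocess_expression(expr, size_factor = size_factor,
                                hvg_count = hvg_count,
                                clip_fraction = clip_fraction)
  pairs <- build_label_set(edges, tfs, prep$hvg_ids, seed = seed)
  universe <- union(prep$hvg_ids,
                    prep$gene_ids[match_ids(tfs, prep$gene_ids)])
  stacks <- build_stacks(pairs, prep, n_neighbors, within = universe)
  aug <- NULL
  aug_map <- NULL
  if (augment > 0) {
    n_cells <- ncol(prep$values)
    take <- max(2L, round(0.7 * n_cells))
    aug <- list()
    aug_map <- integer()
    for (r in seq_len(augment)) {
      cells <- with_seed(seed + 131L * r,
                         sample(n_cells, take))
      aug <- c(aug, build_stacks(pairs, prep, n_neighbors,
                                 within = universe, cells = cells))
      aug_map <- c(aug_map, seq_len(nrow(pairs)))
    }
  }
  fold_split <- make_folds(pairs, k = folds, seed = seed,
                           group_by_tf = group_by_tf)
  cv <- cross_validate(stacks, pairs$label, fold_split, model_cfg = tower,
                       head_cfg = head, cfg = training, seed = seed,
                       manifest = prep$manifest, n_restarts = n_restarts,
                       aug_stacks = aug, aug_map = aug_map)
  structure(list(prep = prep, pairs = pairs, stacks = stacks,
                 fold_split = fold_split, cv = cv, tfs = tfs,
                 n_neighbors = as.integer(n_neighbors),
                 universe = universe,
                 configs = list(tower = tower, head = head,
                                training = training, folds = folds,
                                group_by_tf = group_by_tf, seed = seed)),
            class = "grnimage")
}

#' @export
print.grnimage <- function(x, ...) {
  cat("Image-based GRN classifier fit\n")
  cat(sprintf("  %d TFs, %d labeled pairs (%d positive), %d HVGs, n = %d neighbors\n",
              length(x$tfs), nrow(x$pairs), sum(x$pairs$label),
              length(x$prep$hvg_ids), x$n_neighbors))
  cat(sprintf("  %d-fold CV: mean accuracy %.3f, pooled held-out AUROC %.3f\n",
              length(x$fold_split), x$cv$mean_accuracy, x$cv$pooled_auroc))
  invisible(x)
}

#' @export
summary.grnimage <- function(object, ...) {
  out <- list(pairs = nrow(object$pairs),
              positives = sum(object$pairs$label),
              tfs = length(object$tfs),
              hvgs = length(object$prep$hvg_ids),
              n_neighbors = object$n_neighbors,
              fold_metrics = object$cv$fold_metrics,
              mean_accuracy = object$cv$mean_accuracy,
              mean_auroc = object$cv$mean_auroc,
              pooled_auroc = object$cv$pooled_auroc,
              parameters = count_parameters(object$cv$models[[1L]][[1L]]))
  class(out) <- "summary.grnimage"
  out
}

#' @export
print.summary.grnimage <- function(x, ...) {
  cat("Image-based GRN classifier fit\n")
  cat(sprintf("  labeled pairs: %d (%d positive), TFs: %d, HVGs: %d, neighbors: %d\n",
              x$pairs, x$positives, x$tfs, x$hvgs, x$n_neighbors))
  cat(sprintf("  model parameters per tower pair: %s\n",
              format(x$parameters, big.mark = ",")))
  cat("  per-fold held-out metrics:\n")
  print(x$fold_metrics, row.names = FALSE)
  cat(sprintf("  mean accuracy %.3f | mean AUROC %.3f | pooled AUROC %.3f\n",
              x$mean_accuracy, x$mean_auroc, x$pooled_auroc))
  invisible(x)
}

#' Score candidate TF -> gene pairs with a fitted model
#'
#' Builds the image stack for every `(tf, candidate)` pair (excluding
#' self-pairs) under the preprocessing manifest the model was trained with
#' and scores it with each fold's model, averaging the fold scores.
#' Evaluation mode is deterministic and invariant to candidate order.
#'
#' @param object A [grnimage()] fit.
#' @param tfs TF ids to score; default the fitted TFs.
#' @param candidates Candidate target ids; default the training HVG set.
#' @param newdata Optional [preprocess_expression()] result to score against;
#'   must carry the same preprocessing manifest, otherwise scoring is
#'   refused.
#' @param ... Unused.
#' @return A prediction table: data.frame `tf`, `target`, `score` sorted by
#'   decreasing score.
#' @export
predict.grnimage <- function(object, tfs = NULL, candidates = NULL,
                             newdata = NULL, ...) {
  prep <- newdata %||% object$prep
  if (!identical(prep$manifest, object$prep$manifest)) {
    stop_grn(paste("preprocessing manifest mismatch: the model was trained",
                   "under manifest", object$prep$manifest,
                   "- rerun preprocess_expression() with the same parameters"))
  }
  tfs <- tfs %||% object$tfs
  candidates <- candidates %||% object$prep$hvg_ids
  predict_edges(unlist(object$cv$models, recursive = FALSE), prep, tfs,
                candidates, n = object$n_neighbors, within = object$universe)
}

#' Plot cross-validation training curves
#'
#' Loss and accuracy per epoch, training versus inner-validation, one panel
#' pair per fold.
#'
#' @param x A [grnimage()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.grnimage <- function(x, ...) {
  k <- length(x$cv$histories)
  op <- graphics::par(mfrow = c(k, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) {
    h <- x$cv$histories[[i]]
    graphics::matplot(h$epoch, cbind(h$loss, h$val_loss), type = "l",
                      lty = 1, col = c("black", "red"), xlab = "epoch",
                      ylab = "loss", main = sprintf("fold %d", i), ...)
    graphics::legend("topright", c("loss", "val_loss"), lty = 1,
                     col = c("black", "red"), bty = "n", cex = 0.8)
    graphics::matplot(h$epoch, cbind(h$accuracy, h$val_accuracy), type = "l",
                      lty = 1, col = c("black", "red"), xlab = "epoch",
                      ylab = "accuracy", ylim = c(0, 1), ...)
    graphics::legend("bottomright", c("accuracy", "val_accuracy"), lty = 1,
                     col = c("black", "red"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
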