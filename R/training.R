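# Supervised training: labeled pair construction from a known edge list with
# per-TF balanced negative sampling, stratified (optionally TF-grouped)
# k-fold splits, and the mini-batch SGD loop with early stopping on
# validation accuracy.

#' Training configuration
#'
#' @param batch_size Mini-batch size; default 32.
#' @param max_epochs Maximum epochs; default 100.
#' @param patience Early-stopping patience, in epochs without improvement of
#'   validation accuracy; default 10. Must be below `max_epochs`.
#' @param learning_rate SGD learning rate; default 0.01.
#' @param momentum SGD momentum; default 0.9.
#' @param weight_decay L2 penalty coefficient on all weights; default 0.
#' @param grad_clip Global gradient-norm ceiling (clipped by rescaling);
#'   default `Inf` (off). Guards against divergence at high learning rates.
#' @param val_fraction Fraction of the training pairs held out (stratified)
#'   for early-stopping validation; default 0.1. Set to 0 to disable early
#'   stopping: training then uses every pair for the full `max_epochs` and
#'   keeps the final weights.
#' @param lr_schedule `"constant"` (default) or `"cosine"` — cosine decay
#'   of the learning rate from its initial value to 5% of it across
#'   `max_epochs`, the usual companion of tail weight averaging.
#' @param tail_average In fixed-budget mode (`val_fraction = 0`), average
#'   the weights of the last `tail_average` epochs (Polyak-style tail
#'   averaging, with the batch-norm statistics refreshed afterwards);
#'   default 0 (off). Smooths out the late-training SGD noise that
#'   small-sample runs are sensitive to.
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(batch_size = 32L, max_epochs = 100L,
                            patience = 10L, learning_rate = 0.01,
                            momentum = 0.9, weight_decay = 0,
                            grad_clip = Inf, val_fraction = 0.1,
                            lr_schedule = c("constant", "cosine"),
                            tail_average = 0L) {
  lr_schedule <- match.arg(lr_schedule)
  check_scalar_num(batch_size, "batch_size", lower = 1)
  check_scalar_num(max_epochs, "max_epochs", lower = 1)
  check_scalar_num(patience, "patience", lower = 1)
  if (patience >= max_epochs) stop_grn("patience must be below max_epochs")
  check_scalar_num(learning_rate, "learning_rate", lower = 0,
                   open_lower = TRUE)
  check_scalar_num(momentum, "momentum", lower = 0, upper = 1,
                   open_upper = TRUE)
  check_scalar_num(weight_decay, "weight_decay", lower = 0)
  check_scalar_num(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, grad_clip = grad_clip,
                 val_fraction = val_fraction, lr_schedule = lr_schedule,
                 tail_average = as.integer(tail_average)),
            class = "training_config")
}

#' Build a balanced labeled pair set
#'
#' Positives are the known edges restricted to `tfs x hvgs` (self-pairs
#' excluded). For each TF with `p` positives, exactly `p` negatives are drawn
#' uniformly without replacement from the HVG set minus that TF's known
#' targets and minus the TF itself, so the label set is balanced per TF and
#' globally. TFs with no positives are dropped with a warning.
#'
#' @param edges An [edge_list()] of known TF -> target interactions.
#' @param tfs Character vector of TF ids.
#' @param hvgs Character vector of candidate target ids (the HVG set).
#' @param seed Integer seed for the negative draws.
#' @return Object of class `"labeled_pairs"`: data.frame with columns `tf`,
#'   `target`, `label` (1 = known edge, 0 = sampled non-target), plus
#'   attributes `tf_universe` and `gene_universe`.
#' @export
build_label_set <- function(edges, tfs, hvgs, seed = 1L) {
  if (!length(tfs)) stop_grn("empty TF list")
  if (!nrow(edges)) stop_grn("empty edge list")
  hvgs_u <- toupper(hvgs)
  rows <- list()
  with_seed(seed, {
    for (tf in tfs) {
      pos <- edges$target[toupper(edges$tf) == toupper(tf)]
      pos <- pos[toupper(pos) %in% hvgs_u & toupper(pos) != toupper(tf)]
      pos <- pos[!duplicated(toupper(pos))]
      if (!length(pos)) {
        warning(sprintf("TF %s has no positive pairs in the HVG set; dropped",
                        tf), call. = FALSE)
        next
      }
      known <- edges$target[toupper(edges$tf) == toupper(tf)]
      pool <- hvgs[!(hvgs_u %in% toupper(known)) & hvgs_u != toupper(tf)]
      n_neg <- length(pos)
      if (length(pool) < n_neg) {
        warning(sprintf("TF %s: only %d negatives available for %d positives",
                        tf, length(pool), n_neg), call. = FALSE)
        n_neg <- length(pool)
      }
      neg <- if (n_neg > 0) sample(pool, n_neg) else character()
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, target = c(pos, neg),
        label = c(rep(1L, length(pos)), rep(0L, length(neg))),
        stringsAsFactors = FALSE)
    }
  })
  if (!length(rows)) stop_grn("no TF retained any positive pairs")
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(df, class = c("labeled_pairs", "data.frame"),
            tf_universe = unique(df$tf), gene_universe = hvgs)
}

#' Split labeled pairs into cross-validation folds
#'
#' By default all pairs of one TF land in the same fold (TF-grouped split:
#' the held-out fold contains TFs the model never saw), with TFs assigned to
#' the currently smallest fold in seeded random order. With
#' `group_by_tf = FALSE`, or when there are fewer TFs than folds, plain
#' label-stratified splitting is used instead.
#'
#' @param pairs A [build_label_set()] result.
#' @param k Number of folds; default 3.
#' @param seed Integer seed.
#' @param group_by_tf Keep each TF's pairs in one fold; default `TRUE`.
#' @return List of `k` integer index vectors (class `"fold_split"`),
#'   disjoint and covering `seq_len(nrow(pairs))`.
#' @export
make_folds <- function(pairs, k = 3L, seed = 1L, group_by_tf = TRUE) {
  check_scalar_num(k, "k", lower = 2)
  k <- as.integer(k)
  if (sum(pairs$label == 1L) < k || sum(pairs$label == 0L) < k) {
    stop_grn("need at least %d pairs of each label", k)
  }
  tfs <- unique(pairs$tf)
  folds <- with_seed(seed, {
    if (group_by_tf && length(tfs) < k) {
      warning(sprintf("only %d TF(s) for %d folds; falling back to pair-level split",
                      length(tfs), k), call. = FALSE)
      group_by_tf <- FALSE
    }
    if (group_by_tf) {
      f <- vector("list", k)
      sizes <- integer(k)
      for (tf in sample(tfs)) {
        idx <- which(pairs$tf == tf)
        dest <- which.min(sizes)
        f[[dest]] <- c(f[[dest]], idx)
        sizes[dest] <- sizes[dest] + length(idx)
      }
      f
    } else {
      f <- vector("list", k)
      for (lb in c(1L, 0L)) {
        idx <- sample(which(pairs$label == lb))
        assign_to <- rep_len(seq_len(k), length(idx))
        for (j in seq_len(k)) f[[j]] <- c(f[[j]], idx[assign_to == j])
      }
      f
    }
  })
  folds <- lapply(folds, sort)
  structure(folds, class = "fold_split")
}

bce_loss <- function(prob, label) {
  eps <- 1e-12
  -mean(label * log(prob + eps) + (1 - label) * log(1 - prob + eps))
}

# Average evaluation-mode scores over a list of models.
ensemble_scores <- function(models, stacks) {
  rowMeans(vapply(models, function(m) score_stacks(m, stacks),
                  numeric(length(stacks))))
}

# One evaluation pass: loss + accuracy (+ scores) on a set of stacks.
evaluate_stacks <- function(model, stacks, labels) {
  prob <- score_stacks(model, stacks)
  list(loss = bce_loss(prob, labels),
       accuracy = mean((prob >= 0.5) == (labels == 1L)),
       prob = prob)
}

snapshot_model <- function(model) {
  list(par = model$par, bn = as.list(model$bn))
}

restore_model <- function(model, snap) {
  model$par <- snap$par
  model$bn <- list2env(snap$bn, parent = emptyenv())
  model
}

#' Train the classifier on one fold
#'
#' Seeded mini-batch SGD with momentum on binary cross-entropy, tracking
#' per-epoch training and validation loss and accuracy. Stops early when the
#' validation accuracy has not improved over the last `patience` epochs and
#' restores the weights of the best-validation-accuracy epoch.
#'
#' @param stacks List of image stacks (one per labeled pair).
#' @param labels Integer 0/1 vector aligned with `stacks`.
#' @param train_idx,val_idx Disjoint index vectors into `stacks`.
#' @param model_cfg A [tower_config()].
#' @param head_cfg A [head_config()].
#' @param cfg A [training_config()].
#' @param seed Integer seed controlling weight init, batch order and dropout.
#' @param manifest Optional preprocessing manifest hash pinned to the model.
#' @return List with `model` (trained `"grn_classifier"`), `history`
#'   (data.frame epoch/loss/accuracy/val_loss/val_accuracy) and `best_epoch`.
#' @export
train_fold <- function(stacks, labels, train_idx, val_idx,
                       model_cfg = tower_config("tiny"),
                       head_cfg = head_config(), cfg = training_config(),
                       seed = 1L, manifest = NULL) {
  no_val <- is.null(val_idx) || !length(val_idx)
  if (!length(train_idx)) stop_grn("empty training set")
  if (no_val && cfg$val_fraction > 0) {
    stop_grn("empty validation set (pass val_fraction = 0 to train without one)")
  }
  if (length(intersect(train_idx, val_idx))) {
    stop_grn("training and validation indices overlap")
  }
  n <- stacks[[train_idx[1L]]]$n
  labels <- as.integer(labels)
  with_seed(seed, {
    model <- build_classifier(n, model_cfg, head_cfg, manifest = manifest)
    vel <- lapply(model$par, function(p) p * 0)
    history <- data.frame(epoch = integer(), loss = numeric(),
                          accuracy = numeric(), val_loss = numeric(),
                          val_accuracy = numeric())
    best <- list(acc = -Inf, loss = Inf, epoch = 0L,
                 snap = snapshot_model(model))
    tail_sum <- NULL
    tail_n <- 0L
    mom <- cfg$momentum
    val_stacks <- stacks[val_idx]
    val_labels <- labels[val_idx]
    for (epoch in seq_len(cfg$max_epochs)) {
      lr <- if (cfg$lr_schedule == "cosine") {
        cfg$learning_rate *
          (0.05 + 0.95 * 0.5 * (1 + cos(pi * (epoch - 1) / cfg$max_epochs)))
      } else cfg$learning_rate
      ord <- sample(train_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        y <- labels[bidx]
        fw <- classifier_forward(model, stacks[bidx], train = TRUE,
                                 keep = TRUE)
        ep_loss <- ep_loss + bce_loss(fw$prob, y) * length(bidx)
        ep_correct <- ep_correct + sum((fw$prob >= 0.5) == (y == 1L))
        dlogit <- (fw$prob - y) / length(bidx)
        grads <- classifier_backward(model, fw$caches, dlogit)
        if (is.finite(cfg$grad_clip)) {
          gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g),
                                   numeric(1L))))
          if (gnorm > cfg$grad_clip) {
            sc <- cfg$grad_clip / gnorm
            grads <- lapply(grads, function(g) g * sc)
          }
        }
        for (nmp in names(grads)) {
          g <- grads[[nmp]]
          if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * model$par[[nmp]]
          vel[[nmp]] <- mom * vel[[nmp]] + g
          model$par[[nmp]] <- model$par[[nmp]] - lr * vel[[nmp]]
        }
      }
      ev <- if (no_val) list(loss = NA_real_, accuracy = NA_real_) else {
        evaluate_stacks(model, val_stacks, val_labels)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = ep_loss / length(ord),
        accuracy = ep_correct / length(ord),
        val_loss = ev$loss, val_accuracy = ev$accuracy))
      if (!is.finite(ep_loss)) break
      if (no_val) {
        best <- list(acc = NA_real_, loss = NA_real_, epoch = epoch,
                     snap = snapshot_model(model))
        if (cfg$tail_average > 0 &&
            epoch > cfg$max_epochs - cfg$tail_average) {
          tail_sum <- if (is.null(tail_sum)) model$par else {
            mapply(`+`, tail_sum, model$par, SIMPLIFY = FALSE)
          }
          tail_n <- tail_n + 1L
        }
        next
      }
      if (!is.finite(ev$loss)) break
      # early stopping monitors validation accuracy (patience counts epochs
      # since the last accuracy gain); among epochs tied on the best
      # accuracy, the snapshot with the lowest validation loss is kept
      if (ev$accuracy > best$acc) {
        best <- list(acc = ev$accuracy, loss = ev$loss, epoch = epoch,
                     snap = snapshot_model(model))
      } else if (ev$accuracy == best$acc && ev$loss < best$loss) {
        best$loss <- ev$loss
        best$snap <- snapshot_model(model)
      }
      if (epoch - best$epoch >= cfg$patience) break
    }
    model <- restore_model(model, best$snap)
    if (!is.null(tail_sum) && tail_n > 1L) {
      model$par <- lapply(tail_sum, `/`, tail_n)
      # averaged weights need fresh batch-norm statistics: one
      # training-mode pass over the whole training set with the running
      # stats replaced outright
      model$bn <- new.env(parent = emptyenv())
      model$bn[[".m_override"]] <- 1
      invisible(classifier_forward(model, stacks[train_idx],
                                   train = TRUE, keep = FALSE))
      rm(".m_override", envir = model$bn)
    }
    list(model = model, history = history, best_epoch = best$epoch)
  })
}

# Stratified split of train indices into (train, val) for early stopping.
split_validation <- function(idx, labels, val_fraction, seed) {
  if (val_fraction == 0) return(list(train = idx, val = integer()))
  with_seed(seed, {
    val <- integer()
    for (lb in c(0L, 1L)) {
      sub <- idx[labels[idx] == lb]
      n_val <- max(1L, round(val_fraction * length(sub)))
      if (length(sub) > n_val) val <- c(val, sample(sub, n_val))
    }
    if (!length(val)) val <- sample(idx, 1L)
    list(train = setdiff(idx, val), val = sort(val))
  })
}

#' k-fold cross-validation of the pair classifier
#'
#' Trains one model per fold on the remaining folds (with an inner
#' stratified validation split for early stopping) and evaluates it on the
#' held-out fold. Reports per-fold accuracy and AUROC, their means, and the
#' pooled AUROC computed from all held-out predictions together.
#'
#' @param stacks List of image stacks (one per labeled pair).
#' @param labels Integer 0/1 vector aligned with `stacks`.
#' @param folds A [make_folds()] split.
#' @param model_cfg,head_cfg,cfg Configurations, as in [train_fold()].
#' @param seed Integer seed; fold `i` trains under `seed + i`.
#' @param manifest Optional preprocessing manifest hash.
#' @param n_restarts Independently initialized models trained per fold; the
#'   fold's held-out scores are their average. Default 1.
#' @param aug_stacks,aug_map Optional training-time augmentation: extra
#'   stacks (e.g. built from cell subsamples) and the index of the original
#'   pair each one copies. Augmented copies of a fold's training pairs join
#'   that fold's training set with the same label; held-out evaluation only
#'   ever sees the original stacks.
#' @return Object of class `"grn_cv"`: list with `models` (per fold, a list
#'   of `n_restarts` classifiers), `fold_metrics` (accuracy and AUROC per
#'   fold), `mean_accuracy`, `mean_auroc`, `pooled_auroc`, `pooled`
#'   (held-out scores and labels), `histories`.
#' @export
cross_validate <- function(stacks, labels, folds,
                           model_cfg = tower_config("tiny"),
                           head_cfg = head_config(), cfg = training_config(),
                           seed = 1L, manifest = NULL, n_restarts = 1L,
                           aug_stacks = NULL, aug_map = NULL) {
  labels <- as.integer(labels)
  k <- length(folds)
  P <- length(stacks)
  all_stacks <- c(stacks, aug_stacks)
  all_labels <- c(labels, labels[aug_map])
  models <- vector("list", k)
  histories <- vector("list", k)
  acc <- auc <- numeric(k)
  pooled_scores <- numeric(length(stacks))
  pooled_fold <- integer(length(stacks))
  for (i in seq_len(k)) {
    test_idx <- folds[[i]]
    rest <- sort(unlist(folds[-i]))
    sv <- split_validation(rest, labels, cfg$val_fraction, seed + 1000L * i)
    tr_idx <- c(sv$train, P + which(aug_map %in% sv$train))
    fits <- lapply(seq_len(n_restarts), function(r) {
      train_fold(all_stacks, all_labels, tr_idx, sv$val, model_cfg, head_cfg,
                 cfg, seed = seed + i + 997L * (r - 1L), manifest = manifest)
    })
    models[[i]] <- lapply(fits, `[[`, "model")
    histories[[i]] <- fits[[1L]]$history
    prob <- ensemble_scores(models[[i]], stacks[test_idx])
    acc[i] <- mean((prob >= 0.5) == (labels[test_idx] == 1L))
    auc[i] <- auroc(prob, labels[test_idx])
    pooled_scores[test_idx] <- prob
    pooled_fold[test_idx] <- i
  }
  structure(list(models = models, histories = histories,
                 fold_metrics = data.frame(fold = seq_len(k),
                                           accuracy = acc, auroc = auc),
                 mean_accuracy = mean(acc), mean_auroc = mean(auc),
                 pooled_auroc = auroc(pooled_scores, labels),
                 pooled = data.frame(score = pooled_scores, label = labels,
                                     fold = pooled_fold),
                 folds = folds, seed = seed),
            class = "grn_cv")
}

#' @export
print.grn_cv <- function(x, ...) {
  cat(sprintf("grn_cv: %d folds, mean accuracy %.3f, mean AUROC %.3f, pooled AUROC %.3f\n",
              nrow(x$fold_metrics), x$mean_accuracy, x$mean_auroc,
              x$pooled_auroc))
  invisible(x)
}
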