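test_that("label sets are balanced per TF and exclude known edges", {
  ls <- build_label_set(toy_edges(), c("TF1", "TF2"), toy_hvgs(), seed = 1)
  expect_equal(nrow(ls), 16L)                  # 3+5 positives, mirrored
  expect_equal(sum(ls$label), 8L)
  for (tf in c("TF1", "TF2")) {
    sub <- ls[ls$tf == tf, ]
    expect_equal(sum(sub$label == 1), sum(sub$label == 0))
  }
  # no negative coincides with a known edge; no self pairs; no duplicates
  known <- paste(toy_edges()$tf, toy_edges()$target)
  neg <- ls[ls$label == 0, ]
  expect_false(any(paste(neg$tf, neg$target) %in% known))
  expect_false(any(toupper(ls$tf) == toupper(ls$target)))
  expect_false(anyDuplicated(paste(ls$tf, ls$target)) > 0)
  # determinism
  expect_identical(ls, build_label_set(toy_edges(), c("TF1", "TF2"),
                                       toy_hvgs(), seed = 1))
})

test_that("negative sampling truncates with a warning when the pool dries up", {
  edges <- edge_list(rep("TFX", 3), c("G01", "G02", "G03"))
  expect_warning(
    ls <- build_label_set(edges, "TFX", c("G01", "G02", "G03", "G04"),
                          seed = 2),
    "negatives available")
  expect_equal(sum(ls$label == 0), 1L)
  expect_error(suppressWarnings(
    build_label_set(edges, "NOPE", toy_hvgs(), seed = 1)),
    "no TF retained")
})

test_that("fold splits are disjoint, complete and stratified", {
  ls <- build_label_set(toy_edges(), c("TF1", "TF2"), toy_hvgs(), seed = 1)
  f <- make_folds(ls, k = 3, seed = 4, group_by_tf = FALSE)
  idx <- sort(unlist(f))
  expect_identical(idx, seq_len(nrow(ls)))
  expect_equal(anyDuplicated(unlist(f)), 0L)
  global <- mean(ls$label)
  for (fd in f) {
    expect_lt(abs(mean(ls$label[fd]) - global), 0.05 + 1e-9)
  }
  expect_identical(f, make_folds(ls, k = 3, seed = 4, group_by_tf = FALSE))
})

test_that("TF-grouped folds keep each TF's pairs together", {
  # nine TFs, one positive each, universe large enough for negatives
  edges <- edge_list(sprintf("T%d", 1:9), sprintf("G%02d", 1:9))
  ls <- build_label_set(edges, sprintf("T%d", 1:9), sprintf("G%02d", 1:20),
                        seed = 5)
  f <- make_folds(ls, k = 3, seed = 5, group_by_tf = TRUE)
  for (fd in f) {
    expect_length(unique(ls$tf[fd]), 3L)       # 3 TFs per fold
  }
  for (tf in unique(ls$tf)) {
    holds <- vapply(f, function(fd) any(ls$tf[fd] == tf), logical(1))
    expect_equal(sum(holds), 1L)
  }
  # fewer TFs than folds falls back with a warning
  ls2 <- build_label_set(toy_edges(), c("TF1", "TF2"), toy_hvgs(), seed = 1)
  expect_warning(make_folds(ls2, k = 3, seed = 1, group_by_tf = TRUE),
                 "falling back")
})

test_that("training rejects malformed index sets", {
  sep <- separable_stacks(8)
  expect_error(train_fold(sep$stacks, sep$labels, 1:5, 4:6),
               "overlap")
  expect_error(train_fold(sep$stacks, sep$labels, integer(), 1:2),
               "empty training")
  expect_error(train_fold(sep$stacks, sep$labels, 1:6, integer()),
               "validation")
})

test_that("early stopping fires after `patience` flat epochs", {
  sep <- separable_stacks(10)
  cfg <- training_config(batch_size = 8, max_epochs = 30, patience = 5,
                         learning_rate = 1e-9)  # nothing ever improves
  fit <- train_fold(sep$stacks, sep$labels, 1:8, 9:10,
                    tower_config("mini", dropout_rate = 0),
                    head_config("tiny", dropout_rate = 0), cfg, seed = 1)
  expect_lte(nrow(fit$history), 1 + 5)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training separates the separable fixture within 30 epochs", {
  sep <- separable_stacks(16)
  cfg <- training_config(batch_size = 8, max_epochs = 30, patience = 29,
                         learning_rate = 0.02, grad_clip = 5,
                         val_fraction = 0)
  fit <- train_fold(sep$stacks, sep$labels, seq_along(sep$stacks), NULL,
                    tower_config("mini", dropout_rate = 0.1),
                    head_config("tiny", dropout_rate = 0.1), cfg, seed = 1)
  expect_gte(max(fit$history$accuracy), 0.95)
  # training loss trends down (5-epoch moving average, SGD noise allowed)
  ma <- stats::filter(fit$history$loss, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
})

test_that("cross-validation is leak-free and deterministic", {
  sep <- separable_stacks(12, seed = 31)
  ls <- data.frame(tf = paste0("T", 1:12), target = paste0("G", 1:12),
                   label = sep$labels)
  class(ls) <- c("labeled_pairs", "data.frame")
  folds <- make_folds(ls, k = 3, seed = 6, group_by_tf = FALSE)
  cfg <- training_config(batch_size = 8, max_epochs = 3, patience = 2,
                         learning_rate = 0.02, val_fraction = 0)
  cv1 <- cross_validate(sep$stacks, sep$labels, folds,
                        tower_config("mini", dropout_rate = 0.1),
                        head_config("tiny", dropout_rate = 0.1), cfg,
                        seed = 9)
  cv2 <- cross_validate(sep$stacks, sep$labels, folds,
                        tower_config("mini", dropout_rate = 0.1),
                        head_config("tiny", dropout_rate = 0.1), cfg,
                        seed = 9)
  expect_identical(cv1$pooled$score, cv2$pooled$score)
  # every pair is scored exactly once, by the model of its own fold
  expect_setequal(which(cv1$pooled$fold == 1), folds[[1]])
  expect_setequal(which(cv1$pooled$fold == 2), folds[[2]])
  expect_setequal(which(cv1$pooled$fold == 3), folds[[3]])
  expect_equal(cv1$mean_accuracy, mean(cv1$fold_metrics$accuracy))
  expect_length(cv1$models, 3L)
})

test_that("label sets keep the global balance invariant", {
  set.seed(13)
  for (i in 1:5) {
    ds <- simulate_dataset(synthetic_spec(seed = i))
    pm <- suppressWarnings(preprocess_expression(ds$matrix))
    ls <- build_label_set(ds$truth, ds$tfs, pm$hvg_ids, seed = i)
    expect_lte(abs(mean(ls$label) - 0.5), 1 / nrow(ls))
  }
})
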