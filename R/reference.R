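# The package's reference small-scale configuration: one place that the
# test suite, the acceptance script and the documentation all draw from.

#' Reference small-scale pipeline configuration
#'
#' The configuration the package uses to demonstrate the method's mechanism
#' on the default [synthetic_spec()] fixture (60 genes, 4 TFs, 400 cells,
#' 3 neighbor images) within desk-scale compute: the `"mini"` tower and
#' `"tiny"` head at 10% dropout, mini-batch SGD (batch 8, learning rate
#' 0.02 with cosine decay, momentum 0.9, weight decay 1e-3, gradient-norm
#' clip 5) for a fixed 50-epoch budget with the last 17 epochs
#' weight-averaged, two cell-bootstrap training copies per pair, and plain
#' pair-level 3-fold splits. The methods vignette discusses how and why
#' each of these departs from the full-scale defaults.
#'
#' @return Named list of arguments understood by [grnimage()]: `tower`,
#'   `head`, `training`, `n_neighbors`, `augment`, `group_by_tf`.
#' @export
reference_configs <- function() {
  list(tower = tower_config("mini", dropout_rate = 0.1),
       head = head_config("tiny", dropout_rate = 0.1),
       training = training_config(batch_size = 8L, max_epochs = 50L,
                                  patience = 49L, learning_rate = 0.02,
                                  weight_decay = 0.001, grad_clip = 5,
                                  val_fraction = 0, lr_schedule = "cosine",
                                  tail_average = 17L),
       n_neighbors = 3L, augment = 2L, group_by_tf = FALSE)
}

#' Run the full pipeline under the reference configuration
#'
#' Convenience wrapper: [grnimage()] on a [simulate_dataset()] result (or
#' any list with `matrix`, `truth`, `tfs`) with [reference_configs()].
#'
#' @param dataset A `"synthetic_dataset"` or equivalent list.
#' @param seed Pipeline seed (negative sampling, folds, weights, SGD).
#' @param ... Overrides passed on to [grnimage()].
#' @return A [grnimage()] fit.
#' @export
reference_pipeline <- function(dataset, seed = 1L, ...) {
  cfg <- reference_configs()
  args <- c(list(expr = dataset$matrix, edges = dataset$truth,
                 tfs = dataset$tfs, seed = seed), cfg, list(...))
  args <- args[!duplicated(names(args))]
  suppressWarnings(do.call(grnimage, args))
}
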