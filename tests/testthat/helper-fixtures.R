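# Fixtures built in code, shared across the suite.

# Small count matrix with deterministic entries.
toy_counts <- function(genes = 6, cells = 5, seed = 7) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    m <- matrix(rpois(genes * cells, 3), genes, cells,
                dimnames = list(paste0("G", seq_len(genes)),
                                paste0("C", seq_len(cells))))
    expression_matrix(m)
  })
}

# Five-gene matrix whose covariance structure is checked against a directly
# computed covariance matrix in the neighbor-ranking tests.
five_gene_pm <- function() {
  vals <- rbind(
    A = c(0, 1, 2, 3, 4, 5, 6, 7),
    B = c(0, 1, 2, 3, 4, 5, 6, 7),        # identical to A
    C = c(7, 6, 5, 4, 3, 2, 1, 0),        # anti-correlated with A
    D = c(0, 2, 1, 3, 2, 4, 3, 5),        # positively related to A
    E = c(2, 2, 2, 2, 2, 2, 2, 2))        # constant
  structure(list(values = vals, gene_ids = rownames(vals),
                 cell_ids = paste0("c", 1:8), hvg_ids = rownames(vals),
                 size_factor = 1e4,
                 params = list(), manifest = "fixture"),
            class = "grn_preprocessed")
}

# Synthetic separable stacks: positive pairs carry diagonal-concentrated
# primary images, negatives uniform noise; context images are noise.
separable_stacks <- function(n_pairs = 16, n = 1, seed = 11) {
  set.seed(seed)
  labels <- rep_len(c(1L, 0L), n_pairs)
  stacks <- lapply(seq_len(n_pairs), function(i) {
    s <- 2L * n + 3L
    im <- array(runif(32 * 32 * s, 0, 0.2), c(32, 32, s))
    if (labels[i] == 1L) {
      d <- matrix(0, 32, 32)
      for (k in -2:2) {
        idx <- cbind(pmax(1, pmin(32, 1:32)), pmax(1, pmin(32, 1:32 + k)))
        d[idx] <- 1
      }
      im[, , 1] <- d * runif(1, 0.8, 1) + matrix(runif(1024, 0, 0.1), 32)
    }
    structure(list(pair = c(tf = paste0("T", i), target = paste0("G", i)),
                   n = as.integer(n), images = im, layout = NULL),
              class = "image_stack")
  })
  list(stacks = stacks, labels = labels)
}

# Edge fixture: 2 TFs with 3 and 5 targets inside a 12-gene universe.
toy_edges <- function() {
  edge_list(c(rep("TF1", 3), rep("TF2", 5)),
            c("G01", "G02", "G03", "G02", "G04", "G05", "G06", "G07"))
}

toy_hvgs <- function() sprintf("G%02d", 1:10)

# A fast-to-train reference dataset + configs scaled far down, for smoke
# and determinism tests (not for accuracy claims).
smoke_fit <- function(seed = 1, max_epochs = 4) {
  ds <- simulate_dataset(synthetic_spec())
  cfg <- training_config(batch_size = 8, max_epochs = max_epochs,
                         patience = max_epochs - 1, learning_rate = 0.02,
                         grad_clip = 5, val_fraction = 0)
  suppressWarnings(grnimage(
    ds$matrix, ds$truth, ds$tfs, n_neighbors = 2,
    tower = tower_config("mini", dropout_rate = 0.1),
    head = head_config("tiny", dropout_rate = 0.1),
    training = cfg, group_by_tf = FALSE, seed = seed))
}
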