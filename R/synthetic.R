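# Self-contained synthetic data: a single-cell-like count matrix with
# library-size variation and excess zeros, a planted directed TF -> target
# edge set including transitive chains (TF -> y -> z with no TF -> z edge),
# and the TF list. A multiplicative lognormal/Poisson/zero-inflation model is
# used rather than a published simulator: it is dependency-free and its
# planted covariance structure is analytically transparent.

#' Specification of a synthetic dataset
#'
#' Defaults are the package's reference study conditions: 60 genes, 400
#' cells, 4 TFs with 5 direct targets each and half of those targets driving
#' a second-hop gene, coupling strength 1.5.
#'
#' @param n_genes Total genes; must exceed the planted-structure gene count.
#' @param n_cells Number of cells.
#' @param n_tfs Number of transcription factors.
#' @param targets_per_tf Direct targets planted per TF.
#' @param chain_fraction Fraction of each TF's targets that additionally
#'   regulate a second-hop gene (planting x -> y -> z without x -> z).
#' @param coupling_strength Exponent coupling a regulator's activity to its
#'   target's rate; 0 removes all regulatory signal.
#' @param library_size_log_sd Log-scale SD of the per-cell library factor.
#' @param dropout_logit_slope Slope of the count-dependent zero-inflation:
#'   each count is zeroed with probability `plogis(-slope * log1p(count))`,
#'   so low counts drop out more often.
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 60L, n_cells = 400L, n_tfs = 4L,
                           targets_per_tf = 5L, chain_fraction = 0.5,
                           coupling_strength = 1.5,
                           library_size_log_sd = 0.3,
                           dropout_logit_slope = 1.5, seed = 1L) {
  check_scalar_num(coupling_strength, "coupling_strength", lower = 0)
  check_scalar_num(chain_fraction, "chain_fraction", lower = 0, upper = 1)
  check_scalar_num(library_size_log_sd, "library_size_log_sd", lower = 0)
  if (n_tfs >= n_genes) stop_grn("n_tfs must be below n_genes")
  n_chain_per_tf <- round(chain_fraction * targets_per_tf)
  need <- n_tfs + n_tfs * targets_per_tf + n_tfs * n_chain_per_tf
  if (need > n_genes) {
    stop_grn("planted structure needs %d genes but n_genes = %d",
             need, n_genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), n_tfs = as.integer(n_tfs),
                 targets_per_tf = as.integer(targets_per_tf),
                 chain_fraction = chain_fraction,
                 n_chain_per_tf = as.integer(n_chain_per_tf),
                 coupling_strength = coupling_strength,
                 library_size_log_sd = library_size_log_sd,
                 dropout_logit_slope = dropout_logit_slope,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset
#'
#' Generative model, all draws from the seeded generator:
#' 1. each TF has a latent per-cell activity `a ~ Lognormal(0, 1)`;
#' 2. a direct target's rate is `baseline * a^coupling_strength * noise`;
#'    a second-hop (chain) gene is driven by its parent target's relative
#'    rate the same way; independent genes are `baseline * noise`
#'    (`noise ~ Lognormal(0, 0.3)`, per-gene baselines lognormal);
#' 3. a per-cell library factor `~ Lognormal(0, library_size_log_sd)`
#'    scales all rates;
#' 4. counts are Poisson draws of the scaled rates;
#' 5. zero inflation: each count is independently zeroed with probability
#'    `plogis(-dropout_logit_slope * log1p(count))`, so low counts drop out
#'    preferentially.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `"synthetic_dataset"`: list with `matrix` (an
#'   [expression_matrix()] of counts), `truth` (direct edges: TF -> target
#'   and target -> chain), `second_hop` (the transitive TF -> chain pairs
#'   that are *not* edges), `tfs`, `spec`.
#' @export
simulate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    G <- spec$n_genes; C <- spec$n_cells
    tf_ids <- sprintf("TF%02d", seq_len(spec$n_tfs))
    other <- sprintf("G%03d", seq_len(G - spec$n_tfs))
    genes <- c(tf_ids, other)
    cells <- sprintf("C%04d", seq_len(C))
    # assign roles
    n_tgt <- spec$n_tfs * spec$targets_per_tf
    n_chn <- spec$n_tfs * spec$n_chain_per_tf
    tgt_ids <- other[seq_len(n_tgt)]
    chn_ids <- if (n_chn > 0) other[n_tgt + seq_len(n_chn)] else character()
    tgt_of <- rep(tf_ids, each = spec$targets_per_tf)
    # chain genes hang off the first n_chain_per_tf targets of each TF
    parent_of_chain <- unlist(lapply(seq_len(spec$n_tfs), function(i) {
      tgt_ids[(i - 1L) * spec$targets_per_tf + seq_len(spec$n_chain_per_tf)]
    }))
    tf_of_chain <- rep(tf_ids, each = spec$n_chain_per_tf)
    baseline <- stats::rlnorm(G, meanlog = log(0.8), sdlog = 0.8)
    names(baseline) <- genes
    noise_sd <- 0.3
    activity <- matrix(stats::rlnorm(spec$n_tfs * C, 0, 1), spec$n_tfs, C,
                       dimnames = list(tf_ids, NULL))
    rate <- matrix(0, G, C, dimnames = list(genes, cells))
    noise <- function() stats::rlnorm(C, 0, noise_sd)
    for (i in seq_len(spec$n_tfs)) {
      rate[tf_ids[i], ] <- baseline[tf_ids[i]] * activity[i, ] * noise()
    }
    for (j in seq_along(tgt_ids)) {
      a <- activity[tgt_of[j], ]
      rate[tgt_ids[j], ] <- baseline[tgt_ids[j]] *
        a^spec$coupling_strength * noise()
    }
    for (j in seq_along(chn_ids)) {
      parent_rel <- rate[parent_of_chain[j], ] / baseline[parent_of_chain[j]]
      rate[chn_ids[j], ] <- baseline[chn_ids[j]] *
        parent_rel^spec$coupling_strength * noise()
    }
    indep <- setdiff(genes, c(tf_ids, tgt_ids, chn_ids))
    for (g in indep) rate[g, ] <- baseline[g] * noise()
    lib <- stats::rlnorm(C, 0, spec$library_size_log_sd)
    counts <- matrix(stats::rpois(G * C, t(t(rate) * lib)), G, C,
                     dimnames = list(genes, cells))
    keep <- stats::runif(G * C) >=
      stats::plogis(-spec$dropout_logit_slope * log1p(counts))
    counts <- counts * keep
    truth <- edge_list(c(tgt_of, parent_of_chain), c(tgt_ids, chn_ids))
    second_hop <- if (length(chn_ids)) edge_list(tf_of_chain, chn_ids) else {
      edge_list(character(), character())
    }
    structure(list(matrix = expression_matrix(counts, genes, cells),
                   truth = truth, second_hop = second_hop, tfs = tf_ids,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic_dataset: %d genes x %d cells, %d TFs, %d true edges, %d second-hop pairs (%.1f%% zeros)\n",
    nrow(x$matrix$values), ncol(x$matrix$values), length(x$tfs),
    nrow(x$truth), nrow(x$second_hop), 100 * mean(x$matrix$values == 0)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits seven plain-text files: `matrix.mtx` with companion
#' `matrix_genes.txt` / `matrix_cells.txt`, `truth.tsv` and
#' `second_hop.tsv` edge lists, `tfs.txt`, and the generating spec as
#' `spec.json` (which reproduces the dataset exactly when re-run).
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::Matrix(ds$matrix$values, sparse = TRUE), mtx)
  writeLines(ds$matrix$gene_ids, file.path(dir, "matrix_genes.txt"))
  writeLines(ds$matrix$cell_ids, file.path(dir, "matrix_cells.txt"))
  write_edge_list(ds$truth, file.path(dir, "truth.tsv"))
  write_edge_list(ds$second_hop, file.path(dir, "second_hop.tsv"))
  writeLines(ds$tfs, file.path(dir, "tfs.txt"))
  jsonlite::write_json(unclass(ds$spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, c("matrix.mtx", "matrix_genes.txt",
                             "matrix_cells.txt", "truth.tsv",
                             "second_hop.tsv", "tfs.txt", "spec.json")))
}

#' Read a synthetic dataset written by [write_dataset()]
#' @param dir Directory containing the seven files.
#' @return A `"synthetic_dataset"` list (spec restored from JSON).
#' @export
read_dataset <- function(dir) {
  sp <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- do.call(synthetic_spec, sp[setdiff(names(sp), "n_chain_per_tf")])
  structure(list(matrix = read_expression(file.path(dir, "matrix.mtx")),
                 truth = read_edge_list(file.path(dir, "truth.tsv")),
                 second_hop = read_edge_list(file.path(dir, "second_hop.tsv")),
                 tfs = read_gene_list(file.path(dir, "tfs.txt")),
                 spec = spec),
            class = "synthetic_dataset")
}
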