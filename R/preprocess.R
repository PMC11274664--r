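# Preprocessing chain for raw counts: per-cell total-count normalization,
# log1p transform, highly-variable-gene selection, per-gene winsorization of
# the top values, and covariance-based neighbor ranking. The winsorized
# log-scale matrix is what every histogram image downstream sees.

#' Normalize counts per cell to a common total
#'
#' Scales every cell (column) so that its total across genes equals
#' `size_factor`. Columns whose total is zero carry no information and are
#' dropped with a warning.
#'
#' @param m Numeric genes x cells matrix (or an [expression_matrix()]).
#' @param size_factor Positive target column total; default `1e4`.
#' @return Numeric matrix with every column summing to `size_factor`.
#' @export
normalize_per_cell <- function(m, size_factor = 1e4) {
  check_scalar_num(size_factor, "size_factor", lower = 0, open_lower = TRUE)
  vals <- if (inherits(m, "expression_matrix")) m$values else as.matrix(m)
  if (any(vals < 0)) stop_grn("negative entries in count matrix")
  tot <- colSums(vals)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero cell(s)", sum(zero)), call. = FALSE)
    vals <- vals[, !zero, drop = FALSE]
    tot <- tot[!zero]
  }
  sweep(vals, 2L, tot / size_factor, "/")
}

#' Natural-log transform, log(1 + x)
#'
#' @param m Numeric matrix (or vector) of non-negative values.
#' @return `log1p(m)`.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) stop_grn("log_transform requires non-negative values")
  log1p(m)
}

#' Select highly variable genes
#'
#' Mean-binned normalized-dispersion criterion on a log-scale matrix: per
#' gene, the dispersion var/mean is computed on the de-logged values, genes
#' are cut into `n_bins` equal-width bins of mean expression, the dispersion
#' is z-scored within each bin, and the top `k` genes by z-score are
#' returned. Zero-variance genes are never selected. Ties are broken by
#' lexicographic gene id, so the selection is deterministic and invariant to
#' cell order.
#'
#' @param m Log-scale genes x cells matrix with gene ids as rownames.
#' @param k Number of genes to keep; default 500.
#' @param n_bins Number of mean-expression bins; default 20.
#' @return Character vector of `min(k, #genes with nonzero variance)` gene
#'   ids, ranked by decreasing normalized dispersion.
#' @export
select_hvgs <- function(m, k = 500, n_bins = 20) {
  check_scalar_num(k, "k", lower = 1)
  if (is.null(rownames(m))) stop_grn("matrix must carry gene ids as rownames")
  x <- expm1(m)
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1L)
  ok <- v > 0 & mu > 0
  if (!any(ok)) stop_grn("no gene has nonzero variance")
  if (k > sum(ok)) {
    warning(sprintf("requested %d HVGs but only %d genes have nonzero variance",
                    k, sum(ok)), call. = FALSE)
    k <- sum(ok)
  }
  disp <- v[ok] / mu[ok]
  mu_ok <- mu[ok]
  ids <- rownames(m)[ok]
  bins <- cut(mu_ok, breaks = n_bins, include.lowest = TRUE)
  z <- stats::ave(disp, bins, FUN = function(d) {
    s <- stats::sd(d)
    if (!is.finite(s) || s == 0) rep(0, length(d)) else (d - mean(d)) / s
  })
  ord <- order(-z, ids)
  ids[ord[seq_len(k)]]
}

#' Winsorize the top values of a vector
#'
#' The `ceiling(fraction * N)` largest entries (ties broken by position) are
#' all reset to the minimum among them; everything else is untouched, so the
#' result's maximum equals that minimum.
#'
#' @param values Numeric vector, length >= 1.
#' @param fraction Fraction in (0, 1); default 0.05.
#' @return The clipped vector.
#' @export
clip_top_values <- function(values, fraction = 0.05) {
  check_scalar_num(fraction, "fraction", lower = 0, upper = 1,
                   open_lower = TRUE, open_upper = TRUE)
  n <- length(values)
  if (n < 1L) stop_grn("empty vector")
  k <- ceiling(fraction * n)
  top <- order(values, decreasing = TRUE)[seq_len(k)]
  values[top] <- min(values[top])
  values
}

#' Preprocess a raw count matrix
#'
#' Runs the full chain: optional min-count filtering, per-cell normalization
#' to `size_factor`, log1p transform, HVG selection, and per-gene
#' winsorization of the top `clip_fraction` of values. The returned object
#' carries a manifest hash of all parameters; models trained on one manifest
#' refuse image stacks built under another.
#'
#' @param expr An [expression_matrix()] of raw counts.
#' @param size_factor Per-cell normalization target; default `1e4`.
#' @param hvg_count Number of highly variable genes to select; default 500.
#' @param clip_fraction Winsorization fraction per gene; default 0.05.
#' @param min_cells_per_gene,min_genes_per_cell Simple quality filters on the
#'   raw counts (minimum number of cells a gene is detected in / genes a cell
#'   expresses); defaults 0 (off).
#' @return An object of class `"grn_preprocessed"`: list with `values`
#'   (winsorized log-scale genes x cells matrix), `gene_ids`, `cell_ids`,
#'   `hvg_ids`, `size_factor`, `params`, `manifest`.
#' @export
preprocess_expression <- function(expr, size_factor = 1e4, hvg_count = 500,
                                  clip_fraction = 0.05,
                                  min_cells_per_gene = 0,
                                  min_genes_per_cell = 0) {
  if (!inherits(expr, "expression_matrix")) {
    expr <- expression_matrix(as.matrix(expr))
  }
  vals <- expr$values
  if (min_genes_per_cell > 0) {
    vals <- vals[, colSums(vals > 0) >= min_genes_per_cell, drop = FALSE]
  }
  if (min_cells_per_gene > 0) {
    vals <- vals[rowSums(vals > 0) >= min_cells_per_gene, , drop = FALSE]
  }
  if (!nrow(vals) || !ncol(vals)) stop_grn("no data left after filtering")
  norm <- normalize_per_cell(vals, size_factor)
  lg <- log_transform(norm)
  hvg <- select_hvgs(lg, k = hvg_count)
  clipped <- t(apply(lg, 1L, clip_top_values, fraction = clip_fraction))
  dimnames(clipped) <- dimnames(lg)
  params <- list(size_factor = size_factor, hvg_count = hvg_count,
                 clip_fraction = clip_fraction,
                 min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 log_base = "natural", nbins = 32L)
  structure(list(values = clipped,
                 gene_ids = rownames(clipped),
                 cell_ids = colnames(clipped),
                 hvg_ids = hvg,
                 size_factor = size_factor,
                 params = params,
                 manifest = manifest_hash(params)),
            class = "grn_preprocessed")
}

#' @export
print.grn_preprocessed <- function(x, ...) {
  cat(sprintf("grn_preprocessed: %d genes x %d cells, %d HVGs, manifest %s\n",
              nrow(x$values), ncol(x$values), length(x$hvg_ids),
              substr(x$manifest, 1, 8)))
  invisible(x)
}

#' Rank a gene's positive-covariance neighbors
#'
#' Computes the sample covariance (denominator N-1) between the query gene
#' and every other candidate gene on the preprocessed (log-scale, winsorized)
#' values, keeps the strictly positive covariances, and returns the top `n`
#' in decreasing order. Ties are broken by lexicographic gene id. If fewer
#' than `n` genes have positive covariance, the shorter list is returned with
#' a warning.
#'
#' @param pm A [preprocess_expression()] result.
#' @param gene Query gene id (case-insensitive).
#' @param n Maximum number of neighbors.
#' @param within Candidate gene ids; defaults to the HVG set. The query gene
#'   never appears in its own list.
#' @param warn Warn when fewer than `n` positive-covariance neighbors exist.
#' @return List with `gene_id` and `neighbors`, a data.frame of `gene_id`,
#'   `covariance` sorted by decreasing covariance.
#' @export
rank_neighbors <- function(pm, gene, n, within = NULL, warn = TRUE) {
  check_scalar_num(n, "n", lower = 0)
  gi <- match_ids(gene, pm$gene_ids)
  if (is.na(gi)) stop_grn("unknown gene id: %s", gene)
  within <- within %||% pm$hvg_ids
  wi <- match_ids(within, pm$gene_ids)
  if (anyNA(wi)) {
    stop_grn("candidate ids not in matrix: %s",
             paste(within[is.na(wi)], collapse = ", "))
  }
  wi <- setdiff(unique(wi), gi)
  x <- pm$values[gi, ]
  xc <- x - mean(x)
  nm <- length(x)
  cand <- pm$values[wi, , drop = FALSE]
  cv <- as.vector((cand - rowMeans(cand)) %*% xc) / (nm - 1L)
  ids <- pm$gene_ids[wi]
  pos <- cv > 0
  ids <- ids[pos]; cv <- cv[pos]
  ord <- order(-cv, ids)
  take <- seq_len(min(n, length(ord)))
  if (warn && length(ord) < n) {
    warning(sprintf("gene %s has only %d positive-covariance neighbors (requested %d)",
                    gene, length(ord), n), call. = FALSE)
  }
  list(gene_id = pm$gene_ids[gi],
       neighbors = data.frame(gene_id = ids[ord[take]],
                              covariance = cv[ord[take]],
                              stringsAsFactors = FALSE))
}
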