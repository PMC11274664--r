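# Image encoding of gene pairs: per-gene equal-width bin edges, 32x32 joint
# histograms of cell counts, log-normalization of the bin values, and
# assembly of the fixed-layout image stack (primary, two self-images, 2n
# neighbor images) that the classifier consumes.

#' Equal-width histogram bin edges for one gene
#'
#' Edges span the per-gene value range `[min, max]` divided into `nbins`
#' equal-width bins. A constant vector gets a degenerate span of width 1
#' centered on the value so that all mass falls into a single bin.
#'
#' @param values Non-empty finite numeric vector.
#' @param nbins Number of bins; default 32.
#' @return Numeric vector of `nbins + 1` strictly ascending edges.
#' @export
bin_edges <- function(values, nbins = 32) {
  if (!length(values)) stop_grn("empty value vector")
  if (any(!is.finite(values))) stop_grn("non-finite values")
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  seq(lo, hi, length.out = nbins + 1L)
}

#' Joint histogram of two genes over cells
#'
#' Bin value `[i, j]` counts the cells whose expression of the x-gene falls
#' in x-bin `i` and of the y-gene in y-bin `j`. Bins are half-open
#' `[e_i, e_{i+1})` with the last bin closed on the right, so the total mass
#' always equals the number of cells.
#'
#' @param x_vals,y_vals Cell-aligned numeric vectors of equal length.
#' @param x_edges,y_edges Ascending bin edges from [bin_edges()].
#' @return Integer matrix of dimension `(length(x_edges)-1) x
#'   (length(y_edges)-1)`; rows index x bins.
#' @export
joint_histogram <- function(x_vals, y_vals, x_edges, y_edges) {
  if (length(x_vals) != length(y_vals)) {
    stop_grn("x and y value vectors differ in length")
  }
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  ix <- findInterval(x_vals, x_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(y_vals, y_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  matrix(tabulate((iy - 1L) * nx + ix, nbins = nx * ny), nrow = nx, ncol = ny)
}

#' Log-normalize a joint histogram
#'
#' Applies `log10(1 + 10 * H_ij / sum(H))` to every bin, mapping counts to
#' the bounded range `[0, log10(11)]` while preserving order. Zero bins stay
#' zero.
#'
#' @param counts Non-negative count matrix with positive total.
#' @return Numeric matrix of the same shape.
#' @export
lognorm_histogram <- function(counts) {
  s <- sum(counts)
  if (!is.finite(s) || s <= 0) stop_grn("histogram has no mass")
  if (any(counts < 0)) stop_grn("negative histogram counts")
  log10(1 + 10 * counts / s)
}

# Per-gene bin edges computed once per preprocessed matrix and memoized, so a
# gene's axis is identical across every image that uses it.
gene_edges <- function(pm, gene_idx, cache = NULL, nbins = 32) {
  key <- as.character(gene_idx)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  e <- bin_edges(pm$values[gene_idx, ], nbins)
  if (!is.null(cache)) cache[[key]] <- e
  e
}

# `cells`: optional column subset the histogram is accumulated over; bin
# edges always come from all cells so the axes stay comparable.
pair_image <- function(pm, xi, yi, cache = NULL, nbins = 32, cells = NULL) {
  xe <- gene_edges(pm, xi, cache, nbins)
  ye <- gene_edges(pm, yi, cache, nbins)
  xv <- pm$values[xi, ]; yv <- pm$values[yi, ]
  if (!is.null(cells)) { xv <- xv[cells]; yv <- yv[cells] }
  lognorm_histogram(joint_histogram(xv, yv, xe, ye))
}

#' Build the image stack for a candidate TF -> gene pair
#'
#' Produces the `2n + 3` log-normalized 32x32 images the classifier scores,
#' in the frozen layout order: primary image `(tf, target)`, self-image
#' `(tf, tf)`, self-image `(target, target)`, then the `n` neighbor images of
#' the TF and the `n` neighbor images of the target, each by descending
#' positive covariance with the queried gene on the x-axis. Genes with fewer
#' than `n` positive-covariance neighbors have the missing slots filled with
#' all-zero images, flagged in the layout table.
#'
#' @param tf_gene,target_gene Gene ids present in `pm`.
#' @param pm A [preprocess_expression()] result.
#' @param n Number of neighbor images per gene.
#' @param rankings Optional list of two [rank_neighbors()] results (for the
#'   TF and the target); computed on demand if `NULL`.
#' @param within Candidate set for neighbor ranking; defaults to the HVG set.
#' @param cache Optional environment memoizing per-gene bin edges across
#'   stacks.
#' @return Object of class `"image_stack"`: list with `pair`, `n`, `images`
#'   (32 x 32 x (2n+3) array) and `layout` (data.frame of slot roles, genes
#'   and padding flags).
#' @export
build_image_stack <- function(tf_gene, target_gene, pm, n, rankings = NULL,
                              within = NULL, cache = NULL, cells = NULL) {
  check_scalar_num(n, "n", lower = 0)
  xi <- match_ids(tf_gene, pm$gene_ids)
  yi <- match_ids(target_gene, pm$gene_ids)
  if (is.na(xi)) stop_grn("unknown gene id: %s", tf_gene)
  if (is.na(yi)) stop_grn("unknown gene id: %s", target_gene)
  nbins <- 32L
  if (is.null(rankings)) {
    rankings <- list(rank_neighbors(pm, tf_gene, n, within, warn = FALSE),
                     rank_neighbors(pm, target_gene, n, within, warn = FALSE))
  }
  s <- 2L * n + 3L
  images <- array(0, dim = c(nbins, nbins, s))
  layout <- data.frame(slot = seq_len(s),
                       role = c("primary", "self_x", "self_y",
                                rep("neighbor_x", n), rep("neighbor_y", n)),
                       x_gene = NA_character_, y_gene = NA_character_,
                       padded = FALSE, stringsAsFactors = FALSE)
  put <- function(slot, a, b) {
    images[, , slot] <<- pair_image(pm, a, b, cache, nbins, cells)
    layout$x_gene[slot] <<- pm$gene_ids[a]
    layout$y_gene[slot] <<- pm$gene_ids[b]
  }
  put(1L, xi, yi)
  put(2L, xi, xi)
  put(3L, yi, yi)
  fill_block <- function(offset, qi, ranking) {
    nb <- ranking$neighbors$gene_id
    for (j in seq_len(n)) {
      slot <- offset + j
      if (j <= length(nb)) {
        put(slot, qi, match_ids(nb[j], pm$gene_ids))
      } else {
        layout$padded[slot] <<- TRUE
        layout$x_gene[slot] <<- pm$gene_ids[qi]
      }
    }
  }
  fill_block(3L, xi, rankings[[1L]])
  fill_block(3L + n, yi, rankings[[2L]])
  structure(list(pair = c(tf = pm$gene_ids[xi], target = pm$gene_ids[yi]),
                 n = as.integer(n), images = images, layout = layout),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack %s -> %s: %d images (n = %d, %d padded)\n",
              x$pair[["tf"]], x$pair[["target"]], dim(x$images)[3L], x$n,
              sum(x$layout$padded)))
  invisible(x)
}

# Build the stacks for a table of (tf, target) pairs, sharing neighbor
# rankings and bin-edge computations. Returns a list of image_stack objects.
build_stacks <- function(pairs, pm, n, within = NULL, cells = NULL) {
  cache <- new.env(parent = emptyenv())
  genes <- unique(c(pairs$tf, pairs$target))
  rk <- lapply(genes, function(g) rank_neighbors(pm, g, n, within,
                                                 warn = FALSE))
  names(rk) <- toupper(genes)
  lapply(seq_len(nrow(pairs)), function(i) {
    build_image_stack(pairs$tf[i], pairs$target[i], pm, n,
                      rankings = list(rk[[toupper(pairs$tf[i])]],
                                      rk[[toupper(pairs$target[i])]]),
                      within = within, cache = cache, cells = cells)
  })
}
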