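# Readers/writers for the plain-text formats the pipeline touches:
# expression matrices (MatrixMarket triplet or dense delimited text),
# directed edge lists, TF lists and prediction tables. No numerics here.

#' Construct an expression matrix
#'
#' Bundles a non-negative genes x cells matrix with its gene and cell
#' identifiers and validates the invariants every downstream step relies on:
#' no negative entries, dimensions matching the identifier vectors, and gene
#' identifiers that are unique after case-normalization (identifier matching
#' throughout the package is case-insensitive).
#'
#' @param values Numeric matrix, genes in rows, cells in columns.
#' @param gene_ids Character vector of row identifiers.
#' @param cell_ids Character vector of column identifiers.
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop_grn("gene and cell identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop_grn("%d gene ids for %d rows", length(gene_ids), nrow(values))
  }
  if (length(cell_ids) != ncol(values)) {
    stop_grn("%d cell ids for %d columns", length(cell_ids), ncol(values))
  }
  if (anyNA(values) || any(values < 0)) {
    stop_grn("expression values must be non-negative and non-missing")
  }
  dup <- unique(gene_ids[duplicated(toupper(gene_ids))])
  if (length(dup)) {
    stop_grn("duplicate gene ids (case-insensitive): %s",
             paste(dup, collapse = ", "))
  }
  if (any(!nzchar(gene_ids)) || any(!nzchar(cell_ids))) {
    stop_grn("empty identifiers are not allowed")
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells (%.1f%% zeros)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$values == 0)))
  invisible(x)
}

#' Read an expression matrix from disk
#'
#' Reads either a MatrixMarket triplet file (with companion one-column text
#' files of gene and cell names) or a dense delimited text file whose header
#' row holds cell ids and whose first column holds gene ids. Orientation is
#' normalized to genes x cells; `transpose = TRUE` handles cells-in-rows
#' dumps.
#'
#' @param path Path to the `.mtx` or delimited text file.
#' @param format One of `"auto"`, `"mtx"`, `"csv"`, `"tsv"`. `"auto"` keys on
#'   the file extension.
#' @param genes_file,cells_file Companion name files for MatrixMarket input.
#'   Default to `<stem>_genes.txt` / `<stem>_cells.txt` next to `path`.
#' @param transpose If `TRUE` the file stores cells in rows.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                            genes_file = NULL, cells_file = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_grn("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop_grn("cannot infer format from extension '.%s'", ext))
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, "_genes.txt")
    cells_file <- cells_file %||% paste0(stem, "_cells.txt")
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) stop_grn("companion name file not found: %s", f)
    }
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop_grn("malformed MatrixMarket file %s: %s",
                                               path, conditionMessage(e)))
    vals <- as.matrix(m)
    gene_ids <- readLines(genes_file)
    cell_ids <- readLines(cells_file)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        row.names = NULL, stringsAsFactors = FALSE,
                        comment.char = ""),
      error = function(e) stop_grn("parse error in %s: %s", path,
                                   conditionMessage(e)))
    if (ncol(df) < 2L) stop_grn("%s: expected id column plus data columns", path)
    gene_ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
      stop_grn("parse error in %s: non-numeric entries in column %d",
               path, bad + 1L)
    }
    cell_ids <- colnames(df)[-1L]
  }
  if (transpose) {
    vals <- t(vals)
    tmp <- gene_ids; gene_ids <- cell_ids; cell_ids <- tmp
  }
  expression_matrix(vals, gene_ids, cell_ids)
}

#' Read a directed TF -> target edge list
#'
#' Two-column TSV, optional header (detected when the first line is
#' `tf<TAB>target`). Duplicate directed pairs are dropped, keeping the first
#' occurrence; direction is significant, so `(A,B)` and `(B,A)` are distinct.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `tf`, `target` (class `"edge_list"`).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_grn("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(edge_list(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop_grn("parse error in %s: line %d has %d field(s), expected 2",
             path, which(nf != 2L)[1L], nf[nf != 2L][1L])
  }
  tf <- vapply(fields, `[[`, character(1L), 1L)
  target <- vapply(fields, `[[`, character(1L), 2L)
  if (tolower(tf[1L]) %in% c("tf", "source") &&
      tolower(target[1L]) %in% c("target", "gene")) {
    tf <- tf[-1L]; target <- target[-1L]
  }
  edge_list(tf, target)
}

#' Construct a directed edge list
#'
#' @param tf,target Character vectors of equal length.
#' @return De-duplicated data.frame with columns `tf`, `target`, preserving
#'   first-occurrence order; class `"edge_list"`.
#' @export
edge_list <- function(tf, target) {
  tf <- as.character(tf); target <- as.character(target)
  if (length(tf) != length(target)) stop_grn("tf/target length mismatch")
  if (any(!nzchar(tf)) || any(!nzchar(target))) {
    stop_grn("edge list contains empty identifiers")
  }
  keep <- !duplicated(paste(tf, target, sep = "\r"))
  df <- data.frame(tf = tf[keep], target = target[keep],
                   stringsAsFactors = FALSE)
  class(df) <- c("edge_list", "data.frame")
  df
}

#' Write an edge list as TSV (with header `tf<TAB>target`)
#' @param edges An [edge_list()].
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(as.data.frame(edges)[, c("tf", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table
#'
#' Emits a TSV with header `tf`/`target`/`score`, scores printed with six
#' decimals. Optionally also writes a SIF file (`tf regulates target`) for
#' network viewers.
#'
#' @param table Data.frame with columns `tf`, `target`, `score` in \[0, 1\].
#' @param path Output TSV path.
#' @param sif_path Optional SIF output path.
#' @export
write_predictions <- function(table, path, sif_path = NULL) {
  table <- validate_predictions(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("tf\ttarget\tscore", con)
  if (nrow(table)) {
    writeLines(sprintf("%s\t%s\t%.6f", table$tf, table$target, table$score),
               con)
  }
  if (!is.null(sif_path)) {
    writeLines(sprintf("%s\tregulates\t%s", table$tf, table$target), sif_path)
  }
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#' @param path TSV path.
#' @return Data.frame with columns `tf`, `target`, `score`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_predictions(df)
}

validate_predictions <- function(table) {
  table <- as.data.frame(table)
  need <- c("tf", "target", "score")
  if (!all(need %in% names(table))) {
    stop_grn("prediction table needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(table)) {
    if (any(table$score < 0 | table$score > 1 | !is.finite(table$score))) {
      stop_grn("scores must lie in [0, 1]")
    }
    if (anyDuplicated(paste(table$tf, table$target, sep = "\r"))) {
      stop_grn("duplicate (tf, target) rows in prediction table")
    }
  }
  table[, need]
}

#' Read a one-column list of gene identifiers
#' @param path Text file, one id per line; blank lines ignored.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_grn("file not found: %s", path)
  ids <- readLines(path)
  ids[nzchar(ids)]
}

# Case-insensitive id matching (the join rule used across modules).
# Returns indices of `ids` in `universe`, NA where unmatched.
match_ids <- function(ids, universe) {
  match(toupper(ids), toupper(universe))
}
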