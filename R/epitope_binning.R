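#' Percentage inhibition from a competition fluorescence matrix
#'
#' `PI[i, j] = 100 * (1 - F[i, j] / F_iso[j])`: the percentage reduction of
#' labeled antibody `j`'s fluorescence after pre-blocking with unlabeled
#' antibody `i`, relative to its fluorescence after an isotype-control
#' pre-block. Values are reported raw (they can be negative when blocking
#' enhances binding); flooring at 0 happens at binning time.
#'
#' @param F n x n fluorescence matrix (rows: blocking antibody, columns:
#'   labeled antibody), with antibody IDs as dimnames.
#' @param F_iso length-n fluorescence of each labeled antibody after
#'   isotype-control pre-block; all entries must be positive.
#' @return n x n percent-inhibition matrix.
#' @export
percent_inhibition <- function(F, F_iso) {
  if (!is.matrix(F) || nrow(F) != ncol(F))
    stop_input("F must be a square matrix")
  if (length(F_iso) != ncol(F))
    stop_input("F_iso length must match the matrix dimension")
  if (any(F < 0) || any(F_iso < 0)) stop_input("fluorescence must be >= 0")
  zero <- which(F_iso == 0)
  if (length(zero)) {
    ids <- if (!is.null(colnames(F))) colnames(F)[zero] else zero
    stop_input("isotype-control fluorescence is zero for antibody: ",
               paste(ids, collapse = ", "))
  }
  pi_mat <- 100 * (1 - sweep(F, 2, F_iso, "/"))
  dimnames(pi_mat) <- dimnames(F)
  pi_mat
}

#' Partition antibodies into epitope bins from percent inhibition
#'
#' Builds the competition graph with an undirected edge between two
#' antibodies when the larger of their two directed percent-inhibition
#' values reaches `threshold` (`rule = "min"` requires both directions),
#' and returns its connected components as the epitope bins. The full
#' directed edge list is retained so asymmetric competition remains
#' visible. Antibodies whose self-competition falls below threshold are
#' reported.
#'
#' @param pi_mat square percent-inhibition matrix with ID dimnames.
#' @param threshold percent cutoff in `(0, 100]`.
#' @param rule symmetrisation of the directed pair before thresholding.
#' @return object of class `epitope_bins`: `bins` (list of ID vectors),
#'   `edges` (directed data.frame from/to/percent_inhibition), `threshold`,
#'   `low_self` (IDs with self-PI below threshold),
#'   `percent_inhibition` (input matrix, negatives floored at 0).
#' @export
bin_epitopes <- function(pi_mat, threshold = 50, rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (threshold <= 0 || threshold > 100)
    stop_input("threshold must lie in (0, 100]")
  if (!is.matrix(pi_mat) || nrow(pi_mat) != ncol(pi_mat))
    stop_input("percent-inhibition matrix must be square")
  n <- nrow(pi_mat)
  ids <- colnames(pi_mat)
  if (is.null(ids)) ids <- paste0("mab", seq_len(n))
  if (any(pi_mat > 100 + 1e-9)) stop_input("percent inhibition exceeds 100")
  floored <- pmax(pi_mat, 0)
  sym <- if (rule == "max") pmax(floored, t(floored)) else
    pmin(floored, t(floored))
  adj <- sym >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  bins <- unname(split(ids, comp))
  bins <- bins[order(vapply(bins, min, ""))]
  edges <- which(floored >= threshold & row(floored) != col(floored),
                 arr.ind = TRUE)
  edge_df <- data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                        percent_inhibition = pi_mat[edges],
                        stringsAsFactors = FALSE)
  edge_df <- edge_df[order(edge_df$from, edge_df$to), ]
  rownames(edge_df) <- NULL
  structure(list(bins = bins, edges = edge_df, threshold = threshold,
                 rule = rule, low_self = ids[diag(pi_mat) < threshold],
                 percent_inhibition = floored),
            class = "epitope_bins")
}

#' @export
print.epitope_bins <- function(x, ...) {
  cat("Epitope bins (threshold ", x$threshold, "% inhibition, rule ",
      x$rule, "):\n", sep = "")
  for (i in seq_along(x$bins))
    cat("  bin ", i, ": ", paste(x$bins[[i]], collapse = ", "), "\n",
        sep = "")
  if (length(x$low_self))
    cat("  self-competition below threshold:",
        paste(x$low_self, collapse = ", "), "\n")
  invisible(x)
}

#' Read a competition fluorescence CSV
#'
#' Expected layout: a header row of antibody IDs, one row per blocking
#' antibody, plus a final `isotype` row holding the isotype-control
#' fluorescence of each labeled antibody.
#'
#' @param path CSV path.
#' @return list with `F` (square matrix) and `F_iso` (named vector).
#' @export
read_competition_csv <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  if (!"isotype" %in% rownames(raw))
    stop_input("competition CSV lacks an 'isotype' row")
  iso <- as.numeric(raw["isotype", ])
  F <- as.matrix(raw[setdiff(rownames(raw), "isotype"), , drop = FALSE])
  if (nrow(F) != ncol(F) || !all(rownames(F) == colnames(F)))
    stop_input("competition CSV row/column antibody IDs must match")
  list(F = F, F_iso = setNames(iso, colnames(F)))
}
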