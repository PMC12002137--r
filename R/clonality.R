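#' Partition annotated sequences into clones
#'
#' Two sequences are clonally related when they use the same V gene and J
#' gene (allele suffixes ignored), have junctions of equal length, and
#' their junction nucleotide identity is at least `threshold`; clones are
#' the connected components of that similarity graph (single-linkage
#' closure). Sequences without both V and J calls are excluded and
#' reported.
#'
#' @param annotations an AIRR-style data.frame (from [airr_table()]) or a
#'   list of `bcr_annotation` objects.
#' @param threshold normalized junction similarity cutoff in `[0, 1]`.
#' @return object of class `clone_set`: `assignments` (named character
#'   vector sequence_id -> clone label), `threshold`, `excluded`
#'   (sequence IDs without V/J calls).
#' @export
partition_clones <- function(annotations, threshold = 0.85) {
  if (threshold < 0 || threshold > 1)
    stop_input("threshold must lie in [0, 1]")
  df <- if (is.data.frame(annotations)) annotations else
    airr_table(annotations)
  need <- c("sequence_id", "v_call", "j_call", "junction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_input("annotations lack column(s): ",
               paste(missing_cols, collapse = ", "))
  ok <- !is.na(df$v_call) & !is.na(df$j_call) & !is.na(df$junction)
  excluded <- df$sequence_id[!ok]
  df <- df[ok, , drop = FALSE]
  if (!nrow(df))
    return(structure(list(assignments = setNames(character(0),
                                                 character(0)),
                          threshold = threshold, excluded = excluded),
                     class = "clone_set"))

  key <- paste(gene_of(df$v_call), gene_of(df$j_call),
               nchar(df$junction), sep = "|")
  labels <- rep(NA_character_, nrow(df))
  clone_no <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      clone_no <- clone_no + 1L
      labels[idx] <- sprintf("clone_%04d", clone_no)
      next
    }
    jx <- df$junction[idx]
    m <- do.call(rbind, strsplit(jx, ""))
    n <- length(idx)
    edges <- matrix(integer(0), ncol = 2)
    for (i in seq_len(n - 1L)) {
      same <- rowMeans(m[(i + 1L):n, , drop = FALSE] ==
                         matrix(m[i, ], nrow = n - i, ncol = ncol(m),
                                byrow = TRUE))
      hit <- which(same >= threshold)
      if (length(hit))
        edges <- rbind(edges, cbind(i, i + hit))
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      clone_no <- clone_no + 1L
      labels[idx[comp == cc]] <- sprintf("clone_%04d", clone_no)
    }
  }
  structure(list(assignments = setNames(labels, df$sequence_id),
                 threshold = threshold, excluded = excluded),
            class = "clone_set")
}

#' @export
print.clone_set <- function(x, ...) {
  sizes <- table(x$assignments)
  cat("Clone partition:", length(x$assignments), "sequences in",
      length(sizes), "clones (threshold", x$threshold, ")\n")
  if (length(x$excluded))
    cat("  excluded (no V/J call):", length(x$excluded), "\n")
  invisible(x)
}

#' Summarise a clone partition
#'
#' @param cs a `clone_set`.
#' @return data.frame (clone label, size, comma-separated members), largest
#'   clones first; sizes sum to the number of assigned sequences.
#' @export
clone_summary <- function(cs) {
  stopifnot(inherits(cs, "clone_set"))
  ids <- names(cs$assignments)
  split_ids <- split(ids, cs$assignments)
  split_ids <- lapply(split_ids, sort)
  df <- data.frame(clone_id = names(split_ids),
                   size = lengths(split_ids),
                   members = vapply(split_ids, paste, "", collapse = ","),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$clone_id), ]
  rownames(df) <- NULL
  df
}
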