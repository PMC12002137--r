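#' Read a nucleotide FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] with the package's
#' validation rules: duplicate record IDs are an error and lowercase bases
#' are normalised to uppercase with a warning.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_input("duplicate sequence ID(s) in ", path, ": ",
               paste(dup, collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase bases in ", path, " normalised to uppercase",
            call. = FALSE)
    seqs <- toupper(seqs)
  }
  setNames(seqs, ids)
}

#' Write a nucleotide FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop_input("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

AIRR_REQUIRED <- c("sequence_id", "sequence", "locus", "v_call", "d_call",
                   "j_call", "junction", "junction_aa", "cdr3_aa",
                   "v_identity", "productive", "mutation_count", "clone_id")

#' Read an AIRR Rearrangement TSV
#'
#' Leading `#` comment lines (used to echo the germline reference version
#' tag) are skipped. Required columns missing from the header and duplicate
#' sequence IDs are errors.
#'
#' @param path TSV path.
#' @param required columns that must be present.
#' @return data.frame; the reference version tag (if present) is attached as
#'   attribute `version_tag`.
#' @export
read_airr <- function(path, required = AIRR_REQUIRED) {
  if (!file.exists(path)) stop_input("AIRR TSV not found: ", path)
  lines <- readLines(path)
  comments <- grep("^#", lines)
  tag <- NA_character_
  if (length(comments)) {
    m <- regmatches(lines[comments],
                    regexpr("(?<=version_tag=).*", lines[comments],
                            perl = TRUE))
    if (length(m)) tag <- m[1]
    lines <- lines[-comments]
  }
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_input("AIRR TSV ", path, " lacks required column(s): ",
               paste(missing_cols, collapse = ", "))
  dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
  if (length(dup))
    stop_input("duplicate sequence_id(s) in ", path, ": ",
               paste(dup, collapse = ", "))
  attr(df, "version_tag") <- tag
  df
}

#' Write an AIRR Rearrangement TSV
#'
#' @param df annotation data.frame.
#' @param path output path.
#' @param version_tag germline reference tag echoed as a leading comment
#'   line; `NULL` suppresses it.
#' @export
write_airr <- function(df, path, version_tag = NULL) {
  dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
  if (length(dup))
    stop_input("duplicate sequence_id(s): ", paste(dup, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(version_tag))
    writeLines(paste0("# version_tag=", version_tag), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
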