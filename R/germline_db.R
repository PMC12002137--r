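#' Germline immunoglobulin segment databases
#'
#' A germline database holds the V, D and J gene segments the annotator and
#' the repertoire simulator draw from. Each segment carries its locus (IGH,
#' IGK or IGL), its type (V, D or J), the nucleotide sequence, the 0-based
#' start position of the conserved CDR3 anchor codon (the 2nd-CYS for V
#' segments, the J-TRP/J-PHE for J segments; D segments have none) and, for V
#' and J, the codon reading-frame offset at the start of the sequence.
#' Coordinates are 0-based, half-open throughout the package.
#'
#' @param segments data.frame with columns `name`, `locus`, `segment_type`,
#'   `sequence`, `anchor`, `reading_frame`. `anchor`/`reading_frame` are `NA`
#'   for D segments.
#' @param version_tag free-form string recorded in downstream outputs.
#' @return An object of class `germline_db`.
#' @export
germline_db <- function(segments, version_tag = "unversioned") {
  required <- c("name", "locus", "segment_type", "sequence", "anchor",
                "reading_frame")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols))
    stop_input("germline segment table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  segments <- segments[, required]
  segments$name <- as.character(segments$name)
  segments$locus <- as.character(segments$locus)
  segments$segment_type <- as.character(segments$segment_type)
  segments$sequence <- toupper(as.character(segments$sequence))
  segments$anchor <- as.integer(segments$anchor)
  segments$reading_frame <- as.integer(segments$reading_frame)
  db <- structure(list(segments = segments,
                       version_tag = as.character(version_tag)[1]),
                  class = "germline_db")
  viol <- validate_germline_db(db)
  if (length(viol))
    stop_input("invalid germline database:\n  ",
               paste(viol, collapse = "\n  "))
  db
}

#' Validate a germline database
#'
#' Checks every structural invariant and returns a character vector of
#' violation messages (empty when the database is valid). Unlike
#' [germline_db()], this never throws, so it can be used to inspect
#' hand-built or damaged objects.
#'
#' Invariants checked: sequences are non-empty uppercase ACGT; V anchors fall
#' inside the sequence and are congruent to the reading frame mod 3; V anchor
#' codons translate to Cys and J anchor codons to Trp or Phe; J anchors leave
#' a complete codon; D segments carry no anchor; kappa/lambda loci carry no D
#' segments; names are unique; every locus present has at least one V and
#' one J.
#'
#' @param db a `germline_db` (or structurally similar list).
#' @return character vector of violations, `character(0)` if valid.
#' @export
validate_germline_db <- function(db) {
  seg <- db$segments
  out <- character(0)
  note <- function(...) out <<- c(out, paste0(...))

  dup <- unique(seg$name[duplicated(seg$name)])
  for (d in dup) note("duplicate segment name: ", d)

  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    id <- s$name
    if (!s$locus %in% c("IGH", "IGK", "IGL"))
      note(id, ": unknown locus ", s$locus)
    if (!s$segment_type %in% c("V", "D", "J"))
      note(id, ": unknown segment_type ", s$segment_type)
    n <- nchar(s$sequence)
    if (n == 0L) { note(id, ": empty sequence"); next }
    if (grepl("[^ACGT]", s$sequence))
      note(id, ": sequence contains non-ACGT characters")
    if (s$segment_type == "D") {
      if (!is.na(s$anchor)) note(id, ": D segment must not carry an anchor")
      if (s$locus != "IGH") note(id, ": D segment on light-chain locus ",
                                 s$locus)
      next
    }
    if (is.na(s$anchor) || is.na(s$reading_frame)) {
      note(id, ": V/J segment requires anchor and reading_frame")
      next
    }
    if (s$reading_frame < 0L || s$reading_frame > 2L)
      note(id, ": reading_frame outside 0-2")
    if (s$segment_type == "V") {
      if (s$anchor >= n) note(id, ": V anchor beyond sequence end")
      if ((s$anchor %% 3L) != s$reading_frame)
        note(id, ": V anchor not congruent to reading_frame mod 3")
    }
    if (s$anchor + 3L > n)
      note(id, ": anchor codon extends past sequence end")
    else {
      codon <- substr(s$sequence, s$anchor + 1L, s$anchor + 3L)
      aa <- unname(Biostrings::GENETIC_CODE[codon])
      if (s$segment_type == "V" && !identical(aa, "C"))
        note(id, ": V anchor codon ", codon, " translates to ", aa,
             ", expected C")
      if (s$segment_type == "J" && !aa %in% c("W", "F"))
        note(id, ": J anchor codon ", codon, " translates to ", aa,
             ", expected W or F")
    }
  }
  for (loc in unique(seg$locus)) {
    types <- seg$segment_type[seg$locus == loc]
    if (!"V" %in% types) note("locus ", loc, " has no V segment")
    if (!"J" %in% types) note("locus ", loc, " has no J segment")
  }
  out
}

#' Load a germline database from FASTA plus metadata sidecar
#'
#' The FASTA file holds the segment sequences; the tab-separated sidecar
#' (columns `name`, `locus`, `segment_type`, `anchor`, `reading_frame`)
#' supplies the structural metadata. Every FASTA record must have a metadata
#' row; anchors are validated (a V anchor codon that is not Cys, or a J
#' anchor codon that is not Trp/Phe, is a hard error).
#'
#' @param fasta_path path to the segment FASTA.
#' @param metadata_path path to the metadata TSV.
#' @param version_tag recorded tag; defaults to the FASTA file name.
#' @return a `germline_db`.
#' @export
load_germline_db <- function(fasta_path, metadata_path,
                             version_tag = basename(fasta_path)) {
  seqs <- read_fasta(fasta_path)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  required <- c("name", "locus", "segment_type", "anchor", "reading_frame")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop_input("metadata sidecar lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  absent <- setdiff(names(seqs), meta$name)
  if (length(absent))
    stop_input("FASTA record(s) missing from metadata: ",
               paste(absent, collapse = ", "))
  meta <- meta[match(names(seqs), meta$name), ]
  meta$sequence <- unname(seqs)
  germline_db(meta, version_tag = version_tag)
}

#' Write a germline database to FASTA plus metadata sidecar
#'
#' Inverse of [load_germline_db()]: round trips byte-identically for
#' databases that came from files written by this function.
#'
#' @param db a `germline_db`.
#' @param fasta_path,metadata_path output paths.
#' @export
write_germline_db <- function(db, fasta_path, metadata_path) {
  seg <- db$segments
  write_fasta(setNames(seg$sequence, seg$name), fasta_path)
  meta <- seg[, c("name", "locus", "segment_type", "anchor", "reading_frame")]
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(db)
}

#' @export
print.germline_db <- function(x, ...) {
  seg <- x$segments
  cat("Germline segment database (", x$version_tag, ")\n", sep = "")
  tab <- table(seg$locus, seg$segment_type)
  print(tab)
  invisible(x)
}

db_segments <- function(db, locus = NULL, segment_type = NULL) {
  seg <- db$segments
  if (!is.null(locus)) seg <- seg[seg$locus %in% locus, ]
  if (!is.null(segment_type)) seg <- seg[seg$segment_type %in% segment_type, ]
  seg
}

db_segment <- function(db, name) {
  seg <- db$segments[db$segments$name == name, ]
  if (nrow(seg) != 1L) stop_input("unknown germline segment: ", name)
  seg
}

# ---- bundled synthetic reference -------------------------------------------

# Deterministically sample n codons free of stop codons (and optionally free
# of Cys codons, so that V anchors are unambiguous landmarks).
random_codons <- function(n, exclude_cys = FALSE) {
  bad <- c("TAA", "TAG", "TGA")
  if (exclude_cys) bad <- c(bad, "TGT", "TGC")
  pool <- names(Biostrings::GENETIC_CODE)
  pool <- pool[!pool %in% bad]
  paste0(sample(pool, n, replace = TRUE), collapse = "")
}

make_v_segment <- function(name, locus, n_codons = 96L, tail = 6L) {
  body <- random_codons(n_codons, exclude_cys = TRUE)
  anchor <- nchar(body)
  cys <- sample(c("TGT", "TGC"), 1L)
  cdr3_tail <- paste0(sample(DNA_BASES, tail, replace = TRUE), collapse = "")
  data.frame(name = name, locus = locus, segment_type = "V",
             sequence = paste0(body, cys, cdr3_tail),
             anchor = anchor, reading_frame = anchor %% 3L,
             stringsAsFactors = FALSE)
}

make_j_segment <- function(name, locus, head = 7L, fr4_codons = 14L) {
  head_nt <- paste0(sample(DNA_BASES, head, replace = TRUE), collapse = "")
  anchor_codon <- if (locus == "IGH") "TGG" else sample(c("TTT", "TTC"), 1L)
  fr4 <- random_codons(fr4_codons)
  data.frame(name = name, locus = locus, segment_type = "J",
             sequence = paste0(head_nt, anchor_codon, fr4),
             anchor = head, reading_frame = head %% 3L,
             stringsAsFactors = FALSE)
}

make_d_segment <- function(name, len) {
  data.frame(name = name, locus = "IGH", segment_type = "D",
             sequence = paste0(sample(DNA_BASES, len, replace = TRUE),
                               collapse = ""),
             anchor = NA_integer_, reading_frame = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Bundled synthetic germline reference
#'
#' Builds, deterministically, the synthetic germline reference used by the
#' examples, simulator defaults and tests: 6 heavy-chain V, 3 D and 4 J
#' segments plus kappa (3 V, 2 J) and lambda (2 V, 2 J) light-chain
#' segments, with realistic lengths (V about 297 nt, D 14-30 nt, J 48-52 nt)
#' and valid Cys / Trp / Phe anchors. The sequences are synthetic (not
#' curated reference alleles); the annotator is reference-agnostic and works
#' with any database supplied to it.
#'
#' @return a `germline_db` with version tag `"bcrtol-demo-1"`.
#' @export
demo_germline_db <- function() {
  with_seed(902140L, {
    vh <- do.call(rbind, lapply(
      c("IGHV1-1*01", "IGHV1-2*01", "IGHV3-1*01", "IGHV3-2*01",
        "IGHV4-1*01", "IGHV5-1*01"),
      function(nm) make_v_segment(nm, "IGH",
                                  n_codons = sample(95:98, 1L),
                                  tail = sample(4:7, 1L))))
    dh <- rbind(make_d_segment("IGHD1-1*01", 16L),
                make_d_segment("IGHD2-1*01", 23L),
                make_d_segment("IGHD3-1*01", 30L))
    jh <- do.call(rbind, lapply(
      c("IGHJ1*01", "IGHJ2*01", "IGHJ3*01", "IGHJ4*01"),
      function(nm) make_j_segment(nm, "IGH", head = sample(5:9, 1L),
                                  fr4_codons = sample(13:15, 1L))))
    vk <- do.call(rbind, lapply(
      c("IGKV1-39*01", "IGKV3-1*01", "IGKV4-1*01"),
      function(nm) make_v_segment(nm, "IGK",
                                  n_codons = sample(94:97, 1L),
                                  tail = sample(3:5, 1L))))
    jk <- do.call(rbind, lapply(c("IGKJ1*01", "IGKJ2*01"),
      function(nm) make_j_segment(nm, "IGK", head = sample(4:7, 1L),
                                  fr4_codons = 12L)))
    vl <- do.call(rbind, lapply(c("IGLV1-40*01", "IGLV2-14*01"),
      function(nm) make_v_segment(nm, "IGL",
                                  n_codons = sample(94:97, 1L),
                                  tail = sample(3:5, 1L))))
    jl <- do.call(rbind, lapply(c("IGLJ2*01", "IGLJ3*01"),
      function(nm) make_j_segment(nm, "IGL", head = sample(4:7, 1L),
                                  fr4_codons = 12L)))
    germline_db(rbind(vh, dh, jh, vk, jk, vl, jl),
                version_tag = "bcrtol-demo-1")
  })
}
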