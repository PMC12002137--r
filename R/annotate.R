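# Alignment scoring defaults: match +1, mismatch -1, gap open -4, extend -1.
annot_config <- function(match = 1, mismatch = -1, gap_opening = 4,
                         gap_extension = 1, min_v_identity = 0.60,
                         min_v_length = 100L, min_j_identity = 0.70,
                         min_j_length = 15L, min_d_length = 9L,
                         min_d_identity = 0.75) {
  list(match = match, mismatch = mismatch, gap_opening = gap_opening,
       gap_extension = gap_extension, min_v_identity = min_v_identity,
       min_v_length = min_v_length, min_j_identity = min_j_identity,
       min_j_length = min_j_length, min_d_length = min_d_length,
       min_d_identity = min_d_identity)
}

sub_matrix <- function(cfg) {
  Biostrings::nucleotideSubstitutionMatrix(match = cfg$match,
                                           mismatch = cfg$mismatch,
                                           baseOnly = TRUE)
}

# Local alignment of query vs one germline sequence. Returns NULL when the
# aligner finds nothing, else a block: 0-based half-open intervals on query
# and germline, score, identity over aligned columns, a column map of
# aligned (non-gap) positions, and the count of gapped columns. The common
# ungapped case takes an arithmetic fast path; gapped alignments fall back
# to walking the aligned strings.
align_pair <- function(query, germ, cfg) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = germ, type = "local",
    substitutionMatrix = sub_matrix(cfg),
    gapOpening = cfg$gap_opening, gapExtension = cfg$gap_extension)
  qr <- aln@pattern@range       # 1-based closed
  gr <- aln@subject@range
  if (qr@width == 0L) return(NULL)
  ind <- Biostrings::nindel(aln)
  n_gap <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
    sum(Biostrings::deletion(ind)[, "WidthSum"])
  if (n_gap == 0L) {
    qn <- strsplit(substr(query, qr@start, qr@start + qr@width - 1L),
                   "")[[1]]
    gn <- strsplit(substr(germ, gr@start, gr@start + gr@width - 1L),
                   "")[[1]]
    map <- data.frame(qpos = seq.int(qr@start - 1L,
                                     length.out = qr@width),
                      gpos = seq.int(gr@start - 1L,
                                     length.out = gr@width),
                      qnt = qn, gnt = gn, stringsAsFactors = FALSE)
    n_col <- qr@width
  } else {
    pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    pnon <- pc != "-"; snon <- sc != "-"
    qi <- ifelse(pnon, qr@start - 1L + cumsum(pnon) - 1L, NA_integer_)
    gi <- ifelse(snon, gr@start - 1L + cumsum(snon) - 1L, NA_integer_)
    aligned <- pnon & snon
    map <- data.frame(qpos = qi[aligned], gpos = gi[aligned],
                      qnt = pc[aligned], gnt = sc[aligned],
                      stringsAsFactors = FALSE)
    n_col <- length(pc)
  }
  list(query_interval = c(qr@start - 1L, qr@start - 1L + qr@width),
       germline_interval = c(gr@start - 1L, gr@start - 1L + gr@width),
       score = Biostrings::score(aln),
       identity = sum(map$qnt == map$gnt) / n_col,
       n_gap_columns = n_gap, map = map)
}

# Local alignment scores of one query against many germline sequences,
# in a single vectorized call (the local score is symmetric in its
# arguments, so the germlines can sit on the pattern side).
score_candidates <- function(query, germs, cfg) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(germs),
    subject = Biostrings::DNAString(query), type = "local",
    substitutionMatrix = sub_matrix(cfg),
    gapOpening = cfg$gap_opening, gapExtension = cfg$gap_extension,
    scoreOnly = TRUE)
}

# Extend an alignment block's column map ungapped beyond the local-alignment
# ends: left to query/germline start, right up to germline position
# g_right_max (exclusive) while query remains. Local alignment clips
# terminal mismatches; extension restores coverage of mutated segment ends
# so that mutation calling and reversion see them.
extend_map <- function(block, query_chars, germ_chars, g_left_min = 0L,
                       g_right_max = length(germ_chars)) {
  map <- block$map
  if (!nrow(map)) return(block)
  q0 <- map$qpos[1]; g0 <- map$gpos[1]
  d <- min(q0 - 0L, g0 - g_left_min)
  if (d > 0L) {
    qs <- (q0 - d):(q0 - 1L); gs <- (g0 - d):(g0 - 1L)
    map <- rbind(data.frame(qpos = qs, gpos = gs,
                            qnt = query_chars[qs + 1L],
                            gnt = germ_chars[gs + 1L],
                            stringsAsFactors = FALSE), map)
  }
  q1 <- map$qpos[nrow(map)]; g1 <- map$gpos[nrow(map)]
  d <- min(length(query_chars) - 1L - q1, g_right_max - 1L - g1)
  if (d > 0L) {
    qs <- (q1 + 1L):(q1 + d); gs <- (g1 + 1L):(g1 + d)
    map <- rbind(map, data.frame(qpos = qs, gpos = gs,
                                 qnt = query_chars[qs + 1L],
                                 gnt = germ_chars[gs + 1L],
                                 stringsAsFactors = FALSE))
  }
  block$map <- map
  block$query_interval <- c(map$qpos[1], map$qpos[nrow(map)] + 1L)
  block$germline_interval <- c(map$gpos[1], map$gpos[nrow(map)] + 1L)
  block
}

rank_blocks <- function(blocks) {
  ord <- order(-vapply(blocks, `[[`, 0, "score"),
               -vapply(blocks, `[[`, 0, "identity"),
               vapply(blocks, `[[`, "", "segment_name"))
  blocks[ord]
}

#' Align a query against all candidate germline V segments
#'
#' Local alignment (defaults: match +1, mismatch -1, gap open -4, gap
#' extend -1) of the query against every V segment of the candidate loci,
#' ranked by score, with ties broken by higher identity then lexicographic
#' segment name. The winning block's column map is extended, ungapped, to
#' the start of both sequences and rightwards through the V anchor codon, so
#' that substitutions at clipped segment ends are still visible to mutation
#' calling.
#'
#' @param query nucleotide string (>= 100 nt).
#' @param db a `germline_db`.
#' @param loci candidate loci (default: all in `db`).
#' @param cfg scoring configuration from `annot_config()`.
#' @return ranked list of alignment blocks, or `NULL` (no V assignment) when
#'   the best hit falls below the identity floor (default 0.60) or spans
#'   fewer than `min_v_length` aligned nucleotides (default 100).
#' @export
align_v <- function(query, db, loci = NULL, cfg = annot_config()) {
  if (nchar(query) < 100L)
    stop_input("query shorter than 100 nt")
  vs <- db_segments(db, locus = loci, segment_type = "V")
  if (!nrow(vs)) return(NULL)
  scores <- score_candidates(query, vs$sequence, cfg)
  # full alignment (with column map) only for the score-tied leaders;
  # the remaining candidates are reported as name/score stubs
  top <- which(scores >= max(scores) - 1e-9)
  blocks <- list()
  for (i in top) {
    b <- align_pair(query, vs$sequence[i], cfg)
    if (is.null(b)) next
    b$segment_name <- vs$name[i]
    b$locus <- vs$locus[i]
    b$anchor <- vs$anchor[i]
    b$reading_frame <- vs$reading_frame[i]
    blocks[[length(blocks) + 1L]] <- b
  }
  if (!length(blocks)) return(NULL)
  blocks <- rank_blocks(blocks)
  # a local alignment of unrelated sequence keeps only a short
  # high-identity island, so a length floor accompanies the identity floor
  if (blocks[[1]]$identity < cfg$min_v_identity ||
      nrow(blocks[[1]]$map) < cfg$min_v_length) return(NULL)
  qc <- strsplit(query, "")[[1]]
  gc <- strsplit(vs$sequence[match(blocks[[1]]$segment_name, vs$name)],
                 "")[[1]]
  blocks[[1]] <- extend_map(blocks[[1]], qc, gc,
                            g_right_max = blocks[[1]]$anchor + 3L)
  rest <- order(-scores)
  rest <- rest[!vs$name[rest] %in% vapply(blocks, `[[`, "",
                                          "segment_name")]
  stubs <- lapply(rest, function(i)
    list(segment_name = vs$name[i], locus = vs$locus[i],
         score = scores[i], identity = NA_real_, map = NULL))
  c(blocks, stubs)
}

#' Align germline J segments 3' of an assigned V block
#'
#' Same contract as [align_v()] restricted to the sequence 3' of the V
#' block and to the V call's locus; the best block must span at least 15
#' aligned nucleotides at >= 0.70 identity (defaults). The column map is
#' extended ungapped in both directions (leftward extension can only reach
#' germline positions 5' of the J anchor, which are outside the
#' mutation-calling region).
#'
#' @param query nucleotide string.
#' @param v_block winning V block from [align_v()].
#' @param db a `germline_db`.
#' @param cfg scoring configuration.
#' @return one alignment block, or `NULL` (no J assignment).
#' @export
align_j <- function(query, v_block, db, cfg = annot_config()) {
  offset <- v_block$query_interval[2]     # J search starts 3' of V block
  sub <- substr(query, offset + 1L, nchar(query))
  if (nchar(sub) < cfg$min_j_length) return(NULL)
  js <- db_segments(db, locus = v_block$locus, segment_type = "J")
  if (!nrow(js)) return(NULL)
  scores <- score_candidates(sub, js$sequence, cfg)
  top <- which(scores >= max(scores) - 1e-9)
  blocks <- list()
  for (i in top) {
    b <- align_pair(sub, js$sequence[i], cfg)
    if (is.null(b)) next
    b$segment_name <- js$name[i]
    b$locus <- js$locus[i]
    b$anchor <- js$anchor[i]
    b$reading_frame <- js$reading_frame[i]
    blocks[[length(blocks) + 1L]] <- b
  }
  if (!length(blocks)) return(NULL)
  blocks <- rank_blocks(blocks)
  best <- blocks[[1]]
  if (nrow(best$map) < cfg$min_j_length ||
      best$identity < cfg$min_j_identity) return(NULL)
  sc <- strsplit(sub, "")[[1]]
  gc <- strsplit(js$sequence[match(best$segment_name, js$name)], "")[[1]]
  best <- extend_map(best, sc, gc)
  # shift to whole-query coordinates
  best$map$qpos <- best$map$qpos + offset
  best$query_interval <- best$query_interval + offset
  best
}

#' Search a heavy-chain junction for the best-matching D segment
#'
#' Ungapped local match (match +1, mismatch -1, with reset) of every D
#' segment, on the given strand only, against the junction interior (the
#' junction minus its two anchor codons). A match is reported only when it
#' spans at least 9 nt at >= 0.75 identity; ties are broken by longer
#' match, then segment name order. Absence of a D call is a valid outcome.
#'
#' @param junction_nt junction nucleotide string (anchor codon to anchor
#'   codon, inclusive).
#' @param db a `germline_db`.
#' @param cfg scoring configuration.
#' @return a block with `query_interval` relative to the junction start
#'   (0-based half-open), `germline_interval`, `score`, `identity`, `map`;
#'   or `NULL` when no D qualifies.
#' @export
assign_d <- function(junction_nt, db, cfg = annot_config()) {
  n <- nchar(junction_nt)
  if (n <= 6L) return(NULL)
  interior <- substr(junction_nt, 4L, n - 3L)
  ic <- strsplit(interior, "")[[1]]
  ds <- db_segments(db, locus = "IGH", segment_type = "D")
  best <- NULL
  for (i in seq_len(nrow(ds))) {
    dc <- strsplit(ds$sequence[i], "")[[1]]
    hit <- best_ungapped_run(ic, dc)
    if (is.null(hit)) next
    if (hit$length < cfg$min_d_length || hit$identity < cfg$min_d_identity)
      next
    hit$segment_name <- ds$name[i]
    if (is.null(best) ||
        hit$score > best$score ||
        (hit$score == best$score && hit$length > best$length) ||
        (hit$score == best$score && hit$length == best$length &&
         hit$segment_name < best$segment_name))
      best <- hit
  }
  if (is.null(best)) return(NULL)
  # shift from interior coordinates to junction coordinates (+3 anchor)
  qs <- best$q_start + 3L
  map <- data.frame(qpos = qs:(qs + best$length - 1L),
                    gpos = best$g_start:(best$g_start + best$length - 1L),
                    stringsAsFactors = FALSE)
  map$qnt <- ic[(best$q_start:(best$q_start + best$length - 1L)) + 1L]
  map$gnt <- strsplit(db_segment(db, best$segment_name)$sequence,
                      "")[[1]][map$gpos + 1L]
  list(segment_name = best$segment_name,
       query_interval = c(qs, qs + best$length),
       germline_interval = c(best$g_start, best$g_start + best$length),
       score = best$score, identity = best$identity, map = map)
}

# Best ungapped +1/-1 local run between two character vectors (all
# diagonals, Kadane-style reset). Returns score, 0-based starts, length,
# identity.
best_ungapped_run <- function(a, b) {
  na <- length(a); nb <- length(b)
  best <- NULL
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(0L, off); ib <- ia - off
    len <- min(na - ia, nb - ib)
    if (len <= 0L) next
    s <- ifelse(a[(ia + 1L):(ia + len)] == b[(ib + 1L):(ib + len)], 1L, -1L)
    run_score <- 0L; run_start <- 1L
    for (k in seq_len(len)) {
      if (run_score <= 0L) { run_score <- s[k]; run_start <- k }
      else run_score <- run_score + s[k]
      if (run_score > 0L) {
        # trim trailing mismatches implicitly: only record at match ends
        if (s[k] == 1L) {
          cand_len <- k - run_start + 1L
          matches <- (run_score + cand_len) / 2L
          cand <- list(score = run_score,
                       q_start = ia + run_start - 1L,
                       g_start = ib + run_start - 1L,
                       length = cand_len,
                       identity = matches / cand_len)
          if (is.null(best) || cand$score > best$score ||
              (cand$score == best$score && cand$length > best$length))
            best <- cand
        }
      }
    }
  }
  best
}

# Observed sequence in germline coordinates: germline characters with the
# query base substituted at every aligned column. Used for codon-level
# replacement/silent classification.
observed_on_germline <- function(germ_chars, map) {
  g <- germ_chars
  g[map$gpos + 1L] <- map$qnt
  g
}

classify_effect <- function(gpos, germ_chars, obs_chars, reading_frame) {
  ci <- (gpos - reading_frame) %/% 3L
  s <- reading_frame + 3L * ci + 1L
  if (s < 1L || s + 2L > length(germ_chars)) return(NA_character_)
  g_codon <- paste0(germ_chars[s:(s + 2L)], collapse = "")
  o_codon <- paste0(obs_chars[s:(s + 2L)], collapse = "")
  g_aa <- unname(Biostrings::GENETIC_CODE[g_codon])
  o_aa <- unname(Biostrings::GENETIC_CODE[o_codon])
  if (is.na(g_aa) || is.na(o_aa)) return(NA_character_)
  if (identical(g_aa, o_aa)) "silent" else "replacement"
}

#' Call somatic substitutions in the templated V and J regions
#'
#' Every mismatched aligned column inside the V block up to the end of the
#' V anchor codon, and inside the J block from the start of the J anchor
#' codon, is emitted as a mutation; the junction interior (non-templated N
#' and D nucleotides) is excluded. Each mutation is classified replacement
#' or silent by translating the germline codon against the observed codon
#' in the germline reading frame. Gapped alignment columns are not
#' mutations; they are tallied separately as indels.
#'
#' @param query nucleotide string.
#' @param v_block,j_block winning blocks from [align_v()] / [align_j()].
#' @param db a `germline_db`.
#' @return list with `mutations` (data.frame: query_pos, germline_pos,
#'   germline_nt, observed_nt, region, effect) and `n_indel`.
#' @export
call_mutations <- function(query, v_block, j_block, db) {
  out <- list()
  for (region in c("V", "J")) {
    block <- if (region == "V") v_block else j_block
    germ <- db_segment(db, block$segment_name)
    gc <- strsplit(germ$sequence, "")[[1]]
    map <- block$map
    keep <- if (region == "V") map$gpos < germ$anchor + 3L
            else map$gpos >= germ$anchor
    map <- map[keep, , drop = FALSE]
    mm <- map[map$qnt != map$gnt, , drop = FALSE]
    if (nrow(mm)) {
      obs <- observed_on_germline(gc, block$map)
      eff <- vapply(mm$gpos, classify_effect, "", germ_chars = gc,
                    obs_chars = obs, reading_frame = germ$reading_frame)
      out[[region]] <- data.frame(query_pos = mm$qpos,
                                  germline_pos = mm$gpos,
                                  germline_nt = mm$gnt,
                                  observed_nt = mm$qnt,
                                  region = region, effect = eff,
                                  stringsAsFactors = FALSE)
    }
  }
  muts <- if (length(out)) do.call(rbind, out) else
    data.frame(query_pos = integer(0), germline_pos = integer(0),
               germline_nt = character(0), observed_nt = character(0),
               region = character(0), effect = character(0),
               stringsAsFactors = FALSE)
  rownames(muts) <- NULL
  list(mutations = muts,
       n_indel = v_block$n_gap_columns + j_block$n_gap_columns)
}

failed_annotation <- function(sequence_id, query, status) {
  structure(list(sequence_id = sequence_id, sequence = query,
                 locus = NA_character_, v_call = NA_character_,
                 d_call = NA_character_, j_call = NA_character_,
                 v_block = NULL, d_block = NULL, j_block = NULL,
                 junction_nt = NA_character_, junction_aa = NA_character_,
                 cdr3_aa = NA_character_,
                 mutations = NULL, n_indel = NA_integer_,
                 mutation_count_total = NA_integer_,
                 productive = NA, v_identity = NA_real_,
                 v_anchor_q = NA_integer_, j_anchor_q = NA_integer_,
                 status = status),
            class = "bcr_annotation")
}

#' Annotate one BCR nucleotide sequence
#'
#' Composes [align_v()], [align_j()], [assign_d()] and [call_mutations()]:
#' assigns germline V/(D)/J, extracts the junction from the first base of
#' the V anchor codon through the last base of the J anchor codon
#' (inclusive), translates the CDR3 (junction minus both anchor residues),
#' and calls templated substitutions. A sequence for which no V or no J
#' qualifies yields a failed annotation (`status` of `"no_v"` /`"no_j"`),
#' not an error, so batches survive bad records.
#'
#' @param query nucleotide string.
#' @param db a `germline_db`.
#' @param sequence_id identifier carried into the output.
#' @param cfg scoring configuration from `annot_config()`.
#' @return object of class `bcr_annotation`.
#' @export
annotate <- function(query, db, sequence_id = "query",
                     cfg = annot_config()) {
  query <- toupper(query)
  vhits <- align_v(query, db, cfg = cfg)
  if (is.null(vhits)) return(failed_annotation(sequence_id, query, "no_v"))
  v_block <- vhits[[1]]
  j_block <- align_j(query, v_block, db, cfg = cfg)
  if (is.null(j_block)) return(failed_annotation(sequence_id, query, "no_j"))

  v_anchor_q <- v_block$map$qpos[match(v_block$anchor, v_block$map$gpos)]
  j_anchor_q <- j_block$map$qpos[match(j_block$anchor, j_block$map$gpos)]
  if (is.na(v_anchor_q))
    return(failed_annotation(sequence_id, query, "no_v_anchor"))
  if (is.na(j_anchor_q))
    return(failed_annotation(sequence_id, query, "no_j_anchor"))

  junction_nt <- substr(query, v_anchor_q + 1L, j_anchor_q + 3L)
  in_frame <- nchar(junction_nt) %% 3L == 0L
  junction_aa <- if (in_frame) translate_nt(junction_nt) else NA_character_
  cdr3_aa <- if (in_frame && nchar(junction_aa) >= 2L)
    substr(junction_aa, 2L, nchar(junction_aa) - 1L) else NA_character_

  d_block <- NULL
  if (v_block$locus == "IGH") {
    d_block <- assign_d(junction_nt, db, cfg = cfg)
    if (!is.null(d_block)) {
      # lift junction-relative coordinates to whole-query coordinates
      d_block$query_interval <- d_block$query_interval + v_anchor_q
      d_block$map$qpos <- d_block$map$qpos + v_anchor_q
    }
  }

  mut <- call_mutations(query, v_block, j_block, db)
  frame_off <- v_anchor_q %% 3L
  aa_full <- translate_nt(substr(query, frame_off + 1L, nchar(query)))
  productive <- in_frame && !grepl("\\*", aa_full)

  structure(list(
    sequence_id = sequence_id, sequence = query, locus = v_block$locus,
    v_call = v_block$segment_name,
    d_call = if (is.null(d_block)) NA_character_ else d_block$segment_name,
    j_call = j_block$segment_name,
    v_block = v_block, d_block = d_block, j_block = j_block,
    junction_nt = junction_nt, junction_aa = junction_aa, cdr3_aa = cdr3_aa,
    mutations = mut$mutations, n_indel = mut$n_indel,
    mutation_count_total = nrow(mut$mutations),
    productive = productive, v_identity = v_block$identity,
    v_anchor_q = v_anchor_q, j_anchor_q = j_anchor_q,
    status = "ok"), class = "bcr_annotation")
}

#' @export
print.bcr_annotation <- function(x, ...) {
  cat("BCR annotation:", x$sequence_id, "\n")
  if (x$status != "ok") {
    cat("  FAILED (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat("  locus", x$locus, " V:", x$v_call, " D:",
      ifelse(is.na(x$d_call), "-", x$d_call), " J:", x$j_call, "\n")
  cat("  junction:", x$junction_nt, "\n")
  cat("  CDR3 aa:", x$cdr3_aa, " productive:", x$productive, "\n")
  cat("  mutations:", x$mutation_count_total,
      " (indel columns:", x$n_indel, ")\n")
  invisible(x)
}

#' Annotate a batch of sequences
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param db a `germline_db`.
#' @param cfg scoring configuration.
#' @return list of `bcr_annotation` objects, named by sequence ID.
#' @export
annotate_batch <- function(seqs, db, cfg = annot_config()) {
  if (is.null(names(seqs))) stop_input("sequences must be named")
  out <- lapply(seq_along(seqs),
                function(i) annotate(seqs[[i]], db, names(seqs)[i], cfg))
  setNames(out, names(seqs))
}

#' Convert annotations to an AIRR Rearrangement table
#'
#' @param annotations list of `bcr_annotation` objects.
#' @return data.frame with the package's AIRR columns (`clone_id` blank;
#'   filled by [partition_clones()]).
#' @export
airr_table <- function(annotations) {
  rows <- lapply(annotations, function(a) data.frame(
    sequence_id = a$sequence_id, sequence = a$sequence,
    locus = a$locus, v_call = a$v_call, d_call = a$d_call,
    j_call = a$j_call, junction = a$junction_nt,
    junction_aa = a$junction_aa, cdr3_aa = a$cdr3_aa,
    v_identity = a$v_identity, productive = a$productive,
    mutation_count = a$mutation_count_total, clone_id = NA_character_,
    stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}
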