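#' Simulation configuration
#'
#' Parameters of the synthetic repertoire generator. Defaults emulate the
#' sorted naive / class-switched memory B-cell compartments the package's
#' checkpoint analyses expect: naive receptors unmutated, memory receptors
#' carrying per-clone somatic hypermutation (SHM) loads drawn from a 2-6%
#' per-nucleotide range (roughly 8-25 substitutions on a 400 nt variable
#' region), small geometric clonal expansions and rare (~0.5%)
#' antigen-reactive cells.
#'
#' @param n_cells cells simulated per group x compartment.
#' @param trim_mean mean exonuclease trim per segment end (geometric).
#' @param n_insert_mean mean non-templated insert length per junction
#'   (Poisson).
#' @param shm_rate_naive,shm_rate_memory per-nucleotide substitution
#'   probability; a length-2 vector is a range sampled uniformly per clone.
#' @param clone_size_p geometric parameter for clone sizes (`1` makes every
#'   clone a singleton).
#' @param reactive_fraction probability a cell is labeled antigen-reactive.
#' @param seed integer RNG seed recorded in the output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L, trim_mean = 2, n_insert_mean = 4,
                       shm_rate_naive = 0, shm_rate_memory = c(0.02, 0.06),
                       clone_size_p = 0.5, reactive_fraction = 0.005,
                       seed = 1L) {
  chk01 <- function(x, what) {
    if (any(x < 0) || any(x > 1)) stop_input(what, " must lie in [0, 1]")
  }
  if (n_cells < 1L) stop_input("n_cells must be positive")
  if (trim_mean < 0 || n_insert_mean < 0)
    stop_input("trim_mean and n_insert_mean must be non-negative")
  chk01(shm_rate_naive, "shm_rate_naive")
  chk01(shm_rate_memory, "shm_rate_memory")
  chk01(clone_size_p, "clone_size_p")
  if (clone_size_p == 0) stop_input("clone_size_p must be positive")
  chk01(reactive_fraction, "reactive_fraction")
  structure(list(n_cells = as.integer(n_cells), trim_mean = trim_mean,
                 n_insert_mean = n_insert_mean,
                 shm_rate_naive = shm_rate_naive,
                 shm_rate_memory = shm_rate_memory,
                 clone_size_p = clone_size_p,
                 reactive_fraction = reactive_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Geometric draw (support 0,1,2,...) with the requested mean.
rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(integer(n))
  rgeom(n, 1 / (1 + mean))
}

rand_nt <- function(len) {
  if (len == 0L) return("")
  paste0(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

#' Simulate one V(D)J rearrangement
#'
#' Draws V, (D,) J segments for the requested locus, applies geometric
#' exonuclease trimming and Poisson-length uniform-base non-templated (N)
#' inserts, and rejects draws that are non-productive: the V and J anchor
#' codons must survive trimming, lie in the same reading frame, and the
#' in-frame translation must be free of stop codons. Rejected draws are
#' resampled (new trims/inserts for the same segment choice); more than
#' 1000 consecutive rejections is an error flagging a degenerate
#' configuration.
#'
#' The returned truth record satisfies the concatenation invariant: the
#' premutation sequence equals trimmed V + N1 + trimmed D + N2 + trimmed J
#' (heavy) or trimmed V + N + trimmed J (light).
#'
#' @param db a `germline_db`.
#' @param cfg a `sim_config`.
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @return a list of class `rearrangement_truth`; consumes the current RNG
#'   stream.
#' @export
recombine <- function(db, cfg, locus = "IGH") {
  heavy <- locus == "IGH"
  vs <- db_segments(db, locus, "V")
  js <- db_segments(db, locus, "J")
  ds <- if (heavy) db_segments(db, locus, "D") else NULL
  if (!nrow(vs) || !nrow(js) || (heavy && !nrow(ds)))
    stop_input("database lacks segments for locus ", locus)

  for (attempt in seq_len(1000L)) {
    # segments re-drawn every attempt: in low-diversity limits the frame
    # constraint is decided by the segment combination alone
    v <- vs[sample.int(nrow(vs), 1L), ]
    j <- js[sample.int(nrow(js), 1L), ]
    d <- if (heavy) ds[sample.int(nrow(ds), 1L), ] else NULL
    v_len <- nchar(v$sequence); j_len <- nchar(j$sequence)
    d_len <- if (heavy) nchar(d$sequence) else 0L
    v_keep_min <- v$anchor + 3L         # V anchor codon must survive
    v3 <- rgeom_mean(1L, cfg$trim_mean)
    j5 <- rgeom_mean(1L, cfg$trim_mean)
    if (v3 > v_len - v_keep_min || j5 > j$anchor) next
    if (heavy) {
      d5 <- rgeom_mean(1L, cfg$trim_mean)
      d3 <- rgeom_mean(1L, cfg$trim_mean)
      if (d5 + d3 > d_len) next
      n1 <- rand_nt(rpois(1L, cfg$n_insert_mean))
      n2 <- rand_nt(rpois(1L, cfg$n_insert_mean))
      d_part <- substr(d$sequence, d5 + 1L, d_len - d3)
    } else {
      d5 <- d3 <- 0L
      n1 <- rand_nt(rpois(1L, cfg$n_insert_mean))
      n2 <- ""
      d_part <- ""
    }
    v_part <- substr(v$sequence, 1L, v_len - v3)
    j_part <- substr(j$sequence, j5 + 1L, j_len)
    seq <- paste0(v_part, n1, d_part, n2, j_part)

    v_anchor_q <- v$anchor
    j_anchor_q <- nchar(v_part) + nchar(n1) + nchar(d_part) + nchar(n2) +
      (j$anchor - j5)
    if ((j_anchor_q - v_anchor_q) %% 3L != 0L) next
    aa <- translate_nt(substr(seq, v$reading_frame + 1L, nchar(seq)))
    if (grepl("\\*", aa)) next

    region <- c(rep("V", nchar(v_part)), rep("n", nchar(n1)),
                rep("D", nchar(d_part)), rep("n", nchar(n2)),
                rep("J", nchar(j_part)))
    return(structure(list(
      locus = locus,
      v_call = v$name, d_call = if (heavy) d$name else NA_character_,
      j_call = j$name,
      v3_trim = v3, d5_trim = d5, d3_trim = d3, j5_trim = j5,
      n1_seq = n1, n2_seq = n2,
      premutation_seq = seq, sequence = seq,
      shm_positions = data.frame(position = integer(0),
                                 germline_nt = character(0),
                                 mutated_nt = character(0),
                                 stringsAsFactors = FALSE),
      region = paste0(region, collapse = ""),
      v_anchor_q = v_anchor_q, j_anchor_q = j_anchor_q,
      junction = substr(seq, v_anchor_q + 1L, j_anchor_q + 3L)),
      class = "rearrangement_truth"))
  }
  stop_input("recombine: >1000 consecutive non-productive draws for ",
             locus, " (degenerate configuration)")
}

#' Apply somatic hypermutation to a simulated rearrangement
#'
#' Each position of the current sequence is independently substituted, with
#' probability `shm_rate`, by a uniformly chosen different base. The truth
#' record's `shm_positions` is recomputed as the full set of differences to
#' the premutation sequence, so repeated application stacks correctly (a
#' back-mutation to germline drops out of the list).
#'
#' @param truth a `rearrangement_truth`.
#' @param shm_rate per-nucleotide substitution probability in `[0, 1]`.
#' @return the updated truth record; consumes the current RNG stream.
#' @export
mutate_rearrangement <- function(truth, shm_rate) {
  if (shm_rate < 0 || shm_rate > 1) stop_input("shm_rate must lie in [0, 1]")
  n <- nchar(truth$sequence)
  if (shm_rate > 0 && n > 0L) {
    cur <- strsplit(truth$sequence, "")[[1]]
    hits <- which(runif(n) < shm_rate)
    for (i in hits) {
      cur[i] <- sample(setdiff(DNA_BASES, cur[i]), 1L)
    }
    truth$sequence <- paste0(cur, collapse = "")
  }
  pre <- strsplit(truth$premutation_seq, "")[[1]]
  now <- strsplit(truth$sequence, "")[[1]]
  diffp <- which(pre != now)
  truth$shm_positions <- data.frame(position = diffp - 1L,
                                    germline_nt = pre[diffp],
                                    mutated_nt = now[diffp],
                                    stringsAsFactors = FALSE)
  truth$junction <- substr(truth$sequence, truth$v_anchor_q + 1L,
                           truth$j_anchor_q + 3L)
  truth
}

encode_shm <- function(shm) {
  if (!nrow(shm)) return("")
  paste(sprintf("%d:%s>%s", shm$position, shm$germline_nt, shm$mutated_nt),
        collapse = ",")
}

#' Decode the `sim_shm` truth column
#'
#' @param x encoded string such as `"12:A>G,40:C>T"`.
#' @return data.frame with columns position, germline_nt, mutated_nt.
#' @export
decode_shm <- function(x) {
  if (is.na(x) || x == "")
    return(data.frame(position = integer(0), germline_nt = character(0),
                      mutated_nt = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(x, ",")[[1]], "[:>]")
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             germline_nt = vapply(parts, `[`, "", 2L),
             mutated_nt = vapply(parts, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

truth_row <- function(truth, sequence_id, cell_id, clone_id, group,
                      compartment, reactive) {
  data.frame(sequence_id = sequence_id, cell_id = cell_id,
             clone_id = clone_id, group = group, compartment = compartment,
             reactive = reactive, locus = truth$locus,
             v_call = truth$v_call, d_call = truth$d_call,
             j_call = truth$j_call,
             v3_trim = truth$v3_trim, d5_trim = truth$d5_trim,
             d3_trim = truth$d3_trim, j5_trim = truth$j5_trim,
             n1_seq = truth$n1_seq, n2_seq = truth$n2_seq,
             sequence = truth$sequence,
             sim_premutation_seq = truth$premutation_seq,
             sim_shm = encode_shm(truth$shm_positions),
             sim_region = truth$region,
             sim_v_anchor = truth$v_anchor_q,
             sim_j_anchor = truth$j_anchor_q,
             sim_junction = truth$junction,
             stringsAsFactors = FALSE)
}

shm_rate_draw <- function(range) {
  if (length(range) == 1L) range else runif(1L, range[1], range[2])
}

#' Simulate a full sorted-compartment repertoire
#'
#' For every group x compartment combination, cells are organised into
#' clones of geometric size; each clone draws one heavy and one light
#' rearrangement, receives shared clone-level SHM at the compartment rate,
#' and every clone member then accumulates independent additional SHM at a
#' quarter of that rate (so clone members are similar but not identical).
#' Reactivity labels are independent per-cell Bernoulli draws. Output is
#' deterministic for a fixed `cfg$seed`.
#'
#' @param db a `germline_db`.
#' @param cfg a `sim_config`.
#' @param groups,compartments factor levels simulated.
#' @param light_loci light-chain loci sampled uniformly per clone (those
#'   present in `db`).
#' @return list with `sequences` (named character vector, FASTA-ready) and
#'   `truth` (one row per simulated chain, AIRR-compatible call columns plus
#'   `sim_*` ground-truth columns).
#' @export
simulate_repertoire <- function(db, cfg, groups = c("patient", "control"),
                                compartments = c("naive", "memory"),
                                light_loci = intersect(
                                  c("IGK", "IGL"),
                                  unique(db$segments$locus))) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!length(light_loci)) stop_input("no light-chain locus in database")
  with_seed(cfg$seed, {
    rows <- vector("list", 0L)
    for (g in groups) for (cm in compartments) {
      rate_range <- if (cm == "naive") cfg$shm_rate_naive else
        cfg$shm_rate_memory
      # geometric clone sizes covering n_cells
      sizes <- integer(0)
      while (sum(sizes) < cfg$n_cells)
        sizes <- c(sizes, rgeom(1L, cfg$clone_size_p) + 1L)
      sizes[length(sizes)] <- sizes[length(sizes)] -
        (sum(sizes) - cfg$n_cells)
      cell_no <- 0L
      for (ci in seq_along(sizes)) {
        light <- if (length(light_loci) == 1L) light_loci else
          sample(light_loci, 1L)
        base <- list(IGH = recombine(db, cfg, "IGH"),
                     L = recombine(db, cfg, light))
        rate <- shm_rate_draw(rate_range)
        founder <- lapply(base, mutate_rearrangement, shm_rate = rate)
        for (m in seq_len(sizes[ci])) {
          cell_no <- cell_no + 1L
          cell_id <- sprintf("%s_%s_%04d", g, cm, cell_no)
          reactive <- runif(1L) < cfg$reactive_fraction
          member <- lapply(founder, mutate_rearrangement,
                           shm_rate = rate / 4)
          for (ch in names(member)) {
            tr <- member[[ch]]
            rows[[length(rows) + 1L]] <- truth_row(
              tr,
              sequence_id = paste0(cell_id, "_", tr$locus),
              cell_id = cell_id,
              clone_id = sprintf("%s_%s_cl%03d_%s", g, cm, ci, tr$locus),
              group = g, compartment = cm, reactive = reactive)
          }
        }
      }
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    attr(truth, "seed") <- cfg$seed
    list(sequences = setNames(truth$sequence, truth$sequence_id),
         truth = truth)
  })
}

#' Tally checkpoint screening counts from per-cell reactivity labels
#'
#' Collapses a labeled table (one or more rows per cell) to the
#' contingency-ready counts used by the checkpoint statistics: per group and
#' compartment, the number of reactive cells and the number screened.
#'
#' @param labels data.frame with columns `cell_id`, `group`, `compartment`,
#'   `reactive`.
#' @return data.frame with columns group, compartment, k_reactive,
#'   n_screened.
#' @export
simulate_checkpoint_counts <- function(labels) {
  need <- c("cell_id", "group", "compartment", "reactive")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols))
    stop_input("labels lack column(s): ", paste(missing_cols, collapse = ", "))
  cells <- labels[!duplicated(labels$cell_id), need]
  agg <- aggregate(cbind(k_reactive = reactive,
                         n_screened = rep(1L, nrow(cells))) ~
                     group + compartment, data = cells, FUN = sum)
  agg <- agg[order(agg$group, agg$compartment), ]
  rownames(agg) <- NULL
  agg
}

#' @importFrom stats aggregate
NULL
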