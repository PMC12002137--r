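unmutated_batch <- local({
  sim <- simulate_repertoire(demo_db,
                             sim_config(n_cells = 30, shm_rate_memory = 0,
                                        seed = 881))
  sim$truth
})

test_that("unmutated rearrangements are annotated perfectly", {
  tr <- unmutated_batch[1:50, ]
  anns <- annotate_batch(setNames(tr$sequence, tr$sequence_id), demo_db)
  airr <- airr_table(anns)
  expect_true(all(airr$v_call == tr$v_call))
  expect_true(all(airr$j_call == tr$j_call))
  expect_true(all(airr$junction == tr$sim_junction))
  expect_true(all(airr$mutation_count == 0))
  top_identity <- vapply(anns, `[[`, 0, "v_identity")
  expect_true(all(top_identity == 1))
})

test_that("V/J assignment survives memory-level hypermutation", {
  sim <- simulate_repertoire(demo_db, sim_config(n_cells = 40, seed = 12))
  mem <- sim$truth[sim$truth$compartment == "memory", ]
  mem <- mem[seq_len(min(120, nrow(mem))), ]
  anns <- annotate_batch(setNames(mem$sequence, mem$sequence_id), demo_db)
  airr <- airr_table(anns)
  expect_gte(mean(airr$v_call == mem$v_call), 0.98)
  expect_gte(mean(airr$j_call == mem$j_call), 0.98)
  expect_gte(mean(airr$junction == mem$sim_junction), 0.98)
})

test_that("random sequences yield a no-assignment signal", {
  set.seed(40)
  rand <- paste0(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  expect_null(align_v(rand, demo_db))
  ann <- annotate(rand, demo_db, "rand")
  expect_equal(ann$status, "no_v")
  expect_true(is.na(ann$v_call))
})

test_that("queries truncated before J give a no-J signal, short ones error", {
  tr <- unmutated_batch[unmutated_batch$locus == "IGH", ][1, ]
  stub <- substr(tr$sequence, 1, tr$sim_v_anchor)   # V region only
  ann <- annotate(stub, demo_db, "trunc")
  expect_true(ann$status %in% c("no_j", "no_j_anchor"))
  expect_error(align_v(strrep("ACGT", 20), demo_db), "100 nt")
})

test_that("D genes are recovered when enough D sequence is retained", {
  seg <- demo_db$segments
  d <- seg[seg$name == "IGHD2-1*01", ]
  junction <- paste0("TGT", "ACGGC", d$sequence, "GTCAA", "TGG")
  hit <- assign_d(junction, demo_db)
  expect_equal(hit$segment_name, "IGHD2-1*01")
  expect_equal(hit$identity, 1)
  expect_equal(hit$query_interval[2] - hit$query_interval[1],
               nchar(d$sequence))

  # junction of pure non-templated sequence: no D call
  set.seed(8)
  nojunk <- paste0("TGT", paste0(sample(c("A", "C"), 12, replace = TRUE),
                                 collapse = ""), "TGG")
  expect_null(assign_d(nojunk, demo_db))
})

test_that("D recovery rate is high for well-retained D segments", {
  sim <- simulate_repertoire(demo_db,
                             sim_config(n_cells = 150, trim_mean = 1,
                                        shm_rate_memory = 0, seed = 303),
                             groups = "patient", compartments = "memory")
  tr <- sim$truth[sim$truth$locus == "IGH", ]
  seg <- demo_db$segments
  d_len <- nchar(seg$sequence[match(tr$d_call, seg$name)])
  retained <- d_len - tr$d5_trim - tr$d3_trim
  tr <- tr[retained >= 12, ]
  hits <- vapply(seq_len(nrow(tr)), function(i) {
    b <- assign_d(tr$sim_junction[i], demo_db)
    !is.null(b) && b$segment_name == tr$d_call[i]
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("mutation calls recover the simulated templated substitutions", {
  sim <- simulate_repertoire(demo_db,
                             sim_config(n_cells = 10,
                                        shm_rate_memory = c(0.04, 0.06),
                                        seed = 97))
  mem <- sim$truth[sim$truth$compartment == "memory", ][1:20, ]
  for (i in seq_len(nrow(mem))) {
    tr <- mem[i, ]
    ann <- annotate(tr$sequence, demo_db, tr$sequence_id)
    expect_equal(ann$v_call, tr$v_call)
    shm <- decode_shm(tr$sim_shm)
    region <- strsplit(tr$sim_region, "")[[1]]
    shm$region <- region[shm$position + 1L]
    # positions the caller is defined over: V through its anchor codon,
    # J from its anchor codon; junction interior excluded
    expected <- shm[(shm$region == "V" &
                       shm$position < tr$sim_v_anchor + 3) |
                    (shm$region == "J" & shm$position >= tr$sim_j_anchor), ]
    called <- ann$mutations
    expect_setequal(called$query_pos, expected$position)
    ix <- match(called$query_pos, expected$position)
    expect_identical(called$observed_nt, expected$mutated_nt[ix])
    expect_identical(called$germline_nt, expected$germline_nt[ix])
    # N-region substitutions are never reported
    expect_false(any(called$query_pos %in%
                       shm$position[shm$region == "n"]))
  }
})

test_that("replacement/silent classification agrees with codon translation", {
  tr <- unmutated_batch[unmutated_batch$locus == "IGH", ][2, ]
  seg <- demo_db$segments
  v <- seg[seg$name == tr$v_call, ]
  # force a silent mutation: third base of codon 4 (G->A in most codons
  # keeps the residue only for specific codons, so compute it)
  chars <- strsplit(tr$sequence, "")[[1]]
  pos <- NULL; new_nt <- NULL
  for (p in seq(3, 60, by = 3)) {     # third codon positions, frame 0
    codon <- paste0(chars[(p - 2):p], collapse = "")
    for (alt in setdiff(c("A", "C", "G", "T"), chars[p])) {
      alt_codon <- paste0(substr(codon, 1, 2), alt)
      if (Biostrings::GENETIC_CODE[[codon]] ==
          Biostrings::GENETIC_CODE[[alt_codon]]) {
        pos <- p; new_nt <- alt; break
      }
    }
    if (!is.null(pos)) break
  }
  chars[pos] <- new_nt
  ann <- annotate(paste0(chars, collapse = ""), demo_db, "silent")
  expect_equal(nrow(ann$mutations), 1)
  expect_equal(ann$mutations$effect, "silent")

  # and a guaranteed replacement: first codon base swap that changes aa
  chars2 <- strsplit(tr$sequence, "")[[1]]
  codon <- paste0(chars2[4:6], collapse = "")
  alt <- setdiff(c("A", "C", "G", "T"), chars2[4])
  alt <- alt[vapply(alt, function(x)
    Biostrings::GENETIC_CODE[[paste0(x, substr(codon, 2, 3))]] !=
      Biostrings::GENETIC_CODE[[codon]], TRUE)][1]
  chars2[4] <- alt
  ann2 <- annotate(paste0(chars2, collapse = ""), demo_db, "repl")
  expect_equal(ann2$mutations$effect, "replacement")
})

test_that("internal stop codons mark records non-productive", {
  tr <- unmutated_batch[unmutated_batch$locus == "IGH", ][3, ]
  chars <- strsplit(tr$sequence, "")[[1]]
  chars[31:33] <- c("T", "A", "A")    # frame-0 stop inside V
  ann <- annotate(paste0(chars, collapse = ""), demo_db, "stopped")
  expect_false(ann$productive)
  clean <- annotate(tr$sequence, demo_db, tr$sequence_id)
  expect_true(clean$productive)
  expect_equal(nchar(clean$junction_nt) %% 3, 0)
  expect_equal(nchar(clean$cdr3_aa), nchar(clean$junction_nt) / 3 - 2)
})

test_that("reverting a called mutation strictly reduces the count", {
  sim <- simulate_repertoire(demo_db, sim_config(n_cells = 5, seed = 71))
  mem <- sim$truth[sim$truth$compartment == "memory" &
                     sim$truth$locus == "IGH", ][1:3, ]
  for (i in seq_len(nrow(mem))) {
    ann <- annotate(mem$sequence[i], demo_db, mem$sequence_id[i])
    if (ann$mutation_count_total == 0) next
    m <- ann$mutations[1, ]
    chars <- strsplit(mem$sequence[i], "")[[1]]
    chars[m$query_pos + 1L] <- m$germline_nt
    ann2 <- annotate(paste0(chars, collapse = ""), demo_db, "rev")
    expect_lt(ann2$mutation_count_total, ann$mutation_count_total)
  }
})
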