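test_that("zero-diversity recombination concatenates full segments", {
  cfg <- sim_config(trim_mean = 0, n_insert_mean = 0, seed = 1)
  set.seed(5)
  for (locus in c("IGH", "IGK")) {
    tr <- recombine(demo_db, cfg, locus)
    parts <- c(tr$v_call, tr$d_call, tr$j_call)
    parts <- parts[!is.na(parts)]
    full <- paste0(vapply(parts, function(nm)
      demo_db$segments$sequence[demo_db$segments$name == nm], ""),
      collapse = "")
    expect_identical(tr$sequence, full)
    expect_identical(tr$n1_seq, "")
  }
})

test_that("truth concatenation invariant holds for every draw", {
  cfg <- sim_config(seed = 1)
  set.seed(17)
  for (i in 1:40) {
    locus <- sample(c("IGH", "IGK", "IGL"), 1)
    tr <- recombine(demo_db, cfg, locus)
    seg <- demo_db$segments
    v <- seg[seg$name == tr$v_call, ]
    j <- seg[seg$name == tr$j_call, ]
    v_part <- substr(v$sequence, 1, nchar(v$sequence) - tr$v3_trim)
    j_part <- substr(j$sequence, tr$j5_trim + 1, nchar(j$sequence))
    if (locus == "IGH") {
      d <- seg[seg$name == tr$d_call, ]
      d_part <- substr(d$sequence, tr$d5_trim + 1,
                       nchar(d$sequence) - tr$d3_trim)
      expect_identical(tr$premutation_seq,
                       paste0(v_part, tr$n1_seq, d_part, tr$n2_seq, j_part))
    } else {
      expect_identical(tr$premutation_seq,
                       paste0(v_part, tr$n1_seq, j_part))
    }
    # productive: anchors in frame, no stop between them
    expect_equal((tr$j_anchor_q - tr$v_anchor_q) %% 3, 0)
    expect_false(grepl("\\*", translate_nt(tr$junction)))
  }
})

test_that("insert lengths follow the configured Poisson mean", {
  cfg <- sim_config(n_insert_mean = 4, seed = 1)
  set.seed(91)
  lens <- unlist(lapply(1:1000, function(i) {
    tr <- recombine(demo_db, cfg, "IGH")
    c(nchar(tr$n1_seq), nchar(tr$n2_seq))
  }))
  # productivity rejection tilts long inserts down slightly: each extra
  # junction codon survives the stop-free check w.p. 61/64, shifting the
  # Poisson(4) mean by about 4 * (1 - (61/64)^(1/3)) ~ 0.06; allow for it
  se <- sqrt(4) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 4), 3 * se + 0.07)
})

test_that("degenerate configurations error instead of spinning", {
  # trims that always consume the V anchor tail force endless rejection
  cfg <- sim_config(trim_mean = 500, seed = 1)
  set.seed(3)
  expect_error(recombine(demo_db, cfg, "IGH"), "non-productive")
})

test_that("somatic hypermutation matches its binomial expectation and reverts", {
  base <- list(premutation_seq = strrep("ACGT", 100),
               sequence = strrep("ACGT", 100),
               v_anchor_q = 0L, j_anchor_q = 396L,
               shm_positions = NULL)
  class(base) <- "rearrangement_truth"

  expect_identical(mutate_rearrangement(base, 0)$sequence, base$sequence)
  expect_equal(nrow(mutate_rearrangement(base, 0)$shm_positions), 0)

  set.seed(23)
  counts <- vapply(1:1000, function(i)
    nrow(mutate_rearrangement(base, 0.02)$shm_positions), 0)
  se <- sqrt(400 * 0.02 * 0.98) / sqrt(1000)
  expect_lt(abs(mean(counts) - 8), 3 * se)

  # reverting the listed positions restores the premutation sequence
  set.seed(24)
  tr <- mutate_rearrangement(base, 0.05)
  chars <- strsplit(tr$sequence, "")[[1]]
  chars[tr$shm_positions$position + 1L] <- tr$shm_positions$germline_nt
  expect_identical(paste0(chars, collapse = ""), base$premutation_seq)
})

test_that("repertoire simulation is deterministic and respects clone settings", {
  cfg <- sim_config(n_cells = 15, seed = 77)
  s1 <- simulate_repertoire(demo_db, cfg)
  s2 <- simulate_repertoire(demo_db, cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$truth, s2$truth)

  singles <- simulate_repertoire(demo_db,
                                 sim_config(n_cells = 15, clone_size_p = 1,
                                            seed = 9))
  sizes <- table(singles$truth$clone_id)
  expect_true(all(sizes == 1))
})

test_that("reactivity labels hit the configured fraction", {
  cfg <- sim_config(n_cells = 1000, reactive_fraction = 0.005, seed = 31)
  sim <- simulate_repertoire(demo_db, cfg,
                             groups = "patient", compartments = "naive")
  cells <- sim$truth[!duplicated(sim$truth$cell_id), ]
  expect_equal(nrow(cells), 1000)
  # 4000 cells across four label draws would give 3 SE ~ 13 around 20;
  # scale: 1000 cells, expectation 5
  se <- sqrt(1000 * 0.005 * 0.995)
  expect_lt(abs(sum(cells$reactive) - 5), 3 * se + 1)
})

test_that("checkpoint counts tally labels correctly", {
  labels <- data.frame(
    cell_id = sprintf("c%02d", 1:10),
    group = rep(c("patient", "control"), each = 5),
    compartment = rep(c("naive", "memory"), 5),
    reactive = c(TRUE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, FALSE, TRUE, FALSE, FALSE))
  counts <- simulate_checkpoint_counts(labels)
  pm <- counts[counts$group == "patient" & counts$compartment == "memory", ]
  expect_equal(pm$k_reactive, 1)     # c04 reactive, c02 not
  expect_equal(pm$n_screened, 2)
  expect_equal(sum(counts$n_screened), 10)
  expect_equal(sum(counts$k_reactive), 3)

  none <- labels; none$reactive <- FALSE
  expect_true(all(simulate_checkpoint_counts(none)$k_reactive == 0))
})

test_that("study-scale reactivity difference is detectable by Fisher", {
  set.seed(555)
  hits <- vapply(1:200, function(i) {
    k1 <- rbinom(1, 3806, 0.0026)
    tab <- matrix(c(k1, 3806 - k1, 0, 1920), 2, byrow = TRUE)
    fisher_exact_two_sided(tab) < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
})
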