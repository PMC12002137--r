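test_that("unmutated input reverts to itself", {
  tr <- small_sim$truth[small_sim$truth$compartment == "naive", ][1, ]
  ann <- annotate(tr$sequence, demo_db, tr$sequence_id)
  u <- revert_to_uca(ann, demo_db)
  expect_identical(u$uca_seq, tr$sequence)
  expect_equal(nrow(u$reverted_positions), 0)
  expect_equal(nchar(u$uca_seq), nchar(tr$sequence))
})

test_that("reversion restores templated positions and spares N regions", {
  sim <- simulate_repertoire(demo_db,
                             sim_config(n_cells = 15,
                                        shm_rate_memory = c(0.03, 0.06),
                                        seed = 2203))
  mem <- sim$truth[sim$truth$compartment == "memory", ][1:30, ]
  for (i in seq_len(nrow(mem))) {
    tr <- mem[i, ]
    ann <- annotate(tr$sequence, demo_db, tr$sequence_id)
    if (ann$v_call != tr$v_call || ann$j_call != tr$j_call) next
    u <- revert_to_uca(ann, demo_db)
    pre <- strsplit(tr$sim_premutation_seq, "")[[1]]
    uca <- strsplit(u$uca_seq, "")[[1]]
    expect_length(uca, length(pre))
    interior <- c(tr$sim_v_anchor + 3L, tr$sim_j_anchor)
    bad <- which(pre != uca) - 1L
    # everything outside the junction interior is restored exactly
    expect_true(all(bad >= interior[1] & bad < interior[2]))
    # SHM hits on non-templated junction nucleotides stay irrecoverable,
    # unless the D-guided reversion happens to overlap them
    shm <- decode_shm(tr$sim_shm)
    region <- strsplit(tr$sim_region, "")[[1]]
    n_hits <- shm$position[region[shm$position + 1L] == "n"]
    d_written <- u$reverted_positions$query_pos[
      u$reverted_positions$source == "D"]
    expect_true(all(n_hits %in% c(bad, d_written)))
    # untouched intervals are inside the interior and really untouched
    obs <- strsplit(tr$sequence, "")[[1]]
    for (iv in u$untouched_intervals) {
      expect_true(iv[1] >= interior[1] && iv[2] <= interior[2])
      idx <- seq.int(iv[1] + 1L, iv[2])
      expect_identical(uca[idx], obs[idx])
    }
    # reverted positions never fall in untouched intervals
    for (iv in u$untouched_intervals)
      expect_false(any(u$reverted_positions$query_pos >= iv[1] &
                         u$reverted_positions$query_pos < iv[2]))
  }
})

test_that("replacement_only mode reverts exactly the replacement mutations", {
  sim <- simulate_repertoire(demo_db,
                             sim_config(n_cells = 10,
                                        shm_rate_memory = c(0.04, 0.06),
                                        seed = 412))
  mem <- sim$truth[sim$truth$compartment == "memory", ]
  checked <- 0L
  for (i in seq_len(nrow(mem))) {
    ann <- annotate(mem$sequence[i], demo_db, mem$sequence_id[i])
    if (ann$status != "ok") next
    eff <- ann$mutations$effect
    if (!any(eff == "silent", na.rm = TRUE) ||
        !any(eff == "replacement", na.rm = TRUE)) next
    u_all <- revert_to_uca(ann, demo_db, mode = "all_substitutions")
    u_rep <- revert_to_uca(ann, demo_db, mode = "replacement_only")
    vj_all <- u_all$reverted_positions
    vj_all <- vj_all[vj_all$source %in% c("V", "J"), ]
    vj_rep <- u_rep$reverted_positions
    vj_rep <- vj_rep[vj_rep$source %in% c("V", "J"), ]
    expect_equal(nrow(vj_all), length(eff))
    expect_equal(nrow(vj_rep), sum(eff == "replacement", na.rm = TRUE))
    checked <- checked + 1L
    if (checked >= 5L) break
  }
  expect_gte(checked, 1L)
})

test_that("reversion is idempotent and lowers the mutation count", {
  mem <- small_sim$truth[small_sim$truth$compartment == "memory", ][1:8, ]
  for (i in seq_len(nrow(mem))) {
    ann <- annotate(mem$sequence[i], demo_db, mem$sequence_id[i])
    u1 <- revert_to_uca(ann, demo_db)
    ann_u <- annotate(u1$uca_seq, demo_db, "uca")
    u2 <- revert_to_uca(ann_u, demo_db)
    expect_identical(u2$uca_seq, u1$uca_seq)
    expect_lte(ann_u$mutation_count_total, ann$mutation_count_total)
    if (ann$mutation_count_total > 0)
      expect_lt(ann_u$mutation_count_total, ann$mutation_count_total)
  }
})

test_that("uca_report aggregates by source and ignores input order", {
  mem <- small_sim$truth[small_sim$truth$compartment == "memory", ][1:10, ]
  anns <- annotate_batch(setNames(mem$sequence, mem$sequence_id), demo_db)
  ucas <- lapply(anns, revert_to_uca, db = demo_db)
  rep1 <- uca_report(ucas)
  rep2 <- uca_report(rev(ucas))
  expect_identical(rep1, rep2)
  expect_equal(rep1$reverted_total,
               rep1$reverted_v + rep1$reverted_d + rep1$reverted_j)

  naive <- small_sim$truth[small_sim$truth$compartment == "naive", ][1:5, ]
  anns0 <- annotate_batch(setNames(naive$sequence, naive$sequence_id),
                          demo_db)
  rep0 <- uca_report(lapply(anns0, revert_to_uca, db = demo_db))
  expect_true(all(rep0$reverted_total == 0))
})
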