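test_that("Fisher p-values match the independent enumeration oracle", {
  cases <- list(c(10, 3796, 0, 1920), c(0, 16, 5, 6), c(2, 14, 6, 5),
                c(3, 13, 4, 7), c(1, 1, 1, 1), c(0, 10, 0, 10),
                c(7, 0, 0, 7))
  for (cc in cases) {
    tab <- matrix(cc, 2, byrow = TRUE)
    expect_equal(fisher_exact_two_sided(tab),
                 fisher_enum_oracle(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-12)
  }
  # identical groups, and zero outcome margin conventions
  expect_equal(fisher_exact_two_sided(matrix(c(0, 10, 0, 10), 2,
                                             byrow = TRUE)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(0, 5, 0, 7), 2,
                                             byrow = TRUE)), 1)
})

test_that("Fisher p is invariant under simultaneous row and column swaps", {
  set.seed(77)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_two_sided(tab)
    expect_equal(fisher_exact_two_sided(tab[2:1, 2:1]), p,
                 tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("Fisher agrees with stats::fisher.test across random tables", {
  set.seed(88)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 20), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("reactive frequencies carry exact Clopper-Pearson bounds", {
  fr <- reactive_frequency(5, 20)
  # direct beta-quantile inversion oracle for the exact interval
  expect_equal(fr$ci_low, qbeta(0.025, 5, 16), tolerance = 1e-12)
  expect_equal(fr$ci_high, qbeta(0.975, 6, 15), tolerance = 1e-12)
  expect_true(fr$ci_low <= fr$proportion && fr$proportion <= fr$ci_high)

  zero <- reactive_frequency(0, 50)
  expect_equal(zero$proportion, 0)
  expect_equal(zero$ci_low, 0)
  expect_error(reactive_frequency(5, 0))
})

test_that("Clopper-Pearson coverage stays at or above nominal", {
  set.seed(314)
  for (p in c(0.01, 0.3)) {
    k <- rbinom(2000, 50, p)
    covered <- vapply(k, function(ki) {
      fr <- reactive_frequency(ki, 50)
      fr$ci_low <= p && p <= fr$ci_high
    }, TRUE)
    expect_gte(mean(covered), 0.95)
  }
})

test_that("Fisher type-I rate is conservative under the null", {
  set.seed(2718)
  rej <- vapply(1:1000, function(i) {
    k1 <- rbinom(1, 500, 0.01); k2 <- rbinom(1, 400, 0.01)
    tab <- matrix(c(k1, 500 - k1, k2, 400 - k2), 2, byrow = TRUE)
    fisher_exact_two_sided(tab) < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.07)
})

test_that("usage tables and V-J overlaps match a hand tally", {
  df <- data.frame(
    sequence_id = sprintf("s%d", 1:6),
    v_call = c("IGHV1-1*01", "IGHV1-1*01", "IGHV3-1*01",
               "IGHV1-1*01", "IGHV3-1*01", "IGHV4-1*01"),
    j_call = c("IGHJ1*01", "IGHJ2*01", "IGHJ1*01",
               "IGHJ1*01", "IGHJ1*01", "IGHJ3*01"),
    locus = rep("IGH", 6), stringsAsFactors = FALSE)
  grp <- c("A", "A", "A", "B", "B", "B")
  ut <- usage_tables(df, grp)
  expect_equal(unname(ut$groups$A$family["IGHV1"]), 2)
  expect_equal(unname(ut$groups$A$vj_pairs["IGHV1-1:IGHJ1"]), 1)
  # shared unique pairs: IGHV1-1:IGHJ1 and IGHV3-1:IGHJ1
  expect_equal(ut$overlap["A", "B"], 2)
  expect_equal(ut$overlap, t(ut$overlap))
  expect_setequal(ut$common, c("IGHV1-1:IGHJ1", "IGHV3-1:IGHJ1"))

  # disjoint usage: zero overlap
  df2 <- df; df2$v_call[4:6] <- "IGHV5-1*01"; df2$j_call[4:6] <- "IGHJ4*01"
  expect_equal(usage_tables(df2, grp)$overlap["A", "B"], 0)
})

test_that("V-family goodness of fit matches the direct Pearson formula", {
  obs <- c(IGHV1 = 7, IGHV3 = 4)
  ref <- c(IGHV3 = 0.569, IGHV1 = 0.431)
  got <- vh_family_gof(obs, ref)
  expected <- sum((obs - 11 * c(0.431, 0.569))^2 / (11 * c(0.431, 0.569)))
  expect_equal(got$statistic, expected, tolerance = 1e-12)
  expect_equal(got$df, 1)
  # permutation invariance of the statistic
  got2 <- vh_family_gof(obs[c(2, 1)], ref)
  expect_equal(got2$statistic, got$statistic, tolerance = 1e-12)
  # exact proportionality gives statistic 0, p 1
  null_fit <- vh_family_gof(c(IGHV1 = 431, IGHV3 = 569),
                            c(IGHV1 = 0.431, IGHV3 = 0.569))
  expect_equal(null_fit$statistic, 0, tolerance = 1e-12)
  expect_equal(null_fit$p_value, 1)
})

test_that("CDR3 features follow the residue charge rule", {
  df <- data.frame(sequence_id = c("a", "b", "c"),
                   cdr3_aa = c("GGGG", "RKDE", "RRK"),
                   productive = TRUE, stringsAsFactors = FALSE)
  feats <- cdr3_features(df)
  expect_equal(feats$length_aa, c(4, 4, 3))
  expect_equal(feats$net_charge, c(0, 0, 3))

  # random peptides vs per-residue summation oracle
  set.seed(12)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peps <- vapply(1:30, function(i)
    paste0(sample(aas, sample(5:18, 1), replace = TRUE), collapse = ""), "")
  got <- cdr3_features(data.frame(sequence_id = as.character(1:30),
                                  cdr3_aa = peps, productive = TRUE))
  oracle <- vapply(peps, function(p) {
    r <- strsplit(p, "")[[1]]
    sum(r %in% c("R", "K")) - sum(r %in% c("D", "E"))
  }, 0)
  expect_equal(got$net_charge, unname(oracle))
})

test_that("KD fold changes summarise as geometric means", {
  u <- c(a = 1e-7, b = 1e-6); m <- c(a = 1e-8, b = 1e-8)
  fc <- kd_fold_change(u, m)
  expect_equal(unname(fc$folds), c(10, 100))
  expect_equal(fc$mean_fold, sqrt(1000), tolerance = 1e-12)
  # identical pairs fold 1; scale invariance
  same <- kd_fold_change(c(x = 2e-9), c(x = 2e-9))
  expect_equal(unname(same$folds), 1)
  sc <- kd_fold_change(u * 3.7, m * 3.7)
  expect_equal(sc$folds, fc$folds)
  # non-binding ancestors are excluded and reported
  u2 <- c(a = NA, b = 1e-6)
  fc2 <- kd_fold_change(u2, m)
  expect_equal(fc2$excluded, "a")
  expect_equal(unname(fc2$mean_fold), 100)
})
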