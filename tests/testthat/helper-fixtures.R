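# Shared fixtures, built once per test run.

demo_db <- demo_germline_db()

mini_db_paths <- list(
  fasta = system.file("extdata", "synthetic_germline.fasta",
                      package = "bcrtol"),
  metadata = system.file("extdata", "synthetic_germline.tsv",
                         package = "bcrtol"))

# Small repertoire reused by several suites (seeded, so identical across
# test files).
small_sim <- simulate_repertoire(demo_db,
                                 sim_config(n_cells = 25, seed = 4021))

# A hand-rolled valid segment table for constructing toy databases.
toy_segments <- function() {
  rbind(
    data.frame(name = "IGHV-T*01", locus = "IGH", segment_type = "V",
               sequence = paste0(strrep("GCA", 40), "TGT", "GCGAGA"),
               anchor = 120L, reading_frame = 0L,
               stringsAsFactors = FALSE),
    data.frame(name = "IGHD-T*01", locus = "IGH", segment_type = "D",
               sequence = "GGTACAACTGGAACGAT", anchor = NA_integer_,
               reading_frame = NA_integer_, stringsAsFactors = FALSE),
    data.frame(name = "IGHJ-T*01", locus = "IGH", segment_type = "J",
               sequence = paste0("ACTACT", "TGG", strrep("GGC", 13)),
               anchor = 6L, reading_frame = 0L, stringsAsFactors = FALSE))
}

# Fisher enumeration oracle: exact two-sided minimum-likelihood p-value by
# direct enumeration of all margin-fixed tables via binomial coefficients.
# Independent of the package's dhyper-based implementation.
fisher_enum_oracle <- function(a, b, c, d, tol = 1e-10) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  if (k == 0 || (b + d) == 0 || r1 == 0 || r2 == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, k - x) / choose(N, k), 0)
  p_obs <- probs[match(a, xs)]
  sum(probs[probs <= p_obs * (1 + tol)])
}
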