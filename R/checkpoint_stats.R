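#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value under the minimum-likelihood two-sided convention: with
#' both margins fixed, the p-value is the sum of hypergeometric point
#' probabilities of every table whose probability does not exceed that of
#' the observed table. The comparison uses a relative tolerance of 1e-12 so
#' that exact ties are kept despite floating-point rounding. A zero margin
#' on the outcome columns returns p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = groups, columns =
#'   outcome yes/no), or the count `a` with `b`, `c`, `d` given separately.
#' @param b,c,d optional scalar counts when `tab` is given as `a`.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(matrix(c(10, 3796, 0, 1920), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, byrow = TRUE)
  if (!is.matrix(tab) || any(dim(tab) != 2L))
    stop_input("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(tab != round(tab)))
    stop_input("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (a + b + c + d == 0) stop_input("at least one margin must be positive")
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (k == 0 || b + d == 0 || r1 == 0 || r2 == 0) return(1)
  support <- max(0, k - r2):min(k, r1)
  p <- stats::dhyper(support, r1, r2, k)
  p_obs <- stats::dhyper(a, r1, r2, k)
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Reactive-cell frequency with exact confidence interval
#'
#' Proportion of reactive wells among screened cells, with exact 95%
#' Clopper-Pearson bounds (via [stats::binom.test()]).
#'
#' @param k reactive count; @param n screened count.
#' @param conf_level confidence level.
#' @return object of class `frequency_result` with fields k, n, proportion,
#'   ci_low, ci_high.
#' @examples
#' reactive_frequency(10, 3806)   # 0.26%
#' @export
reactive_frequency <- function(k, n, conf_level = 0.95) {
  if (n <= 0 || k < 0 || k > n) stop_input("need 0 <= k <= n, n > 0")
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  structure(list(k = k, n = n, proportion = k / n,
                 ci_low = ci[1], ci_high = ci[2],
                 conf_level = conf_level),
            class = "frequency_result")
}

#' @export
print.frequency_result <- function(x, ...) {
  cat(sprintf("%d of %d (%.2g%%), %g%% CI [%.3g%%, %.3g%%]\n",
              x$k, x$n, 100 * x$proportion, 100 * x$conf_level,
              100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Gene-usage tables and V-J pair overlaps across groups
#'
#' Per-group counts of V genes, V families, V-J gene pairs and kappa/lambda
#' light-chain usage, plus the pairwise (and, for three or more groups, the
#' common) overlap of unique V-J pairs.
#'
#' @param df AIRR-style data.frame with `v_call`, `j_call`, `locus`.
#' @param group character/factor of group labels, one per row of `df`.
#' @return list with per-group `gene`, `family`, `vj_pairs`,
#'   `kappa_lambda` tables, an `overlap` matrix of shared unique V-J pair
#'   counts, and `common` (pairs present in every group).
#' @export
usage_tables <- function(df, group) {
  if (nrow(df) != length(group)) stop_input("group length must match df")
  ok <- !is.na(df$v_call) & !is.na(df$j_call)
  df <- df[ok, , drop = FALSE]; group <- as.character(group)[ok]
  groups <- sort(unique(group))
  per_group <- lapply(setNames(groups, groups), function(g) {
    sub <- df[group == g, , drop = FALSE]
    list(gene = table(gene_of(sub$v_call)),
         family = table(family_of(sub$v_call)),
         vj_pairs = table(paste(gene_of(sub$v_call), gene_of(sub$j_call),
                                sep = ":")),
         kappa_lambda = table(factor(sub$locus,
                                     levels = c("IGH", "IGK", "IGL"))))
  })
  pair_sets <- lapply(per_group, function(x) names(x$vj_pairs))
  overlap <- outer(groups, groups, Vectorize(function(i, j)
    length(intersect(pair_sets[[i]], pair_sets[[j]]))))
  dimnames(overlap) <- list(groups, groups)
  common <- Reduce(intersect, pair_sets)
  list(groups = per_group, overlap = overlap, common = common)
}

#' Chi-square goodness of fit of V-family usage against reference
#' proportions
#'
#' Pearson goodness-of-fit of observed family counts against externally
#' supplied reference proportions (e.g. published bulk-repertoire VH family
#' frequencies), df = number of families - 1.
#'
#' @param observed named vector of family counts.
#' @param reference named vector of reference proportions summing to 1, in
#'   any order; names must cover `observed`.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
vh_family_gof <- function(observed, reference) {
  if (sum(observed) <= 0) stop_input("observed counts must be positive")
  if (abs(sum(reference) - 1) > 1e-8)
    stop_input("reference proportions must sum to 1")
  if (!is.null(names(observed))) {
    missing_fams <- setdiff(names(observed), names(reference))
    if (length(missing_fams))
      stop_input("reference lacks proportions for: ",
                 paste(missing_fams, collapse = ", "))
    reference <- reference[names(observed)]
    reference <- reference / sum(reference)
  }
  ht <- suppressWarnings(stats::chisq.test(observed, p = reference))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = ht$expected)
}

#' CDR3 amino-acid features
#'
#' Length and integer net charge at neutral pH of each productive CDR3:
#' arginine and lysine count +1, aspartate and glutamate -1, histidine 0.
#' The residue weights are exposed so other charge conventions can be
#' swapped in.
#'
#' @param annotations AIRR-style data.frame with `sequence_id`, `cdr3_aa`,
#'   `productive`, or a list of `bcr_annotation` objects.
#' @param charge_weights named numeric vector of per-residue charges.
#' @return data.frame (sequence_id, cdr3_aa, length_aa, net_charge).
#' @export
cdr3_features <- function(annotations,
                          charge_weights = c(R = 1, K = 1, D = -1, E = -1,
                                             H = 0)) {
  df <- if (is.data.frame(annotations)) annotations else
    airr_table(annotations)
  keep <- !is.na(df$cdr3_aa) & !is.na(df$productive) & df$productive
  df <- df[keep, , drop = FALSE]
  charge <- vapply(df$cdr3_aa, function(aa) {
    res <- strsplit(aa, "")[[1]]
    w <- charge_weights[res]
    sum(w, na.rm = TRUE)
  }, 0)
  data.frame(sequence_id = df$sequence_id, cdr3_aa = df$cdr3_aa,
             length_aa = nchar(df$cdr3_aa), net_charge = unname(charge),
             stringsAsFactors = FALSE)
}

#' Affinity fold-change between ancestor and memory antibodies
#'
#' Per-pair fold worsening of equilibrium affinity, `KD_uca / KD_memory`,
#' summarised by the geometric mean (folds are ratios; an arithmetic mean
#' option is provided). Pairs with a non-binding ancestor (`NA` KD) are
#' excluded and reported.
#'
#' @param kd_uca,kd_memory named molar KD vectors matched by antibody ID.
#' @param summary `"geometric"` (default) or `"arithmetic"`.
#' @return list with `folds` (named per-pair vector), `mean_fold`,
#'   `excluded` (antibody IDs with non-binding ancestor).
#' @export
kd_fold_change <- function(kd_uca, kd_memory,
                           summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  if (is.null(names(kd_uca)) || is.null(names(kd_memory)))
    stop_input("KD vectors must be named by antibody ID")
  ids <- intersect(names(kd_uca), names(kd_memory))
  if (!length(ids)) stop_input("no shared antibody IDs")
  u <- kd_uca[ids]; m <- kd_memory[ids]
  if (any(!is.na(u) & u <= 0) || any(!is.na(m) & m <= 0))
    stop_input("KD values must be positive")
  excluded <- ids[is.na(u) | is.na(m)]
  keep <- setdiff(ids, excluded)
  folds <- u[keep] / m[keep]
  mean_fold <- if (!length(folds)) NA_real_
  else if (summary == "geometric") exp(mean(log(folds)))
  else mean(folds)
  list(folds = folds, mean_fold = mean_fold, summary = summary,
       excluded = excluded)
}
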