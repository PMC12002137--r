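default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "bcrtol_out",
    germline = list(fasta = NULL, metadata = NULL, version_tag = NULL),
    simulate = list(enabled = TRUE, n_cells = 100L, trim_mean = 2,
                    n_insert_mean = 4, shm_rate_naive = 0,
                    shm_rate_memory = c(0.02, 0.06), clone_size_p = 0.5,
                    reactive_fraction = 0.005),
    annotate = list(enabled = TRUE, input_fasta = NULL),
    revert = list(enabled = TRUE, mode = "all_substitutions"),
    clones = list(enabled = TRUE, threshold = 0.85),
    stats = list(enabled = TRUE)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(base))
      stop_input("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]])))
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]), full)
    else base[key] <- list(user[[key]])   # keeps NULL values as NULL
  }
  base
}

#' Build a pipeline configuration
#'
#' Merges user settings over the package defaults; unknown keys are
#' rejected so typos fail loudly. The configuration round-trips through a
#' single YAML document.
#'
#' @param x a named list of overrides, a YAML file path, or `NULL` for the
#'   defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL) {
  user <- if (is.null(x)) list()
  else if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_input("configuration file not found: ", x)
    yaml::read_yaml(x)
  } else if (is.list(x)) x
  else stop_input("x must be a list, a YAML path, or NULL")
  cfg <- merge_config(default_pipeline_config(), user)
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration as YAML
#' @param cfg a `pipeline_config`; @param path output path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

log_msg <- function(...) message("[bcrtol] ", ...)

#' Run the sequence-analysis pipeline
#'
#' Executes the toggled stages in order — simulate, annotate, revert,
#' clones, stats — writing every intermediate as a file under
#' `cfg$out_dir` and returning a manifest of outputs with MD5 content
#' hashes. The run is deterministic under a fixed `cfg$seed`. Referenced
#' input files are checked before any stage runs; a stage failure aborts
#' the run. Progress is logged to the message stream (stderr), never mixed
#' into result files.
#'
#' @param cfg a `pipeline_config` (or anything [pipeline_config()]
#'   accepts).
#' @return data.frame manifest (file, md5), invisibly also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  cfg <- pipeline_config(unclass(cfg))
  # fail before any stage if referenced inputs are missing
  for (p in c(cfg$germline$fasta, cfg$germline$metadata,
              cfg$annotate$input_fasta))
    if (!is.null(p) && !file.exists(p))
      stop_input("configured input file not found: ", p)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("seed = ", cfg$seed)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  db <- if (!is.null(cfg$germline$fasta))
    load_germline_db(cfg$germline$fasta, cfg$germline$metadata)
  else demo_germline_db()
  if (!is.null(cfg$germline$version_tag))
    db$version_tag <- cfg$germline$version_tag
  log_msg("germline reference: ", db$version_tag, " (",
          nrow(db$segments), " segments)")

  seqs <- NULL; truth <- NULL
  if (isTRUE(cfg$simulate$enabled)) {
    sc <- do.call(sim_config,
                  c(cfg$simulate[setdiff(names(cfg$simulate), "enabled")],
                    list(seed = cfg$seed)))
    log_msg("simulate: n_cells = ", sc$n_cells, " per group x compartment")
    sim <- simulate_repertoire(db, sc)
    seqs <- sim$sequences; truth <- sim$truth
    fa <- file.path(cfg$out_dir, "repertoire.fasta")
    write_fasta(seqs, fa); emit(fa)
    tt <- file.path(cfg$out_dir, "truth.tsv")
    write.table(truth, tt, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(tt)
  } else if (!is.null(cfg$annotate$input_fasta)) {
    seqs <- read_fasta(cfg$annotate$input_fasta)
  }

  anns <- NULL; airr <- NULL
  if (isTRUE(cfg$annotate$enabled)) {
    if (is.null(seqs)) stop_input("annotate stage has no input sequences")
    log_msg("annotate: ", length(seqs), " sequences")
    anns <- annotate_batch(seqs, db)
    airr <- airr_table(anns)
    n_fail <- sum(vapply(anns, function(a) a$status != "ok", TRUE))
    if (n_fail) log_msg("annotate: ", n_fail, " record(s) failed")
    out <- file.path(cfg$out_dir, "annotations.airr.tsv")
    write_airr(airr, out, version_tag = db$version_tag); emit(out)
  }

  if (isTRUE(cfg$revert$enabled) && !is.null(anns)) {
    ok <- Filter(function(a) a$status == "ok", anns)
    log_msg("revert: ", length(ok), " annotated records, mode = ",
            cfg$revert$mode)
    ucas <- lapply(ok, revert_to_uca, db = db, mode = cfg$revert$mode)
    rep_tab <- uca_report(ucas)
    ix <- match(airr$sequence_id, rep_tab$sequence_id)
    airr$uca_sequence <- vapply(ucas, `[[`, "",
                                "uca_seq")[match(airr$sequence_id,
                                                 names(ok))]
    airr$uca_reverted_count <- rep_tab$reverted_total[ix]
    airr$uca_untouched_intervals <- vapply(ucas, function(u)
      paste(vapply(u$untouched_intervals,
                   function(iv) sprintf("%d-%d", iv[1], iv[2]), ""),
            collapse = ";"), "")[match(airr$sequence_id, names(ok))]
    out <- file.path(cfg$out_dir, "uca_report.tsv")
    write.table(rep_tab, out, sep = "\t", quote = FALSE,
                row.names = FALSE); emit(out)
  }

  if (isTRUE(cfg$clones$enabled) && !is.null(airr)) {
    cs <- partition_clones(airr, threshold = cfg$clones$threshold)
    log_msg("clones: ", length(unique(cs$assignments)), " clones")
    airr$clone_id <- unname(cs$assignments[airr$sequence_id])
    out <- file.path(cfg$out_dir, "clone_summary.tsv")
    write.table(clone_summary(cs), out, sep = "\t", quote = FALSE,
                row.names = FALSE); emit(out)
  }

  if (!is.null(airr)) {
    out <- file.path(cfg$out_dir, "annotations.airr.tsv")
    write_airr(airr, out, version_tag = db$version_tag)
    if (!out %in% outputs) emit(out)
  }

  if (isTRUE(cfg$stats$enabled) && !is.null(truth) && !is.null(airr)) {
    counts <- simulate_checkpoint_counts(truth)
    stats_out <- list(checkpoint_counts = counts)
    for (cm in unique(counts$compartment)) {
      sub <- counts[counts$compartment == cm, ]
      if (nrow(sub) == 2L) {
        tab <- matrix(c(sub$k_reactive[1],
                        sub$n_screened[1] - sub$k_reactive[1],
                        sub$k_reactive[2],
                        sub$n_screened[2] - sub$k_reactive[2]),
                      2, byrow = TRUE)
        stats_out[[paste0("fisher_p_", cm)]] <- fisher_exact_two_sided(tab)
      }
    }
    feats <- cdr3_features(airr)
    stats_out$cdr3_length_mean <- mean(feats$length_aa)
    stats_out$cdr3_charge_mean <- mean(feats$net_charge)
    heavy <- airr[!is.na(airr$locus) & airr$locus == "IGH", ]
    tr <- truth[match(heavy$sequence_id, truth$sequence_id), ]
    ut <- usage_tables(heavy, paste(tr$group, tr$compartment))
    stats_out$vj_pair_overlap <- ut$overlap
    out <- file.path(cfg$out_dir, "stats.json")
    jsonlite::write_json(stats_out, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    emit(out)
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  mf <- file.path(cfg$out_dir, "manifest.tsv")
  write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("done: ", nrow(manifest), " outputs")
  manifest
}
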