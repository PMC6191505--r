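# Pipeline orchestration: configuration, the end-to-end run, and the
# deterministic summary report.

#' Pipeline configuration
#'
#' Collects all inputs and tuning parameters of the preference pipeline.
#' Defaults mirror the analysis the package was built around: rarefaction to
#' 1,073 reads per sample, a strict >2,000-read abundance filter for per-OTU
#' reporting, 10,000 permutations for the preference statistics and 1,000
#' for the community-level tests.
#'
#' @param otu_table,metadata Input paths (see [read_sample_table()]).
#' @param output_dir Directory for result files (created if needed).
#' @param depth Rarefaction depth (reads per sample).
#' @param min_otu_reads Abundance threshold (strict) for per-OTU reporting.
#' @param n_perm_pref Permutations for d'/2DP.
#' @param n_perm_network Permutations for H2'/C-scores.
#' @param tail Tail of the permutation p-values.
#' @param seed Single integer seed; all randomness in the run flows from it.
#' @param abundance_basis Apply the abundance filter to `"post_rarefaction"`
#'   (default) or `"pre_rarefaction"` read totals.
#' @param transposed Set `TRUE` when the OTU table TSV is OTUs-as-rows.
#' @return Object of class `run_config`.
#' @export
run_config <- function(otu_table, metadata, output_dir,
                       depth = 1073, min_otu_reads = 2000,
                       n_perm_pref = 10000, n_perm_network = 1000,
                       tail = "upper", seed = 1,
                       abundance_basis = c("post_rarefaction",
                                           "pre_rarefaction"),
                       transposed = FALSE) {
  stopifnot(depth >= 1, min_otu_reads >= 0, n_perm_pref >= 2,
            n_perm_network >= 2)
  structure(list(otu_table = otu_table, metadata = metadata,
                 output_dir = output_dir, depth = depth,
                 min_otu_reads = min_otu_reads,
                 n_perm_pref = n_perm_pref,
                 n_perm_network = n_perm_network,
                 tail = match.arg(tail, c("upper", "lower", "two_sided")),
                 seed = as.integer(seed),
                 abundance_basis = match.arg(abundance_basis),
                 transposed = isTRUE(transposed)),
            class = "run_config")
}

pipeline_files <- c("species_matrix.tsv", "host_preferences.tsv",
                    "otu_preferences.tsv", "pair_2dp.tsv",
                    "network_stats.tsv", "run_manifest.json")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full preference pipeline
#'
#' Executes read -> rarefy -> binarize -> aggregate -> host/OTU/pair
#' preference analysis -> community-level tests, and writes
#' `species_matrix.tsv`, `host_preferences.tsv`, `otu_preferences.tsv`,
#' `pair_2dp.tsv`, `network_stats.tsv` and `run_manifest.json` (config,
#' package version, sub-seeds, input checksums) into the output directory.
#' Deterministic: identical config produces byte-identical outputs. On any
#' stage failure partial outputs are removed and the error names the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`table`,
#'   `species_matrix`, `preferences`, `network`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- file.path(config$output_dir, pipeline_files)
  on_fail_cleanup <- function() suppressWarnings(file.remove(outs[file.exists(outs)]))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      on_fail_cleanup()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sub_seeds <- with_local_seed(config$seed, sample.int(2147483646L, 3))

  raw <- stage("read", read_sample_table(config$otu_table, config$metadata,
                                         transposed = config$transposed))
  rare <- stage("rarefy", rarefy_counts(raw, depth = config$depth,
                                        seed = sub_seeds[1]))
  abundant <- if (config$abundance_basis == "post_rarefaction")
    filter_abundant_otus(rare, config$min_otu_reads)
  else
    filter_abundant_otus(raw, config$min_otu_reads)
  bin <- stage("binarize", binarize(rare))
  sm <- stage("aggregate", aggregate_to_species(bin))
  prefs <- stage("preferences",
                 host_and_otu_preferences(bin, n_perm = config$n_perm_pref,
                                          seed = sub_seeds[2],
                                          abundant_otus = abundant,
                                          tail = config$tail))
  net <- stage("community", community_level_test(bin,
                                                 n_perm = config$n_perm_network,
                                                 seed = sub_seeds[3],
                                                 tail = config$tail))

  manifest <- list(
    package = "sympref",
    version = as.character(utils::packageVersion("sympref")),
    config = unclass(config),
    sub_seeds = sub_seeds,
    input_checksums = as.list(tools::md5sum(c(config$otu_table,
                                              config$metadata))),
    n_samples_raw = length(raw$sample_ids),
    n_samples_rarefied = length(rare$sample_ids),
    n_hosts = length(sm$hosts),
    n_otus = length(sm$otus),
    n_abundant_otus = length(abundant))

  stage("write", {
    write_species_matrix(sm, outs[1])
    write_tsv(prefs$hosts, outs[2])
    write_tsv(prefs$otus, outs[3])
    write_tsv(prefs$pairs, outs[4])
    write_tsv(net$stats, outs[5])
    jsonlite::write_json(manifest, outs[6], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  invisible(list(table = rare, species_matrix = sm, preferences = prefs,
                 network = net, manifest = manifest))
}

#' Summarize a pipeline output directory
#'
#' Reports the fractions of host species and abundant OTUs with FDR q <
#' 0.05, pair counts (significant and strong, 2DP > 6), and the observed vs
#' null network statistics. Writes `summary.tsv` and `summary.json`
#' (field-for-field identical) into the directory.
#'
#' @param dir A directory written by [run_pipeline()].
#' @return The summary as a one-row data.frame (invisibly also written to
#'   disk).
#' @export
summarize_run <- function(dir) {
  need <- file.path(dir, c("host_preferences.tsv", "otu_preferences.tsv",
                           "pair_2dp.tsv", "network_stats.tsv"))
  for (f in need) if (!file.exists(f)) stop("missing pipeline output: ", f)
  hosts <- utils::read.delim(need[1])
  otus <- utils::read.delim(need[2])
  pairs <- utils::read.delim(need[3])
  net <- utils::read.delim(need[4])
  pick <- function(stat, col) {
    v <- net[[col]][net$statistic == stat]
    if (length(v)) v else NA_real_
  }
  frac <- function(x) if (length(x)) mean(x) else NA_real_
  out <- data.frame(
    n_hosts = nrow(hosts),
    frac_hosts_significant = frac(hosts$q_fdr < 0.05),
    n_otus = nrow(otus),
    frac_otus_significant = frac(otus$q_fdr < 0.05),
    n_pairs = nrow(pairs),
    n_pairs_significant = sum(pairs$q_fdr < 0.05),
    n_strong_pairs = sum(pairs$strong),
    h2_prime_observed = pick("h2_prime", "observed"),
    h2_prime_null_mean = pick("h2_prime", "null_mean"),
    h2_prime_null_sd = pick("h2_prime", "null_sd"),
    h2_prime_p = pick("h2_prime", "p_perm"),
    c_score_otus_observed = pick("c_score_otus", "observed"),
    c_score_otus_null_mean = pick("c_score_otus", "null_mean"),
    c_score_hosts_observed = pick("c_score_hosts", "observed"),
    c_score_hosts_null_mean = pick("c_score_hosts", "null_mean"))
  write_tsv(out, file.path(dir, "summary.tsv"))
  jsonlite::write_json(as.list(out), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}
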