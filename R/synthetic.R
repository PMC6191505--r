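# Synthetic community generator: sample x OTU tables with known (tunable)
# host-preference structure and exact exchangeable nulls, emulating the data
# regime of a regional ectomycorrhizal root-tip survey: tens of host species,
# a handful of samples per species, ~1,000 reads per sample after rarefaction
# and a long-tailed OTU rank-abundance distribution in which most OTUs occur
# in only a few samples.

#' Parameters of a synthetic community
#'
#' @param n_hosts Number of host species (default 61).
#' @param samples_per_host Samples per host species (default 5).
#' @param n_otus Number of OTUs (default 2000).
#' @param depth Reads per sample (default 1073).
#' @param theta Specialization strength in \[0, 1\]: each host's OTU profile
#'   is the mixture `(1 - theta) * base_profile + theta * uniform(preferred
#'   set)`. `theta = 0` is an exact label-exchangeable null; `theta = 1`
#'   confines every host to its preferred OTUs.
#' @param n_preferred Preferred OTUs per host (default 5).
#' @param overlap Fraction of the preferred block shared between consecutive
#'   hosts, in \[0, 1): 0 gives disjoint blocks; larger values emulate
#'   related hosts sharing symbionts.
#' @param tail_exponent Exponent of the rank-frequency base profile
#'   `rank^(-tail_exponent)` (default 1.5, a long-tailed log-series-like
#'   shape).
#' @param seed Integer seed.
#' @return Object of class `synthetic_truth` holding all parameters, the
#'   `base_profile` (simplex vector) and `preferred_otus` (list of OTU ids
#'   per host; blocks are carved from the rare tail of the base profile so
#'   that preference is expressed as host-specific taxa rather than as extra
#'   weight on community-wide dominants).
#' @export
synthetic_truth <- function(n_hosts = 61, samples_per_host = 5,
                            n_otus = 2000, depth = 1073, theta = 0.3,
                            n_preferred = 5, overlap = 0,
                            tail_exponent = 1.5, seed = 1) {
  stopifnot(n_hosts >= 1, samples_per_host >= 1, n_otus >= 2, depth >= 1,
            theta >= 0, theta <= 1, overlap >= 0, overlap < 1)
  if (theta > 0 && n_preferred < 1)
    stop("theta > 0 requires a non-empty preferred-OTU set per host")
  step <- max(1, round(n_preferred * (1 - overlap)))
  if ((n_hosts - 1) * step + n_preferred > n_otus)
    stop("n_otus too small for ", n_hosts, " preferred blocks of ",
         n_preferred, " (step ", step, ")")
  otu_ids <- sprintf("otu%04d", seq_len(n_otus))
  host_ids <- sprintf("host%02d", seq_len(n_hosts))
  base <- seq_len(n_otus)^(-tail_exponent)
  base <- base / sum(base)
  # Preferred blocks are allocated from the rare tail of the base profile:
  # host-specific symbionts are modeled as taxa outside the shared background
  # pool. Blocks carved out of the ubiquitous core would be invisible to
  # presence/absence statistics (every host carries those OTUs through base
  # reads), making theta non-identifiable.
  preferred <- lapply(seq_len(n_hosts), function(i) {
    otu_ids[n_otus - (i - 1) * step - n_preferred + seq_len(n_preferred)]
  })
  names(preferred) <- host_ids
  structure(list(n_hosts = n_hosts, samples_per_host = samples_per_host,
                 n_otus = n_otus, depth = depth, theta = theta,
                 n_preferred = n_preferred, overlap = overlap,
                 tail_exponent = tail_exponent, seed = seed,
                 host_ids = host_ids, otu_ids = otu_ids,
                 base_profile = stats::setNames(base, otu_ids),
                 preferred_otus = preferred),
            class = "synthetic_truth")
}

#' Generate a synthetic community
#'
#' Draws each sample's counts multinomially (`depth` trials) from its host's
#' profile `(1 - theta) * base_profile + theta * uniform(preferred set)`.
#' Fully reproducible from the seed stored in `truth`.
#'
#' @param truth A [synthetic_truth()] (or arguments forwarded to it).
#' @param ... Passed to [synthetic_truth()] when `truth` is missing.
#' @return List with `table` (a [sample_table()]; every sample sums to
#'   `depth`) and `truth`.
#' @export
generate_community <- function(truth = NULL, ...) {
  if (is.null(truth)) truth <- synthetic_truth(...)
  stopifnot(inherits(truth, "synthetic_truth"))
  counts <- with_local_seed(truth$seed, {
    blocks <- lapply(seq_len(truth$n_hosts), function(i) {
      u <- numeric(truth$n_otus)
      if (truth$theta > 0)
        u[match(truth$preferred_otus[[i]], truth$otu_ids)] <-
          1 / truth$n_preferred
      p <- (1 - truth$theta) * truth$base_profile + truth$theta * u
      t(stats::rmultinom(truth$samples_per_host, truth$depth, p))
    })
    do.call(rbind, blocks)
  })
  host_of <- rep(truth$host_ids, each = truth$samples_per_host)
  rownames(counts) <- paste0(host_of, "_s",
                             rep(seq_len(truth$samples_per_host),
                                 truth$n_hosts))
  colnames(counts) <- truth$otu_ids
  list(table = sample_table(counts, host_of), truth = truth)
}

#' Generate a label-exchangeable null community
#'
#' Equivalent to [generate_community()] with `theta = 0`: all hosts share
#' one OTU profile, so the sample -> host assignment is exchangeable by
#' construction. Used for calibration suites.
#'
#' @param n_hosts,samples_per_host,n_otus,depth,seed As in
#'   [synthetic_truth()].
#' @return A [sample_table()].
#' @export
generate_null_community <- function(n_hosts = 20, samples_per_host = 5,
                                    n_otus = 200, depth = 500, seed = 1) {
  generate_community(synthetic_truth(
    n_hosts = n_hosts, samples_per_host = samples_per_host,
    n_otus = n_otus, depth = depth, theta = 0, seed = seed))$table
}

#' Write a synthetic community to disk
#'
#' Writes the OTU table TSV, metadata TSV and a `truth.json` with all
#' generator parameters and preferred sets.
#'
#' @param community Result of [generate_community()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("otu_table.tsv", "metadata.tsv", "truth.json"))
  write_sample_table(community$table, paths[1], paths[2])
  tr <- community$truth
  jsonlite::write_json(
    list(n_hosts = tr$n_hosts, samples_per_host = tr$samples_per_host,
         n_otus = tr$n_otus, depth = tr$depth, theta = tr$theta,
         n_preferred = tr$n_preferred, overlap = tr$overlap,
         tail_exponent = tr$tail_exponent, seed = tr$seed,
         preferred_otus = tr$preferred_otus),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
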