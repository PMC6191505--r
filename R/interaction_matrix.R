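# Normalization, binarization and aggregation of sample-level OTU data into
# the host-species x OTU incidence matrix the preference statistics consume.

#' Rarefy read counts to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads, dropping (and logging) samples whose total falls below the depth.
#' Each sample draws from its own substream derived from `(seed, sample_id)`,
#' so results are reproducible and independent of sample order.
#'
#' @param table A [sample_table()] of raw read counts.
#' @param depth Target reads per sample (default 1073, the depth used for the
#'   ectomycorrhizal root-tip survey this package was built around).
#' @param seed Integer seed.
#' @return A rarefied [sample_table()]; every retained row sums to `depth`.
#' @export
rarefy_counts <- function(table, depth = 1073, seed = 1) {
  stopifnot(depth >= 1)
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep))
    stop("all samples fall below the rarefaction depth of ", depth)
  for (id in table$sample_ids[!keep])
    sym_log("dropping sample '", id, "' with ", totals[id],
            " reads (< depth ", depth, ")")
  counts <- table$counts[keep, , drop = FALSE]
  nj <- ncol(counts)
  out <- counts
  for (s in seq_len(nrow(counts))) {
    tot <- sum(counts[s, ])
    if (tot == depth) next
    reads <- rep.int(seq_len(nj), counts[s, ])
    drawn <- with_local_seed(substream_seed(seed, rownames(counts)[s]),
                             sample(reads, depth))
    out[s, ] <- tabulate(drawn, nbins = nj)
  }
  sample_table(out, table$host_of[rownames(out)])
}

#' Binarize counts to presence/absence
#'
#' @param table A [sample_table()].
#' @return A [sample_table()] whose cells are 1 where reads were present and
#'   0 elsewhere. Idempotent.
#' @export
binarize <- function(table) {
  sample_table((table$counts > 0) * 1, table$host_of)
}

is_binary <- function(table) all(table$counts %in% c(0, 1))

#' Aggregate samples into the species-level matrix
#'
#' Builds the host-species x OTU matrix whose cell (i, j) counts the number
#' of samples of host i in which OTU j occurred. All-zero rows and columns
#' are removed (they are undefined for the specialization indices) with a
#' logged warning. Host and OTU orderings are stable: first appearance for
#' hosts, input column order for OTUs.
#'
#' @param table A [sample_table()], normally binarized.
#' @param binary If `TRUE` (default), cells are treated as presence/absence
#'   (counts are binarized before tallying); if `FALSE`, raw reads are summed.
#' @return An object of class `species_matrix`: list with `hosts`, `otus`,
#'   `a` (the matrix), `row_totals`, `col_totals`, `m` (grand total) and
#'   `samples_per_host`.
#' @export
aggregate_to_species <- function(table, binary = TRUE) {
  if (nrow(table$counts) == 0) stop("no samples to aggregate")
  x <- table$counts
  if (binary) x <- (x > 0) * 1
  hosts <- unique(unname(table$host_of))
  z <- rowsum(x, group = unname(table$host_of))
  z <- z[hosts, , drop = FALSE]
  zero_r <- rowSums(z) == 0
  zero_c <- colSums(z) == 0
  if (any(zero_r)) {
    warning("dropping all-zero host rows: ",
            paste(rownames(z)[zero_r], collapse = ", "))
    z <- z[!zero_r, , drop = FALSE]
    hosts <- hosts[!zero_r]
  }
  if (any(zero_c)) {
    warning("dropping ", sum(zero_c), " all-zero OTU columns")
    z <- z[, !zero_c, drop = FALSE]
  }
  species_matrix(z, samples_per_host = table(factor(unname(table$host_of),
                                                   levels = hosts)))
}

species_matrix <- function(a, samples_per_host = NULL) {
  a <- as.matrix(a)
  structure(list(hosts = rownames(a), otus = colnames(a), a = a,
                 row_totals = rowSums(a), col_totals = colSums(a),
                 m = sum(a), samples_per_host = samples_per_host),
            class = "species_matrix")
}

#' @export
print.species_matrix <- function(x, ...) {
  cat(sprintf("species_matrix: %d hosts x %d OTUs, %s interaction records\n",
              length(x$hosts), length(x$otus), format(x$m, big.mark = ",")))
  invisible(x)
}

as_interaction_matrix <- function(x) {
  if (inherits(x, "species_matrix")) x$a else as.matrix(x)
}

#' Identify abundant OTUs by total reads
#'
#' Returns the ids of OTUs whose total read count strictly exceeds
#' `min_reads`. Used to restrict per-OTU preference reporting (host
#' preferences of rare symbionts cannot be estimated reliably), never to
#' restrict matrix construction.
#'
#' @param table A [sample_table()] of read counts (pre-binarization).
#' @param min_reads Threshold; an OTU with exactly `min_reads` reads is
#'   excluded (strict inequality). Default 2000.
#' @return Character vector of OTU ids.
#' @export
filter_abundant_otus <- function(table, min_reads = 2000) {
  table$otu_ids[table$otu_total_reads > min_reads]
}

#' Write a species-level matrix as TSV
#'
#' @param mat A `species_matrix` (or plain matrix).
#' @param path Output path; rows = host species, header = OTU ids.
#' @return Invisibly, `mat`.
#' @export
write_species_matrix <- function(mat, path) {
  a <- as_interaction_matrix(mat)
  df <- data.frame(host_species = rownames(a), a, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}
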