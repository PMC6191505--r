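# SampleTable: per-sample OTU read counts plus the sample -> host-species map.

#' Construct a sample table
#'
#' A `sample_table` bundles a non-negative integer count matrix (rows =
#' samples, columns = OTUs) with the assignment of every sample to a host
#' species. It is the raw input of the preference pipeline.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   sample ids as row names and OTU ids as column names.
#' @param host_of Character vector of host-species labels, either named by
#'   sample id or in row order of `counts`.
#' @return An object of class `sample_table` with elements `counts`,
#'   `sample_ids`, `otu_ids`, `host_of` (named by sample) and
#'   `otu_total_reads` (per-OTU column sums).
#' @export
sample_table <- function(counts, host_of) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample ids as row names and OTU ids as column names")
  storage.mode(counts) <- "double"
  if (is.null(names(host_of))) {
    if (length(host_of) != nrow(counts))
      stop("host_of must be named by sample id or match the number of samples")
    names(host_of) <- rownames(counts)
  }
  host_of <- host_of[rownames(counts)]
  tab <- structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         otu_ids = colnames(counts),
         host_of = host_of,
         otu_total_reads = colSums(counts)),
    class = "sample_table")
  validate_sample_table(tab)
  tab
}

validate_sample_table <- function(x) {
  counts <- x$counts
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of missing values")
  if (any(counts != floor(counts)))
    stop("counts must be integral read counts")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  missing_host <- rownames(counts)[is.na(x$host_of) | x$host_of == ""]
  if (length(missing_host))
    stop("samples without a host-species label: ",
         paste(missing_host, collapse = ", "))
  if (!isTRUE(all.equal(unname(x$otu_total_reads), unname(colSums(counts)))))
    stop("otu_total_reads out of sync with counts")
  invisible(x)
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("sample_table: %d samples x %d OTUs, %d host species, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$host_of)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Read a sample-by-OTU table with its metadata
#'
#' Reads a tab-separated OTU table (header row of OTU ids, first column of
#' sample ids) and a metadata table with columns `sample_id` and
#' `host_species`, and returns a validated [sample_table()]. A dense
#' BIOM-format JSON file (`.biom`) is also accepted for the OTU table, via
#' the biomformat package.
#'
#' @param otu_table_path Path to the OTU table (TSV or dense BIOM JSON).
#' @param metadata_path Path to the TSV metadata (`sample_id`, `host_species`).
#' @param transposed Set `TRUE` when the TSV is written OTUs-as-rows (both
#'   dialects are common); the matrix is transposed after reading.
#' @return A [sample_table()]. OTUs with zero total reads are retained;
#'   downstream steps decide their fate.
#' @export
read_sample_table <- function(otu_table_path, metadata_path, transposed = FALSE) {
  if (!file.exists(otu_table_path)) stop("OTU table not found: ", otu_table_path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  if (grepl("\\.biom$", otu_table_path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom input requires the biomformat package")
    b <- biomformat::read_biom(otu_table_path)
    counts <- t(as(biomformat::biom_data(b), "matrix"))  # biom stores OTUs x samples
  } else {
    raw <- tryCatch(
      utils::read.table(otu_table_path, header = TRUE, sep = "\t",
                        check.names = FALSE, quote = "", comment.char = "",
                        stringsAsFactors = FALSE, fill = FALSE),
      error = function(e) stop("malformed OTU table '", otu_table_path,
                               "': ", conditionMessage(e), call. = FALSE))
    if (ncol(raw) < 2) stop("OTU table must have a sample-id column plus OTU columns")
    ids <- as.character(raw[[1]])
    mat <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(mat)) stop("OTU table contains non-numeric count cells")
    rownames(mat) <- ids
    counts <- mat
    if (transposed) counts <- t(counts)
  }
  meta <- utils::read.table(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "host_species")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  orphans <- setdiff(rownames(counts), meta$sample_id)
  if (length(orphans))
    stop("samples missing from metadata: ", paste(orphans, collapse = ", "))
  host_of <- stats::setNames(as.character(meta$host_species),
                             as.character(meta$sample_id))[rownames(counts)]
  sample_table(counts, host_of)
}

#' Write a sample table back to TSV
#'
#' Inverse of [read_sample_table()]; integer counts are written losslessly.
#'
#' @param table A [sample_table()].
#' @param otu_table_path,metadata_path Output paths.
#' @return Invisibly, the table.
#' @export
write_sample_table <- function(table, otu_table_path, metadata_path) {
  df <- data.frame(sample_id = table$sample_ids,
                   table$counts, check.names = FALSE)
  utils::write.table(df, otu_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = table$sample_ids,
                     host_species = unname(table$host_of))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
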