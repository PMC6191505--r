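# Shared fixtures and independent oracle code for the test suite. Everything
# is generated in code; no data files.

# A tiny hand-written table: 3 samples (2 hosts) x 2 OTUs.
tiny_table <- function() {
  counts <- matrix(c(5, 0,
                     2, 3,
                     0, 7), nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"), c("otuA", "otuB")))
  sample_table(counts, c(s1 = "oak", s2 = "oak", s3 = "beech"))
}

write_tiny_files <- function(table, dir = tempfile("fixdir")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  otu <- file.path(dir, "otu.tsv")
  meta <- file.path(dir, "meta.tsv")
  write_sample_table(table, otu, meta)
  list(otu = otu, meta = meta, dir = dir)
}

random_count_table <- function(n_samples, n_otus, n_hosts, seed,
                               max_count = 5) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, 1.2), n_samples, n_otus,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("o%02d", seq_len(n_otus))))
  counts[counts > max_count] <- max_count
  counts[rowSums(counts) == 0, 1] <- 1  # no empty samples
  hosts <- sprintf("h%02d", sample(n_hosts, n_samples, replace = TRUE))
  sample_table(counts, hosts)
}

# --------------------------------------------------------------------------
# Independent oracles (brute force / closed form), kept free of package
# internals.

# All non-negative integer matrices with the given row and column sums
# (shapes up to 3x3): enumerate the free (n-1) x (J-1) block and complete.
enum_matrices <- function(r, s) {
  n <- length(r)
  J <- length(s)
  stopifnot(sum(r) == sum(s), n <= 3, J <= 3)
  if (n == 1) return(list(matrix(s, 1, J)))
  if (J == 1) return(list(matrix(r, n, 1)))
  grids <- list()
  for (i in seq_len(n - 1)) for (j in seq_len(J - 1))
    grids[[paste(i, j)]] <- 0:min(r[i], s[j])
  combos <- as.matrix(expand.grid(grids))
  out <- list()
  for (k in seq_len(nrow(combos))) {
    X <- matrix(0, n, J)
    X[seq_len(n - 1), seq_len(J - 1)] <- matrix(combos[k, ], n - 1, J - 1,
                                                byrow = TRUE)
    X[seq_len(n - 1), J] <- r[seq_len(n - 1)] - rowSums(X[seq_len(n - 1),
                                                          seq_len(J - 1),
                                                          drop = FALSE])
    X[n, ] <- s - colSums(X[seq_len(n - 1), , drop = FALSE])
    if (all(X >= 0)) out[[length(out) + 1]] <- X
  }
  out
}

# All vectors of `k` parts, each in 1..max_part.
all_compositions <- function(k, max_part) {
  if (k == 1) return(matrix(seq_len(max_part), ncol = 1))
  sub <- all_compositions(k - 1, max_part)
  do.call(rbind, lapply(seq_len(max_part),
                        function(a) cbind(a, sub, deparse.level = 0)))
}

oracle_entropy <- function(X) {
  m <- sum(X)
  p <- X[X > 0] / m
  -sum(p * log(p))
}

oracle_d <- function(x, col_totals, m) {
  A <- sum(x)
  p <- x[x > 0] / A
  q <- col_totals[x > 0] / m
  sum(p * log(p / q))
}

# Brute-force double-loop species tally (no dropping of empty lines).
oracle_aggregate <- function(table) {
  hosts <- unique(unname(table$host_of))
  tally <- matrix(0, length(hosts), ncol(table$counts),
                  dimnames = list(hosts, colnames(table$counts)))
  for (i in hosts)
    for (j in seq_len(ncol(table$counts)))
      for (s in seq_len(nrow(table$counts)))
        if (unname(table$host_of)[s] == i && table$counts[s, j] > 0)
          tally[i, j] <- tally[i, j] + 1
  tally
}
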