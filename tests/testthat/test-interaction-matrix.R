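test_that("reading a toy table round-trips and validates the metadata join", {
  tab <- tiny_table()
  f <- write_tiny_files(tab)
  got <- read_sample_table(f$otu, f$meta)
  expect_identical(dim(got$counts), c(3L, 2L))
  expect_equal(got$counts, tab$counts)
  expect_equal(got$host_of, tab$host_of)

  # round trip again: write -> read restores an identical counts matrix
  f2 <- write_tiny_files(got)
  expect_equal(read_sample_table(f2$otu, f2$meta)$counts, tab$counts)

  # metadata missing one sample names the orphan
  meta <- read.delim(f$meta)
  write.table(meta[meta$sample_id != "s2", ], f$meta, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_sample_table(f$otu, f$meta), "s2")
})

test_that("dense BIOM-JSON OTU tables are accepted", {
  tab <- tiny_table()
  path <- tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(t(tab$counts)), path)
  f <- write_tiny_files(tab)
  got <- read_sample_table(path, f$meta)
  expect_equal(got$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
})

test_that("malformed input is rejected with an informative error", {
  f <- write_tiny_files(tiny_table())
  lines <- readLines(f$otu)
  writeLines(c(lines, "ragged\t1"), f$otu)
  expect_error(read_sample_table(f$otu, f$meta), "malformed")

  # duplicate sample row in the count table itself
  tab <- tiny_table()
  counts <- tab$counts[c(1, 1, 2, 3), ]
  expect_error(sample_table(counts, c("oak", "oak", "oak", "beech")),
               "duplicate")
  expect_error(sample_table(tab$counts * -1, tab$host_of), "non-negative")
  expect_error(sample_table(tab$counts + 0.5, tab$host_of), "integral")
})

test_that("rarefaction hits the target depth exactly and drops shallow samples", {
  set.seed(1)
  counts <- matrix(rpois(5 * 20, 80), 5, 20,
                   dimnames = list(paste0("s", 1:5), paste0("o", 1:20)))
  counts[5, ] <- c(65, rep(0, 19))  # a 65-read sample, as shallow ones occur
  tab <- sample_table(counts, rep(c("hA", "hB"), c(3, 2)))

  expect_message(r1 <- rarefy_counts(tab, depth = 1073, seed = 3),
                 "dropping sample 's5'")
  expect_false("s5" %in% r1$sample_ids)

  r2 <- suppressMessages(rarefy_counts(tab, depth = 500, seed = 3))
  expect_true(all(rowSums(r2$counts) == 500))
  # reproducible for a fixed seed, bit for bit
  r3 <- suppressMessages(rarefy_counts(tab, depth = 500, seed = 3))
  expect_identical(r2$counts, r3$counts)
  # a different seed still lands every row exactly on the depth
  r4 <- suppressMessages(rarefy_counts(tab, depth = 500, seed = 4))
  expect_false(identical(r2$counts, r4$counts))
  expect_true(all(rowSums(r4$counts) == 500))

  # a sample at exactly the target depth passes through unchanged
  exact <- sample_table(matrix(c(3, 2), 1, 2,
                               dimnames = list("sx", c("o1", "o2"))), "hA")
  expect_identical(rarefy_counts(exact, depth = 5, seed = 1)$counts,
                   exact$counts)

  # subsampling never invents reads in empty cells
  expect_true(all(r2$counts[counts[1:4, ] == 0] == 0))

  expect_error(rarefy_counts(tab, depth = 10^6, seed = 1), "below")
})

test_that("rarefaction does not depend on sample order", {
  set.seed(7)
  counts <- matrix(rpois(4 * 10, 60), 4, 10,
                   dimnames = list(paste0("s", 1:4), paste0("o", 1:10)))
  tab <- sample_table(counts, rep("h", 4))
  flipped <- sample_table(counts[4:1, ], rep("h", 4))
  a <- rarefy_counts(tab, depth = 300, seed = 9)
  b <- rarefy_counts(flipped, depth = 300, seed = 9)
  expect_equal(a$counts, b$counts[rownames(a$counts), ])
})

test_that("binarization is idempotent and conserves presences", {
  tab <- tiny_table()
  b1 <- binarize(tab)
  expect_true(all(b1$counts %in% c(0, 1)))
  expect_identical(binarize(b1)$counts, b1$counts)
  expect_equal(sum(b1$counts), sum(tab$counts > 0))
  expect_equal(b1$counts["s1", "otuA"], 1)
  expect_equal(b1$counts["s1", "otuB"], 0)
})

test_that("species aggregation equals the brute-force tally on random tables", {
  for (seed in 1:100) {
    tab <- binarize(random_count_table(10, 20, 4, seed))
    want <- oracle_aggregate(tab)
    want <- want[rowSums(want) > 0, colSums(want) > 0, drop = FALSE]
    got <- suppressWarnings(aggregate_to_species(tab))
    expect_equal(got$a, want)
    # conservation: row and column totals both sum to the grand total
    expect_equal(sum(got$row_totals), got$m)
    expect_equal(sum(got$col_totals), got$m)
    # a cell never exceeds the number of samples of its host
    expect_true(all(got$a <= as.vector(got$samples_per_host[rownames(got$a)])))
  }
})

test_that("aggregation counts samples per host-OTU pair and drops empty lines", {
  counts <- matrix(c(1, 0,
                     1, 0,
                     1, 0,
                     0, 0), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), c("x", "y")))
  counts[4, 1] <- 1
  tab <- sample_table(counts, c("A", "A", "B", "B"))
  expect_warning(sm <- aggregate_to_species(tab), "all-zero OTU")
  expect_equal(sm$a["A", "x"], 2)
  expect_equal(sm$a["B", "x"], 2)
  expect_false("y" %in% sm$otus)
  expect_error(aggregate_to_species(sample_table(counts[0, , drop = FALSE],
                                                 character(0))))
})

test_that("the abundance filter applies a strict read threshold", {
  counts <- matrix(c(2000, 2001, 1), 1, 3,
                   dimnames = list("s1", c("at", "above", "rare")))
  tab <- sample_table(counts, "h")
  expect_identical(filter_abundant_otus(tab, 2000), "above")
  expect_identical(filter_abundant_otus(tab, 0), c("at", "above", "rare"))
  expect_length(filter_abundant_otus(tab, 10^7), 0)
})
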