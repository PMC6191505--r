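test_that("label shuffling permutes assignments without touching content", {
  tab <- binarize(random_count_table(12, 8, 3, seed = 2))
  set.seed(10)
  shuf <- shuffle_host_labels(tab)
  expect_identical(shuf$counts, tab$counts)
  expect_identical(sort(unname(shuf$host_of)), sort(unname(tab$host_of)))
})

test_that("label shuffles are uniform over orderings", {
  counts <- diag(4)
  dimnames(counts) <- list(paste0("s", 1:4), paste0("o", 1:4))
  tab <- sample_table(counts, c("A", "B", "C", "D"))
  set.seed(123)
  n <- 10000
  seen <- character(n)
  for (i in seq_len(n))
    seen[i] <- paste(shuffle_host_labels(tab)$host_of, collapse = "")
  tally <- table(seen)
  expect_length(tally, 24)
  expect_gt(chisq.test(tally)$p.value, 0.001)
})

test_that("null ensembles are deterministic, prefix-stable and well-formed", {
  tab <- binarize(random_count_table(10, 6, 3, seed = 4))
  # an invariant statistic has zero spread under the null
  ens_m <- build_null_ensemble(tab, function(sm) sm$m, n_perm = 20, seed = 5)
  expect_equal(unname(ens_m$sd), 0)
  expect_true(all(ens_m$draws == ens_m$draws[1]))

  stat <- function(sm) stats::setNames(sm$row_totals, sm$hosts)
  e1 <- build_null_ensemble(tab, stat, n_perm = 10, seed = 9)
  e2 <- build_null_ensemble(tab, stat, n_perm = 10, seed = 9)
  expect_identical(e1$draws, e2$draws)
  # extending n_perm leaves the first draws unchanged
  e3 <- build_null_ensemble(tab, stat, n_perm = 30, seed = 9)
  expect_identical(e3$draws[1:10, ], e1$draws)
})

test_that("the null mean of a pair count matches the exhaustive expectation", {
  # 2 samples, 2 hosts: sample s1 carries OTU x, s2 carries OTU y. The two
  # label assignments are equally likely, so E[a(A, x)] = 1/2 exactly.
  counts <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("x", "y")))
  tab <- sample_table(counts, c(s1 = "A", s2 = "B"))
  ens <- build_null_ensemble(tab, function(sm) sm$a["A", "x"],
                             n_perm = 2000, seed = 21)
  expect_equal(unname(ens$mean), 0.5, tolerance = 0.05)
  expect_true(all(ens$draws %in% c(0, 1)))
})

test_that("standardized scores center and scale against the null draws", {
  draws <- c(1, 2, 3)  # sample sd = 1
  expect_equal(standardized_score(4, draws), 2)
  expect_equal(standardized_score(2, draws), 0)
  expect_equal(standardized_score(mean(draws) + 2 * sd(draws), draws), 2)
  expect_true(is.na(standardized_score(5, rep(3, 10))))
  expect_error(standardized_score(1, c(2)), "at least 2")
})

test_that("add-one permutation p-values honour tails and ties", {
  draws <- seq_len(999)
  expect_equal(permutation_pvalue(1000, draws, "upper"), 1 / 1000)
  expect_equal(permutation_pvalue(0, draws, "upper"), 1)
  expect_equal(permutation_pvalue(0, draws, "lower"), 1 / 1000)
  expect_equal(permutation_pvalue(3, rep(3, 99), "upper"), 1)
  expect_equal(permutation_pvalue(500, draws, "two_sided"), 1)
  p_up <- permutation_pvalue(990, draws, "upper")
  expect_equal(permutation_pvalue(990, draws, "two_sided"), 2 * p_up)
})

test_that("Benjamini-Hochberg agrees with hand step-up computations", {
  expect_equal(benjamini_hochberg(0.04), 0.04)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(c(0.005, 0.04, 0.03, 0.9)),
               c(0.02, 0.16 / 3, 0.16 / 3, 0.9))
  expect_equal(benjamini_hochberg(c(0.2, 0.1, 0.05, 0.025)),
               c(0.2, 0.4 / 3, 0.1, 0.1))
  expect_equal(benjamini_hochberg(c(0.05, 0.05)), c(0.05, 0.05))
  # step-up output is non-decreasing in the p-value order
  set.seed(8)
  p <- runif(50)
  q <- benjamini_hochberg(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(benjamini_hochberg(c(0.5, 0)), "0, 1")
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("the streaming preference analysis matches the generic ensemble", {
  tab <- binarize(generate_community(synthetic_truth(
    n_hosts = 5, samples_per_host = 3, n_otus = 30, depth = 100,
    theta = 0.5, seed = 6))$table)
  n_perm <- 60
  seed <- 17
  pref <- host_and_otu_preferences(tab, n_perm = n_perm, seed = seed,
                                   families = "hosts")
  stat <- function(sm) {
    dp <- suppressWarnings(d_prime_all(sm, axis = "rows"))
    stats::setNames(dp$d_prime, dp$entity)
  }
  ens <- build_null_ensemble(tab, stat, n_perm = n_perm, seed = seed)
  obs <- stat(suppressWarnings(aggregate_to_species(tab)))
  hosts <- pref$hosts$entity
  expect_equal(pref$hosts$d_prime_observed, unname(obs[hosts]),
               tolerance = 1e-12)
  expect_equal(pref$hosts$standardized_d_prime,
               unname((obs[hosts] - ens$mean[hosts]) / ens$sd[hosts]),
               tolerance = 1e-9)
  want_p <- vapply(hosts, function(h)
    permutation_pvalue(obs[[h]], ens$draws[, h], "upper"), numeric(1))
  expect_equal(pref$hosts$p_perm, unname(want_p), tolerance = 1e-12)
})

test_that("fully private symbiont use yields positive preference everywhere", {
  com <- generate_community(synthetic_truth(
    n_hosts = 6, samples_per_host = 4, n_otus = 40, depth = 300,
    theta = 1, seed = 13))
  tab <- binarize(com$table)
  pref <- host_and_otu_preferences(tab, n_perm = 400, seed = 3)
  expect_true(all(pref$hosts$standardized_d_prime > 0))
  matched <- mapply(function(h, o) o %in% com$truth$preferred_otus[[h]],
                    pref$pairs$host, pref$pairs$otu)
  expect_true(all(pref$pairs$two_dp[matched & pref$pairs$n_observed > 0] > 0,
                  na.rm = TRUE))
  # determinism of the full result object
  pref2 <- host_and_otu_preferences(tab, n_perm = 400, seed = 3)
  expect_identical(pref, pref2)
})

test_that("community-level tests report coherent null summaries", {
  tab <- binarize(generate_community(synthetic_truth(
    n_hosts = 8, samples_per_host = 4, n_otus = 60, depth = 200,
    theta = 0.9, seed = 2))$table)
  ct <- community_level_test(tab, n_perm = 200, seed = 4)
  df <- ct$stats
  expect_setequal(df$statistic, c("h2_prime", "c_score_otus", "c_score_hosts"))
  for (i in seq_len(nrow(df))) {
    d <- ct$draws[, df$statistic[i]]
    expect_equal(df$null_mean[i], mean(d))
    expect_equal(df$null_sd[i], sd(d))
    expect_equal(df$z[i], (df$observed[i] - mean(d)) / sd(d))
  }
  # strong specialization: observed H2' above every null draw
  h2 <- df[df$statistic == "h2_prime", ]
  expect_true(all(ct$draws[, "h2_prime"] < h2$observed))
  expect_equal(h2$p_perm, 1 / 201)
})
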