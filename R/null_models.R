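# Shuffle-host-label permutation null, standardized effect sizes (standardized
# d', 2DP), permutation p-values, FDR adjustment, and community-level tests.

#' Shuffle host-species labels across samples
#'
#' Applies a uniformly random permutation to the sample -> host assignment.
#' Every sample's OTU content is untouched and the multiset of labels (hence
#' each host's sample count) is preserved; only which samples belong to which
#' host changes. This is the null model of the preference analysis.
#'
#' @param table A [sample_table()] (normally binarized).
#' @return A [sample_table()] with permuted host labels.
#' @export
shuffle_host_labels <- function(table) {
  sample_table(table$counts,
               stats::setNames(sample(unname(table$host_of)), table$sample_ids))
}

#' Build a permutation null ensemble for a matrix statistic
#'
#' Repeats `n_perm` times: shuffle host labels, aggregate to the species
#' level, evaluate `statistic` on the permuted species matrix. Entities are
#' aligned across permutations by name, never by matrix position; an entity
#' for which the statistic is undefined in a permutation is recorded as a
#' missing draw. Each permutation runs on its own sub-seed drawn sequentially
#' from `seed`, so extending `n_perm` leaves earlier draws unchanged.
#'
#' @param table A binarized [sample_table()].
#' @param statistic Function of a `species_matrix` returning a (possibly
#'   named) numeric vector.
#' @param n_perm Number of permutations (>= 2).
#' @param seed Integer seed.
#' @param max_missing Abort when the fraction of missing draws for any entity
#'   exceeds this (default 0.05).
#' @return Object of class `null_ensemble`: list with `draws` (n_perm x
#'   entities matrix), `n_perm`, `mean`, `sd` (per entity, sample sd with
#'   the n-1 denominator), `n_ok`.
#' @export
build_null_ensemble <- function(table, statistic, n_perm, seed = 1,
                                max_missing = 0.05) {
  stopifnot(n_perm >= 2)
  seeds <- perm_seeds(seed, n_perm)
  vals <- vector("list", n_perm)
  for (t in seq_len(n_perm)) {
    v <- with_local_seed(seeds[t], {
      shuf <- shuffle_host_labels(table)
      tryCatch(statistic(suppressWarnings(aggregate_to_species(shuf))),
               error = function(e) NA_real_)
    })
    vals[[t]] <- v
  }
  nm <- unique(unlist(lapply(vals, names)))
  if (is.null(nm)) {
    draws <- matrix(unlist(lapply(vals, function(v) v[1])), ncol = 1)
    colnames(draws) <- "statistic"
  } else {
    draws <- matrix(NA_real_, n_perm, length(nm), dimnames = list(NULL, nm))
    for (t in seq_len(n_perm)) {
      v <- vals[[t]]
      if (length(v) == 1 && is.na(v) && is.null(names(v))) next
      draws[t, names(v)] <- v
    }
  }
  n_ok <- colSums(!is.na(draws))
  if (any((n_perm - n_ok) / n_perm > max_missing))
    stop("more than ", round(100 * max_missing),
         "% of permutations failed for: ",
         paste(colnames(draws)[(n_perm - n_ok) / n_perm > max_missing],
               collapse = ", "))
  structure(list(draws = draws, n_perm = n_perm,
                 mean = colMeans(draws, na.rm = TRUE),
                 sd = apply(draws, 2, stats::sd, na.rm = TRUE),
                 n_ok = n_ok),
            class = "null_ensemble")
}

ensemble_draws <- function(ensemble) {
  if (inherits(ensemble, "null_ensemble")) ensemble$draws[, 1] else as.numeric(ensemble)
}

#' Standardized (z-like) score against a null ensemble
#'
#' `(observed - mean(draws)) / sd(draws)` with the sample (n-1) standard
#' deviation. This is the "standardized d'" / 2DP form of effect size.
#' When the null sd is zero the score is undefined and `NA` is returned
#' (never +-Inf); callers should carry the flag forward.
#'
#' @param observed Observed statistic.
#' @param ensemble A `null_ensemble` (its first entity) or a numeric vector
#'   of draws.
#' @return Standardized score, or `NA` if the null sd is 0.
#' @export
standardized_score <- function(observed, ensemble) {
  draws <- ensemble_draws(ensemble)
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2) stop("need at least 2 non-missing draws")
  s <- stats::sd(draws)
  if (s == 0) return(NA_real_)
  (observed - mean(draws)) / s
}

#' Permutation p-value with the add-one estimator
#'
#' Upper tail: `p = (1 + #\{draws >= observed\}) / (1 + n)`; ties count
#' toward the tail, so p is always in (0, 1\] and valid under the null.
#'
#' @param observed Observed statistic.
#' @param ensemble A `null_ensemble` or numeric vector of draws.
#' @param tail `"upper"` (default: preference/segregation means observed
#'   above the null), `"lower"`, or `"two_sided"` (twice the smaller
#'   one-sided p, capped at 1).
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, ensemble,
                               tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  draws <- ensemble_draws(ensemble)
  draws <- draws[!is.na(draws)]
  n <- length(draws)
  if (n < 2) stop("need at least 2 non-missing draws")
  up <- (1 + sum(draws >= observed)) / (1 + n)
  lo <- (1 + sum(draws <= observed)) / (1 + n)
  switch(tail,
         upper = up,
         lower = lo,
         two_sided = min(1, 2 * min(up, lo)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(k) = min_{j >= k} (n * p_(j) / j)` mapped back to
#' input order (delegates to [stats::p.adjust()] after validating the input).
#'
#' @param pvals p-values in (0, 1].
#' @return FDR-adjusted q-values in (0, 1].
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# ---------------------------------------------------------------------------
# Fast permutation machinery shared by the preference and community tests.
# The host labels are permuted and the binary sample matrix re-aggregated by
# rowsum(); column totals of the species matrix (number of samples containing
# each OTU) and the grand total are invariant under label shuffles, which the
# d' caches below exploit.

# d' for every row of matrix `a` against fixed column totals, with d_min /
# d_max cached by row total A (they depend only on (A, col_totals, m); the
# cache is a pair of numeric vectors indexed by A).
dprime_rows_cached <- function(a, cs, m, cache) {
  A <- rowSums(a)
  P <- a / A
  Q <- matrix(cs / m, nrow(a), ncol(a), byrow = TRUE)
  W <- P * log(P / Q)
  W[a == 0] <- 0
  d <- rowSums(W)
  Amax <- max(A)
  if (is.null(cache$dmin) || length(cache$dmin) < Amax) {
    old <- length(cache$dmin %||% numeric(0))
    cache$dmin <- c(cache$dmin, rep(NA_real_, Amax - old))
    cache$dmax <- c(cache$dmax, rep(NA_real_, Amax - old))
  }
  for (Ai in unique(A[A > 0])) {
    if (is.na(cache$dmin[Ai])) {
      cache$dmin[Ai] <- d_min_value(Ai, cs, m)
      cache$dmax[Ai] <- d_max_value(Ai, cs, m)
    }
  }
  dmin <- cache$dmin[pmax(A, 1)]
  dmax <- cache$dmax[pmax(A, 1)]
  denom <- dmax - dmin
  out <- ifelse(denom < 1e-12, 0, pmin(1, pmax(0, (d - dmin) / denom)))
  out[A == 0] <- NA_real_
  out
}

new_cache <- function() new.env(parent = emptyenv())

# Streaming accumulator for permutation draws: running sum, sum of squares,
# tail counts against the observed values, and valid-draw counts.
stream_init <- function(obs) {
  list(obs = obs, n = 0 * obs, sum = 0 * obs, sumsq = 0 * obs,
       n_ge = 0 * obs, n_le = 0 * obs)
}

stream_add <- function(acc, draw) {
  ok <- !is.na(draw)
  acc$n[ok] <- acc$n[ok] + 1
  acc$sum[ok] <- acc$sum[ok] + draw[ok]
  acc$sumsq[ok] <- acc$sumsq[ok] + draw[ok]^2
  acc$n_ge[ok] <- acc$n_ge[ok] + (draw[ok] >= acc$obs[ok])
  acc$n_le[ok] <- acc$n_le[ok] + (draw[ok] <= acc$obs[ok])
  acc
}

stream_result <- function(acc, tail = "upper") {
  n <- acc$n
  mu <- acc$sum / n
  var <- pmax(0, (acc$sumsq - n * mu^2) / (n - 1))
  sd <- sqrt(var)
  std <- ifelse(sd > 0, (acc$obs - mu) / sd, NA_real_)
  up <- (1 + acc$n_ge) / (1 + n)
  lo <- (1 + acc$n_le) / (1 + n)
  p <- switch(tail,
              upper = up,
              lower = lo,
              two_sided = pmin(1, 2 * pmin(up, lo)))
  list(mean = mu, sd = sd, std = std, p = p, n = n)
}

#' Host- and symbiont-level preference analysis
#'
#' Scores every host species (and every abundant OTU) for interaction
#' specialization, and every host x abundant-OTU pair for association
#' preference, against the shuffle-host-label null:
#' standardized d' `= (d'_obs - mean(d'_rand)) / sd(d'_rand)` and
#' `2DP(i,j) = (N_obs(i,j) - mean(N_rand(i,j))) / sd(N_rand(i,j))`, with
#' add-one permutation p-values and Benjamini-Hochberg FDR adjustment applied
#' separately within each family of tests (hosts; OTUs; pairs). Pairs with
#' `2DP > 6` carry a `strong` reporting flag (a descriptive convention, not
#' an inferential threshold).
#'
#' @param table A binarized [sample_table()].
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param abundant_otus OTU ids for which symbiont-level and pair results are
#'   reported (see [filter_abundant_otus()]); default all OTUs.
#' @param families Which result families to compute, any of `"hosts"`,
#'   `"otus"`, `"pairs"` (all by default).
#' @param tail Tail for permutation p-values (default `"upper"`:
#'   preference means observed above the null).
#' @return List of class `preference_result` with data.frames `hosts`,
#'   `otus` (`entity`, `d_prime_observed`, `standardized_d_prime`, `p_perm`,
#'   `q_fdr`, `sd_zero`) and `pairs` (`host`, `otu`, `n_observed`, `two_dp`,
#'   `p_perm`, `q_fdr`, `strong`, `sd_zero`), plus `n_perm` and `seed`.
#' @export
host_and_otu_preferences <- function(table, n_perm = 10000, seed = 1,
                                     abundant_otus = NULL,
                                     families = c("hosts", "otus", "pairs"),
                                     tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(n_perm >= 2)
  if (!is_binary(table))
    stop("table must be binarized (presence/absence) before the preference analysis")
  families <- match.arg(families, several.ok = TRUE)
  obs_sm <- suppressWarnings(aggregate_to_species(table))
  hosts <- obs_sm$hosts
  otus <- obs_sm$otus
  if (is.null(abundant_otus)) abundant_otus <- otus
  abundant_otus <- otus[otus %in% abundant_otus]
  # restrict to the OTU columns retained in the observed aggregate (all-zero
  # columns carry no information and are invariant under label shuffles)
  pres <- (table$counts > 0)[, otus, drop = FALSE] * 1
  labs <- unname(table$host_of)
  cs <- obs_sm$col_totals        # invariant under label shuffles
  m <- obs_sm$m

  do_hosts <- "hosts" %in% families
  do_otus <- "otus" %in% families && length(abundant_otus) > 0
  do_pairs <- "pairs" %in% families && length(abundant_otus) > 0

  host_cache <- new_cache()
  if (do_hosts) {
    host_obs <- dprime_rows_cached(obs_sm$a, cs, m, host_cache)
    host_acc <- stream_init(stats::setNames(host_obs, hosts))
  }
  ab_idx <- match(abundant_otus, otus)
  if (do_otus) {
    otu_obs <- dprime_rows_cached(t(obs_sm$a)[ab_idx, , drop = FALSE],
                                  obs_sm$row_totals, m, new_cache())
    otu_acc <- stream_init(stats::setNames(otu_obs, abundant_otus))
  }
  if (do_pairs) {
    pair_obs <- obs_sm$a[, abundant_otus, drop = FALSE]
    pair_acc <- stream_init(pair_obs)
  }

  seeds <- perm_seeds(seed, n_perm)
  for (t in seq_len(n_perm)) {
    perm <- with_local_seed(seeds[t], sample(labs))
    z <- rowsum(pres, group = perm)
    z <- z[hosts, , drop = FALSE]
    if (do_hosts)
      host_acc <- stream_add(host_acc, dprime_rows_cached(z, cs, m, host_cache))
    if (do_otus)
      otu_acc <- stream_add(
        otu_acc,
        dprime_rows_cached(t(z)[ab_idx, , drop = FALSE], rowSums(z), m,
                           new_cache()))
    if (do_pairs)
      pair_acc <- stream_add(pair_acc, z[, abundant_otus, drop = FALSE])
  }

  finish_family <- function(acc, entities) {
    if (any((n_perm - acc$n) / n_perm > 0.05))
      stop("more than 5% of permutations undefined for some entities")
    res <- stream_result(acc, tail)
    data.frame(entity = entities,
               d_prime_observed = unname(acc$obs),
               standardized_d_prime = unname(res$std),
               p_perm = unname(res$p),
               q_fdr = benjamini_hochberg(unname(res$p)),
               sd_zero = unname(res$sd == 0),
               row.names = NULL)
  }

  out <- list(hosts = NULL, otus = NULL, pairs = NULL,
              n_perm = n_perm, seed = seed, tail = tail,
              abundant_otus = abundant_otus)
  empty_entity <- data.frame(entity = character(0),
                             d_prime_observed = numeric(0),
                             standardized_d_prime = numeric(0),
                             p_perm = numeric(0), q_fdr = numeric(0),
                             sd_zero = logical(0))
  if (do_hosts) out$hosts <- finish_family(host_acc, hosts)
  if ("otus" %in% families && !do_otus) out$otus <- empty_entity
  if (do_otus) out$otus <- finish_family(otu_acc, abundant_otus)
  if ("pairs" %in% families && !do_pairs)
    out$pairs <- data.frame(host = character(0), otu = character(0),
                            n_observed = numeric(0), two_dp = numeric(0),
                            p_perm = numeric(0), q_fdr = numeric(0),
                            strong = logical(0), sd_zero = logical(0))
  if (do_pairs) {
    res <- stream_result(pair_acc, tail)
    out$pairs <- data.frame(
      host = rep(hosts, times = length(abundant_otus)),
      otu = rep(abundant_otus, each = length(hosts)),
      n_observed = as.vector(pair_acc$obs),
      two_dp = as.vector(res$std),
      p_perm = as.vector(res$p),
      q_fdr = benjamini_hochberg(as.vector(res$p)),
      strong = as.vector(!is.na(res$std) & res$std > 6),
      sd_zero = as.vector(res$sd == 0),
      row.names = NULL)
  }
  class(out) <- "preference_result"
  out
}

#' @export
print.preference_result <- function(x, ...) {
  cat("preference_result (", x$n_perm, " permutations, ", x$tail, " tail)\n",
      sep = "")
  for (f in c("hosts", "otus")) {
    if (!is.null(x[[f]]))
      cat(sprintf("  %s: %d scored, %d with q < 0.05\n", f, nrow(x[[f]]),
                  sum(x[[f]]$q_fdr < 0.05)))
  }
  if (!is.null(x$pairs))
    cat(sprintf("  pairs: %d scored, %d with q < 0.05, %d strong (2DP > 6)\n",
                nrow(x$pairs), sum(x$pairs$q_fdr < 0.05), sum(x$pairs$strong)))
  invisible(x)
}

#' Community-level specialization and co-occurrence tests
#'
#' Compares the observed network-level H2' and the per-guild normalized
#' checkerboard scores with their distributions under the shuffle-host-label
#' null. For each statistic the null mean and sd (the "expected by chance"
#' values), the standardized score z, the add-one permutation p-value and a
#' one-sample t-statistic of the null draws against the observed value (with
#' its p) are reported.
#'
#' @param table A binarized [sample_table()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param statistics Subset of `c("h2_prime", "c_score_otus",
#'   "c_score_hosts")` to compute.
#' @param tail Tail for the permutation p (default `"upper"`).
#' @return List of class `network_test`: `stats` data.frame (`statistic`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p_perm`, `t_stat`, `p_t`)
#'   and `draws` matrix.
#' @export
community_level_test <- function(table, n_perm = 1000, seed = 1,
                                 statistics = c("h2_prime", "c_score_otus",
                                                "c_score_hosts"),
                                 tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (!is_binary(table))
    stop("table must be binarized (presence/absence) before the community test")
  obs_sm <- suppressWarnings(aggregate_to_species(table))
  hosts <- obs_sm$hosts
  pres <- (table$counts > 0)[, obs_sm$otus, drop = FALSE] * 1
  labs <- unname(table$host_of)

  eval_stats <- function(a) {
    v <- c(h2_prime = NA_real_, c_score_otus = NA_real_,
           c_score_hosts = NA_real_)
    if ("h2_prime" %in% statistics) v["h2_prime"] <- h2_prime(a)$h2_prime
    if ("c_score_otus" %in% statistics)
      v["c_score_otus"] <- c_score(a, axis = "cols")
    if ("c_score_hosts" %in% statistics)
      v["c_score_hosts"] <- c_score(a, axis = "rows")
    v[statistics]
  }

  observed <- eval_stats(obs_sm$a)
  draws <- matrix(NA_real_, n_perm, length(statistics),
                  dimnames = list(NULL, statistics))
  seeds <- perm_seeds(seed, n_perm)
  for (t in seq_len(n_perm)) {
    perm <- with_local_seed(seeds[t], sample(labs))
    z <- rowsum(pres, group = perm)
    z <- z[hosts, , drop = FALSE]
    draws[t, ] <- eval_stats(z)
  }
  rows <- lapply(statistics, function(stat) {
    d <- draws[, stat]
    d <- d[!is.na(d)]
    tt <- stats::t.test(d, mu = observed[[stat]])
    data.frame(statistic = stat,
               observed = observed[[stat]],
               null_mean = mean(d),
               null_sd = stats::sd(d),
               z = standardized_score(observed[[stat]], d),
               p_perm = permutation_pvalue(observed[[stat]], d, tail),
               t_stat = unname(tt$statistic),
               p_t = tt$p.value)
  })
  structure(list(stats = do.call(rbind, rows), draws = draws,
                 n_perm = n_perm, seed = seed),
            class = "network_test")
}

#' @export
print.network_test <- function(x, ...) {
  cat("network_test (", x$n_perm, " permutations)\n", sep = "")
  df <- x$stats
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-14s observed %.3f vs null %.3f +- %.3f (z = %.2f, p = %.4g)\n",
                df$statistic[i], df$observed[i], df$null_mean[i],
                df$null_sd[i], df$z[i], df$p_perm[i]))
  invisible(x)
}
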