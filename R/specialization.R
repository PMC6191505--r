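# Interaction specialization indices for bipartite host-symbiont matrices:
# per-species d' (Kullback-Leibler specialization, min-max normalized under
# fixed marginal totals), network-level H2', and the checkerboard C-score.
# All logarithms are natural (nats).

EXTREMAL_TOL <- 1e-9

# Per-column KL contribution of an allocation t given cap-derived availability
# q_j = c_j / m: f_j(t) = (t/A) * ln(t * m / (A * c_j)), with f_j(0) = 0.
kl_terms <- function(t, A, c, m) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / A) * log(t[pos] * m / (A * c[pos]))
  out
}

#' Kullback-Leibler specialization d of one species
#'
#' For a row of the species-level matrix, computes
#' `d = sum_j p'_j * ln(p'_j / q_j)` with `p'_j = a_j / A` (the species'
#' interaction proportions) and `q_j = c_j / m` (partner availability from
#' column totals). Zero cells contribute 0. `d = 0` when the species uses
#' partners exactly in proportion to availability.
#'
#' @param row Non-negative integer interaction vector of one species.
#' @param col_totals Column totals of the full matrix (they include the focal
#'   row's contribution).
#' @param grand_total Grand total m of the matrix.
#' @return The specialization d in nats (>= 0).
#' @export
d_index <- function(row, col_totals, grand_total) {
  if (any(row < 0)) stop("negative entries in interaction vector")
  A <- sum(row)
  if (A == 0) stop("zero interaction row: d is undefined")
  if (any(row > 0 & col_totals <= 0))
    stop("positive cell in a column with zero total")
  sum(kl_terms(row, A, col_totals, grand_total))
}

# Exact integer minimum of d over allocations {0 <= x <= c, sum x = A}:
# largest-remainder rounding of the proportional allocation A*c/m, followed by
# single-unit exchange repair. For a separable convex objective on this
# polytope, exchange-local optimality implies the global minimum, so the
# repaired allocation is exact (verified against exhaustive enumeration on
# small matrices in the test suite).
d_min_value <- function(A, c, m) {
  use <- c > 0
  cc <- c[use]
  if (length(cc) == 0) stop("no available partners")
  xstar <- A * cc / m
  x <- floor(xstar)
  repeat {
    r <- A - sum(x)
    if (r <= 0) break
    avail <- which(x < cc)
    inc <- kl_terms(x[avail] + 1, A, cc[avail], m) -
      kl_terms(x[avail], A, cc[avail], m)
    take <- avail[order(inc)[seq_len(min(r, length(avail)))]]
    x[take] <- x[take] + 1
  }
  repeat {
    dec <- which(x >= 1)
    inc <- which(x < cc)
    gain <- kl_terms(x[dec], A, cc[dec], m) -
      kl_terms(x[dec] - 1, A, cc[dec], m)
    cost <- kl_terms(x[inc] + 1, A, cc[inc], m) -
      kl_terms(x[inc], A, cc[inc], m)
    best <- best_exchange(dec, gain, inc, cost)
    if (is.null(best) || best$delta <= 1e-12) break
    x[best$from] <- x[best$from] - 1
    x[best$to] <- x[best$to] + 1
  }
  sum(kl_terms(x, A, cc, m))
}

# Best (gain - cost) over pairs with distinct columns.
best_exchange <- function(dec, gain, inc, cost) {
  if (!length(dec) || !length(inc)) return(NULL)
  og <- order(gain, decreasing = TRUE)
  oc <- order(cost)
  for (gi in og[seq_len(min(2L, length(og)))]) {
    for (ci in oc[seq_len(min(2L, length(oc)))]) {
      if (dec[gi] != inc[ci])
        return(list(from = dec[gi], to = inc[ci],
                    delta = gain[gi] - cost[ci]))
    }
  }
  NULL
}

# Exact integer maximum of d over {0 <= x <= c, sum x = A}. The objective is
# convex, the polytope is integral, so the maximum sits at a vertex: all
# coordinates at 0 or at their cap except at most one partial coordinate.
# Every saturated column contributes ln(m/A) per unit, which reduces the
# search to a subset-sum problem over column totals (bitset dynamic program),
# plus a scan over candidate partial columns.
d_max_value <- function(A, c, m) {
  cc <- c[c > 0]
  if (length(cc) == 0) stop("no available partners")
  reach <- subset_sums(cc, A)
  if (reach[A + 1]) return(log(m / A))
  best <- -Inf
  lmA <- log(m / A)
  for (v in unique(cc)) {
    rmax <- min(v - 1, A)
    if (rmax < 1) next
    reach_v <- if (v <= A) subset_sums(cc[-match(v, cc)], A) else reach
    rs <- seq_len(rmax)
    ok <- reach_v[A - rs + 1]
    if (any(ok)) {
      r <- rs[ok]
      cand <- ((A - r) * lmA + r * log(r * m / (A * v))) / A
      best <- max(best, max(cand))
    }
  }
  if (!is.finite(best))
    stop("internal error: no feasible extremal allocation found")
  best
}

# Achievable subset sums of the multiset `vals`, capped at `target`:
# logical vector indexed by sum + 1. Bounded-knapsack with binary splitting.
subset_sums <- function(vals, target) {
  reach <- c(TRUE, rep(FALSE, target))
  small <- vals[vals <= target]
  for (v in unique(small)) {
    k <- min(sum(small == v), target %/% v)
    w <- 1L
    while (k > 0) {
      take <- min(w, k)
      item <- v * take
      if (item <= target)
        reach <- reach | c(rep(FALSE, item), reach[seq_len(target + 1 - item)])
      k <- k - take
      w <- w * 2L
    }
  }
  reach
}

# d, d_min, d_max and d' for one row given fixed column totals.
dprime_components <- function(x, col_totals, grand_total, warn = TRUE) {
  A <- sum(x)
  d <- d_index(x, col_totals, grand_total)
  if (sum(col_totals > 0) < 2) {
    if (warn) warning("single available partner: d_max = d_min, d' set to 0")
    return(list(d = d, d_min = d, d_max = d, d_prime = 0))
  }
  dmin <- d_min_value(A, col_totals, grand_total)
  dmax <- d_max_value(A, col_totals, grand_total)
  if (d < dmin - EXTREMAL_TOL || d > dmax + EXTREMAL_TOL)
    stop(sprintf("internal error: d = %.12g outside extremal bounds [%.12g, %.12g]",
                 d, dmin, dmax))
  denom <- dmax - dmin
  dp <- if (denom < 1e-12) 0 else min(1, max(0, (d - dmin) / denom))
  list(d = d, d_min = dmin, d_max = dmax, d_prime = dp)
}

#' Standardized specialization d' for every species on one axis
#'
#' Computes, for each row (or column) of a species-level matrix, the KL
#' specialization d together with its exact integer minimum and maximum under
#' the observed marginal totals, and the normalization
#' `d' = (d - d_min) / (d_max - d_min)` in \[0, 1\]. Column totals retain the
#' focal row's contribution, matching the convention of the index's reference
#' implementation.
#'
#' @param mat A `species_matrix` (from [aggregate_to_species()]) or a plain
#'   non-negative integer matrix.
#' @param axis `"rows"` scores the row guild (host plants); `"cols"` scores
#'   the column guild (symbiont OTUs) on the transposed matrix.
#' @return A data.frame with columns `entity`, `d`, `d_min`, `d_max`,
#'   `d_prime`.
#' @export
d_prime_all <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  a <- as_interaction_matrix(mat)
  if (axis == "cols") a <- t(a)
  cs <- colSums(a)
  m <- sum(a)
  warned <- FALSE
  rows <- lapply(seq_len(nrow(a)), function(i) {
    comp <- withCallingHandlers(
      dprime_components(a[i, ], cs, m, warn = !warned),
      warning = function(w) {
        warned <<- TRUE
      })
    comp
  })
  data.frame(entity = rownames(a) %||% as.character(seq_len(nrow(a))),
             d = vapply(rows, `[[`, numeric(1), "d"),
             d_min = vapply(rows, `[[`, numeric(1), "d_min"),
             d_max = vapply(rows, `[[`, numeric(1), "d_max"),
             d_prime = vapply(rows, `[[`, numeric(1), "d_prime"),
             row.names = NULL)
}

# ---------------------------------------------------------------------------
# Network-level H2'

entropy_nats <- function(x) {
  m <- sum(x)
  p <- x[x > 0] / m
  -sum(p * log(p))
}

# Maximum-entropy integer fill under fixed marginals: largest-remainder
# rounding of the independence table r_i * s_j / m per row, then column-sum
# repair by moving single units between rows.
h2_fill_max <- function(r, s) {
  m <- sum(r)
  E <- outer(r, s) / m
  X <- floor(E)
  for (i in seq_along(r)) {
    need <- r[i] - sum(X[i, ])
    while (need > 0) {
      take <- order(E[i, ] - X[i, ], decreasing = TRUE)[seq_len(min(need, length(s)))]
      X[i, take] <- X[i, take] + 1
      need <- r[i] - sum(X[i, ])
    }
  }
  e <- colSums(X) - s
  while (any(e > 0)) {
    jo <- which.max(e)
    ju <- which.min(e)
    cand <- which(X[, jo] >= 1)
    i <- cand[which.max(X[cand, jo] - E[cand, jo])]
    X[i, jo] <- X[i, jo] - 1
    X[i, ju] <- X[i, ju] + 1
    e[jo] <- e[jo] - 1
    e[ju] <- e[ju] + 1
  }
  X
}

# Exact entropy extremes under fixed marginals for small matrices, by
# dynamic programming over columns: a state is the vector of remaining row
# marginals; for each column every bounded composition of its total over the
# rows is tried, tracking the extreme achievable entropy sums. Exhaustive
# over the integer transportation polytope, so both bounds are exact.
# Affordable while prod(r + 1) stays small; larger matrices use the greedy
# fills below.
h2_extrema_exact <- function(r, s) {
  m <- sum(r)
  g <- function(t) ifelse(t > 0, -(t / m) * log(t / m), 0)
  n <- length(r)
  compositions <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(matrix(total, 1, 1)) else return(NULL)
    }
    out <- NULL
    for (a in 0:min(total, caps[1])) {
      sub <- compositions(total - a, caps[-1])
      if (!is.null(sub)) out <- rbind(out, cbind(a, sub))
    }
    out
  }
  states <- new.env(parent = emptyenv())
  assign(paste(r, collapse = ","), c(0, 0), envir = states)
  for (j in seq_along(s)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(states)) {
      rr <- as.numeric(strsplit(key, ",")[[1]])
      val <- get(key, envir = states)
      allocs <- compositions(s[j], rr)
      if (is.null(allocs)) next
      for (k in seq_len(nrow(allocs))) {
        a <- allocs[k, ]
        add <- sum(g(a))
        k2 <- paste(rr - a, collapse = ",")
        old <- nxt[[k2]]
        cand <- c(val[1] + add, val[2] + add)
        nxt[[k2]] <- if (is.null(old)) cand else c(min(old[1], cand[1]),
                                                   max(old[2], cand[2]))
      }
    }
    states <- nxt
  }
  res <- states[[paste(rep(0, n), collapse = ",")]]
  if (is.null(res)) stop("internal error: infeasible marginals")
  res
}

# Minimum-entropy greedy packing: repeatedly place min(remaining row,
# remaining column) into the cell of the currently largest remaining
# marginals; ties broken by index order.
h2_fill_min <- function(r, s) {
  X <- matrix(0, length(r), length(s))
  rr <- r
  ss <- s
  while (sum(rr) > 0) {
    i <- which.max(rr)
    j <- which.max(ss)
    t <- min(rr[i], ss[j])
    X[i, j] <- X[i, j] + t
    rr[i] <- rr[i] - t
    ss[j] <- ss[j] - t
  }
  X
}

# Steepest 2x2 exchange repair of an integer fill: repeatedly apply the
# cyclic move (+1, -1 / -1, +1) that most improves the entropy in the chosen
# direction. Used on small matrices where the full scan is affordable.
h2_repair <- function(X, maximize = TRUE, max_moves = 500) {
  m <- sum(X)
  g <- function(t) ifelse(t > 0, -(t / m) * log(t / m), 0)
  n <- nrow(X)
  J <- ncol(X)
  if (n < 2 || J < 2) return(X)
  for (iter in seq_len(max_moves)) {
    best_delta <- 0
    best <- NULL
    for (i in seq_len(n - 1)) for (k in (i + 1):n) {
      for (j in seq_len(J - 1)) for (l in (j + 1):J) {
        # direction 1: +1 at (i,j),(k,l); -1 at (i,l),(k,j)
        if (X[i, l] >= 1 && X[k, j] >= 1) {
          d1 <- g(X[i, j] + 1) - g(X[i, j]) + g(X[k, l] + 1) - g(X[k, l]) +
            g(X[i, l] - 1) - g(X[i, l]) + g(X[k, j] - 1) - g(X[k, j])
          if (!maximize) d1 <- -d1
          if (d1 > best_delta + 1e-12) {
            best_delta <- d1
            best <- c(i, j, k, l, 1)
          }
        }
        # direction 2: the reverse move
        if (X[i, j] >= 1 && X[k, l] >= 1) {
          d2 <- g(X[i, j] - 1) - g(X[i, j]) + g(X[k, l] - 1) - g(X[k, l]) +
            g(X[i, l] + 1) - g(X[i, l]) + g(X[k, j] + 1) - g(X[k, j])
          if (!maximize) d2 <- -d2
          if (d2 > best_delta + 1e-12) {
            best_delta <- d2
            best <- c(i, j, k, l, -1)
          }
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]; k <- best[3]; l <- best[4]; sgn <- best[5]
    X[i, j] <- X[i, j] + sgn
    X[k, l] <- X[k, l] + sgn
    X[i, l] <- X[i, l] - sgn
    X[k, j] <- X[k, j] - sgn
  }
  X
}

#' Network-level specialization H2'
#'
#' Computes the two-dimensional Shannon entropy
#' `H2 = -sum_ij (a_ij/m) ln(a_ij/m)` of the interaction frequency
#' distribution and normalizes it between the extremal entropies achievable
#' under the observed marginal totals:
#' `H2' = (H2_max - H2) / (H2_max - H2_min)`, 0 for a perfectly proportional
#' network and 1 for maximal specialization. Extremal integer fills come from
#' largest-remainder rounding of the independence table (maximum) and a
#' largest-remaining-marginal greedy packing (minimum), each refined by 2x2
#' exchange repair on matrices with at most `repair_cells` cells; the
#' observed matrix itself is always admitted as a feasible bound candidate,
#' which guarantees `H2_min <= H2 <= H2_max`.
#'
#' @param mat A `species_matrix` or plain non-negative integer matrix.
#' @param repair_cells Cell-count cutoff below which the exhaustive 2x2
#'   exchange repair runs (default 100).
#' @return List with `h2`, `h2_min`, `h2_max`, `h2_prime`.
#' @export
h2_prime <- function(mat, repair_cells = 100) {
  a <- as_interaction_matrix(mat)
  if (sum(a) <= 0) stop("empty interaction matrix")
  r <- rowSums(a)
  s <- colSums(a)
  m <- sum(a)
  h2 <- entropy_nats(a)
  if (length(r) <= 4 && length(s) <= 4 && prod(r + 1) <= 20000 && m <= 48) {
    ex <- h2_extrema_exact(r, s)
    h2min <- min(ex[1], h2)
    h2max <- max(ex[2], h2)
  } else {
    small <- length(a) <= repair_cells
    Xmax <- h2_fill_max(r, s)
    if (small) Xmax <- h2_repair(Xmax, maximize = TRUE)
    h2max <- max(entropy_nats(Xmax), h2)
    Xmin <- h2_fill_min(r, s)
    if (small) Xmin <- h2_repair(Xmin, maximize = FALSE)
    h2min <- min(entropy_nats(Xmin), h2)
  }
  denom <- h2max - h2min
  if (denom < 1e-12) {
    warning("degenerate matrix: H2 extremes coincide, H2' set to 0")
    h2p <- 0
  } else {
    h2p <- min(1, max(0, (h2max - h2) / denom))
  }
  list(h2 = h2, h2_min = h2min, h2_max = h2max, h2_prime = h2p)
}

# ---------------------------------------------------------------------------
# Checkerboard C-score

#' Mean checkerboard score of one guild
#'
#' For every pair of species (u, v) on the chosen axis of the binarized
#' species-level matrix, the checkerboard unit count
#' `C_uv = (r_u - S_uv)(r_v - S_uv)` is computed from partner counts r and
#' shared-partner counts S, normalized by `r_u * r_v` so each pair lies in
#' \[0, 1\] (1 = perfect segregation, 0 = complete co-occurrence), and
#' averaged over all distinct pairs. The unnormalized Stone-Roberts mean is
#' available with `normalized = FALSE`.
#'
#' @param mat A `species_matrix` or matrix; cells are binarized (`> 0`).
#' @param axis `"rows"` scores the row guild (hosts), `"cols"` the column
#'   guild (OTUs).
#' @param normalized Divide each pair by `r_u * r_v` (default `TRUE`).
#' @return Mean checkerboard score (scalar).
#' @export
c_score <- function(mat, axis = c("cols", "rows"), normalized = TRUE) {
  axis <- match.arg(axis)
  B <- (as_interaction_matrix(mat) > 0) * 1
  if (axis == "cols") B <- t(B)
  B <- B[rowSums(B) > 0, , drop = FALSE]
  n <- nrow(B)
  if (n < 2) stop("need at least 2 species with partners on the chosen axis")
  S <- tcrossprod(B)
  r <- rowSums(B)
  M <- (r - S) * t(r - t(S))
  if (normalized) M <- M / outer(r, r)
  mean(M[upper.tri(M)])
}
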