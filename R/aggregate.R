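#' Bundle ranked lists (with optional scores) for consensus aggregation
#'
#' @param lists a list of `stability_scores` objects, or of character
#'   vectors (rankings over the same gene set). Score vectors, when
#'   present, weight the footrule distance.
#' @return a `ranking_ensemble`: `rankings` (list of character vectors),
#'   `weights` (list of per-position normalized scores in [0, 1] with 0 =
#'   most stable, or `NULL`), `items` (the common item set).
#' @export
ranking_ensemble <- function(lists) {
  rankings <- lapply(lists, function(l) {
    if (inherits(l, "stability_scores")) l$ranking else as.character(l)
  })
  items <- sort(rankings[[1]])
  for (r in rankings) {
    if (!identical(sort(r), items))
      stop_refstab("every list must be a permutation of the same item set",
                   "refstab_invalid_argument")
  }
  weights <- lapply(lists, function(l) {
    if (!inherits(l, "stability_scores")) return(NULL)
    s <- unname(l$score[l$ranking])            # scores by position
    if (l$orientation == "higher_better") s <- -s
    rng <- diff(range(s))
    if (rng == 0) seq(0, 1, length.out = length(s))
    else (s - min(s)) / rng                    # 0 = most stable position
  })
  if (any(vapply(weights, is.null, logical(1)))) weights <- NULL
  structure(list(rankings = rankings, weights = weights,
                 items = rankings[[1]]),
            class = "ranking_ensemble")
}

#' Spearman-footrule objective of a candidate consensus ranking
#'
#' Unweighted: sum over lists and items of the absolute difference between
#' the item's position in the candidate and in the list. Weighted: each
#' list's stability scores are oriented (smaller = more stable) and min-max
#' normalized to [0, 1] by position, and the distance term for item g in
#' list i is |W_i(candidate position of g) - W_i(list position of g)| — the
#' weighted-footrule formulation used for weighted rank aggregation.
#'
#' @param candidate character vector, a permutation of the ensemble's items.
#' @param ensemble a [ranking_ensemble()].
#' @param weighted use the score-weighted footrule (requires scores).
#' @return non-negative objective value.
#' @export
footrule_objective <- function(candidate, ensemble, weighted = FALSE) {
  if (!identical(sort(as.character(candidate)), sort(ensemble$items)))
    stop_refstab("candidate is not a permutation of the ensemble's items",
                 "refstab_invalid_argument")
  if (weighted && is.null(ensemble$weights))
    stop_refstab("weighted objective requires per-list scores",
                 "refstab_invalid_argument")
  pos_cand <- match(ensemble$items, candidate)
  total <- 0
  for (i in seq_along(ensemble$rankings)) {
    pos_list <- match(ensemble$items, ensemble$rankings[[i]])
    if (weighted) {
      w <- ensemble$weights[[i]]
      total <- total + sum(abs(w[pos_cand] - w[pos_list]))
    } else {
      total <- total + sum(abs(pos_cand - pos_list))
    }
  }
  total
}

# position-cost matrix: cost[g, p] = contribution of placing item g at
# position p; the footrule objective is separable, so consensus search is a
# linear assignment problem
footrule_cost_matrix <- function(ensemble, weighted = FALSE) {
  items <- ensemble$items
  G <- length(items)
  cost <- matrix(0, G, G, dimnames = list(items, NULL))
  for (i in seq_along(ensemble$rankings)) {
    pos_list <- match(items, ensemble$rankings[[i]])
    if (weighted) {
      w <- ensemble$weights[[i]]
      cost <- cost + abs(outer(w[pos_list], w, "-"))
    } else {
      cost <- cost + abs(outer(pos_list, seq_len(G), "-"))
    }
  }
  cost
}

#' Exact consensus ranking by linear assignment
#'
#' The footrule objective (weighted or not) decomposes over (item,
#' position) pairs, so the global minimiser over all permutations is the
#' solution of a linear assignment problem — identical to enumerating all
#' G! rankings, but tractable. Ties are resolved toward lexicographic item
#' order via an infinitesimal tie-break perturbation.
#'
#' @param ensemble a [ranking_ensemble()].
#' @param weighted minimise the score-weighted objective.
#' @param max_items refuse problems larger than this (the exhaustive
#'   semantics are only verified at small G; use [ce_aggregate()] beyond).
#' @return a `consensus_ranking`: `ordering`, `objective` (of the stated
#'   kind), `objective_unweighted` (always reported), `method`, `weighted`.
#' @export
brute_force_aggregate <- function(ensemble, weighted = FALSE,
                                  max_items = 10L) {
  G <- length(ensemble$items)
  if (G > max_items)
    stop_refstab(sprintf(
      "%d items exceeds the exact-search limit (%d); use ce_aggregate()",
      G, max_items), "refstab_invalid_argument")
  cost <- footrule_cost_matrix(ensemble, weighted = weighted)
  # deterministic tie-break: prefer earlier positions for lexicographically
  # earlier items, at a scale that cannot change the optimum
  eps <- if (all(cost == 0)) 1 else min(diff(sort(unique(c(cost)))), 1)
  lex_rank <- order(order(ensemble$items))
  tie <- outer(lex_rank, G - seq_len(G)) * (eps / (4 * G^5))
  assign <- solve_assignment(cost + tie)
  ordering <- character(G)
  ordering[assign] <- ensemble$items
  structure(list(ordering = ordering,
                 objective = footrule_objective(ordering, ensemble,
                                                weighted = weighted),
                 objective_unweighted = footrule_objective(ordering, ensemble),
                 method = "brute_force", weighted = weighted),
            class = "consensus_ranking")
}

# Hungarian algorithm (O(n^3), potentials + augmenting paths).
# Returns assigned column (position) per row (item).
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)            # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                      # columns offset by +1; column 1 is virtual
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1L:(n + 1L)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

# full-enumeration minimiser; retained as the independent test oracle
enumerate_aggregate <- function(ensemble, weighted = FALSE) {
  items <- ensemble$items
  perms <- permutations_of(length(items))
  best <- NULL; best_obj <- Inf
  for (k in seq_len(nrow(perms))) {
    cand <- items[perms[k, ]]
    obj <- footrule_objective(cand, ensemble, weighted = weighted)
    if (obj < best_obj - 1e-12) { best_obj <- obj; best <- cand }
  }
  list(ordering = best, objective = best_obj)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Consensus ranking by cross-entropy Monte Carlo
#'
#' Stochastic search over permutations: a G-by-G position-probability
#' matrix (rows = items, columns = positions) starts uniform; each
#' iteration samples `samples_per_iter` permutations sequentially from it,
#' scores them with the footrule objective, re-estimates the matrix from
#' the elite fraction, and blends it with the previous matrix using
#' multiplicative smoothing. Search stops once the best objective has not
#' improved for `patience` iterations.
#'
#' @param ensemble a [ranking_ensemble()].
#' @param weighted minimise the score-weighted objective.
#' @param samples_per_iter permutations sampled per iteration.
#' @param elite_fraction fraction of best samples used for the update.
#' @param smoothing weight of the new elite-frequency estimate in the blend.
#' @param patience stop after this many iterations without improvement.
#' @param seed integer seed; required for reproducibility.
#' @param max_iter hard iteration cap.
#' @return a `consensus_ranking` with `method = "cross_entropy"`, `seed`,
#'   `iterations`, and the best-objective trace in `trace`.
#' @export
ce_aggregate <- function(ensemble, weighted = FALSE,
                         samples_per_iter = 2000L, elite_fraction = 0.1,
                         smoothing = 0.7, patience = 5L, seed,
                         max_iter = 200L) {
  G <- length(ensemble$items)
  if (G < 2L)
    stop_refstab("need at least 2 items", "refstab_invalid_argument")
  if (missing(seed)) stop_refstab("seed is required", "refstab_invalid_argument")
  set.seed(as.integer(seed))
  cost <- footrule_cost_matrix(ensemble, weighted = weighted)
  P <- matrix(1 / G, G, G)
  best_perm <- NULL; best_obj <- Inf
  stall <- 0L; iter <- 0L; reinit_used <- FALSE
  trace <- numeric(0)
  n_elite <- max(1L, ceiling(elite_fraction * samples_per_iter))
  while (iter < max_iter && stall < patience) {
    iter <- iter + 1L
    perms <- sample_permutations(P, samples_per_iter)
    obj <- perm_costs(perms, cost)
    ord <- order(obj)
    elite <- perms[ord[seq_len(n_elite)], , drop = FALSE]
    if (obj[ord[1L]] < best_obj - 1e-12) {
      best_obj <- obj[ord[1L]]
      best_perm <- perms[ord[1L], ]
      stall <- 0L
    } else stall <- stall + 1L
    trace <- c(trace, best_obj)
    Pnew <- matrix(0, G, G)
    for (k in seq_len(nrow(elite)))
      Pnew[cbind(seq_len(G), elite[k, ])] <- Pnew[cbind(seq_len(G), elite[k, ])] + 1
    Pnew <- Pnew / nrow(elite)
    P <- smoothing * Pnew + (1 - smoothing) * P
    if (any(!is.finite(P)) || any(rowSums(P) < 1e-12)) {
      if (reinit_used)
        stop_refstab("cross-entropy probability matrix degenerated twice",
                     "refstab_numerical_error")
      warning("degenerate probability matrix; re-initializing once")
      P <- matrix(1 / G, G, G)
      reinit_used <- TRUE
    }
  }
  ordering <- character(G)
  ordering[best_perm] <- ensemble$items
  structure(list(ordering = ordering,
                 objective = footrule_objective(ordering, ensemble,
                                                weighted = weighted),
                 objective_unweighted = footrule_objective(ordering, ensemble),
                 method = "cross_entropy", weighted = weighted,
                 seed = as.integer(seed), iterations = iter, trace = trace),
            class = "consensus_ranking")
}

# sample m permutations from a position-probability matrix, item by item,
# renormalising over still-free positions; vectorised across samples
sample_permutations <- function(P, m) {
  G <- nrow(P)
  out <- matrix(0L, m, G)
  free <- matrix(TRUE, m, G)
  for (g in seq_len(G)) {
    prob <- free * rep(P[g, ], each = m)
    rs <- rowSums(prob)
    flat <- rs < 1e-300               # item's mass entirely on taken positions
    if (any(flat)) {
      prob[flat, ] <- free[flat, ]
      rs[flat] <- rowSums(prob[flat, , drop = FALSE])
    }
    cum <- prob %*% upper.tri(diag(G), diag = TRUE)   # row-wise cumsum
    r <- stats::runif(m) * rs
    pos <- max.col(cum >= r, ties.method = "first")
    # float-edge guard: a rounding miss may land on a taken position
    bad <- which(!free[cbind(seq_len(m), pos)])
    for (k in bad) pos[k] <- which(free[k, ])[1L]
    out[, g] <- pos
    free[cbind(seq_len(m), pos)] <- FALSE
  }
  out
}

perm_costs <- function(perms, cost) {
  G <- ncol(perms)
  vapply(seq_len(nrow(perms)), function(k)
    sum(cost[cbind(seq_len(G), perms[k, ])]), numeric(1))
}

#' @exportS3Method base::print
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("consensus ranking (%s%s), objective = %.4g\n", x$method,
              if (x$weighted) ", weighted" else "", x$objective))
  print(data.frame(rank = seq_along(x$ordering), gene = x$ordering))
  invisible(x)
}
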