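#' Brute-force oracles
#'
#' Independent, naive reimplementations of the package's core quantities,
#' used by the test suite to validate the production code paths. Each
#' oracle deliberately shares no code with the module it checks:
#' iterative matrix relaxation instead of memoized BFS for path lengths,
#' explicit transitive closure for descendant sums, a dense linear solve
#' for PageRank, and O(n^2) rank counting plus the raw Pearson sum
#' formula for Spearman.
#'
#' @name oracles
NULL

#' @describeIn oracles Full matrix of minimum upward edge distances
#'   (concept to ancestor), by Bellman-Ford-style relaxation over parent
#'   edges until fixpoint. `Inf` where no upward path exists.
#' @param t a `taxonomy`.
#' @export
oracle_up_distances <- function(t) {
  n <- length(t$concepts)
  U <- matrix(Inf, n, n, dimnames = list(t$concepts, t$concepts))
  diag(U) <- 0
  repeat {
    changed <- FALSE
    for (u in t$concepts) {
      for (v in t$parents[[u]]) {
        relaxed <- pmin(U[u, ], U[v, ] + 1)
        if (any(relaxed < U[u, ])) {
          U[u, ] <- relaxed
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  U
}

#' @describeIn oracles Shortest path and LCS by exhaustive enumeration of
#'   all common subsumers; same tie-break convention as [shortest_path()]
#'   (greater depth, then lexicographic id).
#' @param c1,c2 concept ids.
#' @param U optional precomputed [oracle_up_distances()] matrix.
#' @export
oracle_shortest_path <- function(t, c1, c2, U = oracle_up_distances(t)) {
  common <- t$concepts[is.finite(U[c1, ]) & is.finite(U[c2, ])]
  tot <- U[c1, common] + U[c2, common]
  p <- min(tot)
  cand <- common[tot == p]
  cand <- cand[t$depth[cand] == max(t$depth[cand])]
  list(p = as.integer(p) + 1L, lcs = min(cand))
}

#' @describeIn oracles Aggregated frequency of one concept by explicit
#'   transitive-closure descendant sets (no reliance on topological
#'   propagation), confirming no multi-path double counting.
#' @param raw named numeric vector of raw counts (missing concepts 0).
#' @param concept the concept whose aggregated count is wanted.
#' @export
oracle_descendant_sum <- function(t, raw, concept) {
  n <- length(t$concepts)
  A <- matrix(FALSE, n, n, dimnames = list(t$concepts, t$concepts))
  for (p in t$concepts) for (ch in t$children[[p]]) A[p, ch] <- TRUE
  reach <- A
  repeat {
    nxt <- reach | ((reach %*% A) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  full <- stats::setNames(numeric(n), t$concepts)
  raw <- unlist(raw)
  full[intersect(names(raw), t$concepts)] <- raw[intersect(names(raw), t$concepts)]
  full[[concept]] + sum(full[reach[concept, ]])
}

#' @describeIn oracles Personalized PageRank by dense linear solve of
#'   `(I - cM) P = (1 - c) v`, with dangling columns redirected to the
#'   seed to mirror [ppr_vector()]'s mass-return convention.
#' @param graph a `ppr_graph`.
#' @param seed seed concept id.
#' @param damping damping factor.
#' @export
oracle_ppr_dense <- function(graph, seed, damping = 0.85) {
  n <- graph$n
  si <- match(seed, graph$concepts)
  A <- as.matrix(graph$adj)
  deg <- colSums(A)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (deg[i] > 0) M[, i] <- A[, i] / deg[i] else M[si, i] <- 1
  }
  v <- numeric(n); v[si] <- 1
  P <- solve(diag(n) - damping * M, (1 - damping) * v)
  P <- P / sum(P)
  stats::setNames(P, graph$concepts)
}

#' @describeIn oracles Spearman correlation by O(n^2) fractional-rank
#'   counting and the explicit Pearson sum formula.
#' @param x,y numeric vectors.
#' @export
oracle_spearman <- function(x, y) {
  brute_rank <- function(v) {
    vapply(seq_along(v),
           function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
           numeric(1))
  }
  rx <- brute_rank(x); ry <- brute_rank(y)
  n <- length(x)
  num <- n * sum(rx * ry) - sum(rx) * sum(ry)
  den <- sqrt((n * sum(rx^2) - sum(rx)^2) * (n * sum(ry^2) - sum(ry)^2))
  num / den
}
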