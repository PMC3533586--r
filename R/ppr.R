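#' Build an undirected graph for personalized PageRank
#'
#' Two graph modes: `"taxonomy"` uses only the taxonomic edges of the
#' concept graph (undirected); `"all"` additionally merges the labelled
#' non-taxonomic edges, so relatedness can leverage non-hierarchical
#' relationships. Reciprocal duplicates and repeated labels collapse to a
#' single undirected edge; isolated vertices are permitted.
#'
#' @param g a [concept_graph()].
#' @param mode `"taxonomy"` or `"all"`.
#' @return An object of class `ppr_graph`: list with `concepts` (sorted),
#'   `n`, `adj` (sparse symmetric 0/1 adjacency, no self-loops), `degree`
#'   (per-vertex neighbor count), and `mode`.
#' @export
build_ppr_graph <- function(g, mode = c("taxonomy", "all")) {
  if (!inherits(g, "concept_graph")) stop("g must be a concept_graph")
  if (length(g$concepts) == 0L) stop("empty concept graph")
  mode <- match.arg(mode)
  concepts <- sort(g$concepts)
  n <- length(concepts)
  id <- stats::setNames(seq_len(n), concepts)

  a <- id[g$taxonomic_edges$child]
  b <- id[g$taxonomic_edges$parent]
  if (mode == "all" && nrow(g$other_edges)) {
    a <- c(a, id[g$other_edges$c1])
    b <- c(b, id[g$other_edges$c2])
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(cbind(lo, hi)) & lo != hi
  lo <- lo[keep]; hi <- hi[keep]

  adj <- Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1,
                              dims = c(n, n))
  structure(list(concepts = concepts, n = n, adj = adj,
                 degree = stats::setNames(Matrix::colSums(adj), concepts),
                 mode = mode),
            class = "ppr_graph")
}

#' @export
print.ppr_graph <- function(x, ...) {
  cat(sprintf("ppr_graph (%s): %d vertices, %d undirected edges\n",
              x$mode, x$n, sum(x$degree) / 2))
  invisible(x)
}

#' Personalized PageRank vector for a seed concept
#'
#' Solves `P = c M P + (1 - c) v` by power iteration, where `M` is the
#' column-stochastic transition matrix of the undirected graph
#' (`M[j, i] = 1/degree(i)` for each neighbor `j` of `i`), `v` is the
#' indicator vector of the seed concept, and `c` is the damping factor
#' weighting edge navigation against teleportation (default 0.85).
#' Probability mass arriving at vertices with no neighbors has nowhere to
#' flow and is returned to the seed, preserving the personalization
#' semantics. Iteration stops when the L1 change drops below `tol`; the
#' result is normalized to sum to 1 and entries below `1e-12` are
#' truncated to keep the vector sparse.
#'
#' @param graph a `ppr_graph`.
#' @param seed a concept id present in the graph.
#' @param damping damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence yields a warning (with
#'   the residual) but still returns the current vector.
#' @return An object of class `ppr_vector`: list with `scores` (named
#'   numeric summing to 1), `seed`, `damping`, `iterations`, `residual`,
#'   and `concepts` (the vertex universe, used to detect graph mismatch).
#' @export
ppr_vector <- function(graph, seed, damping = 0.85, tol = 1e-9,
                       max_iter = 100L) {
  if (!inherits(graph, "ppr_graph")) stop("graph must be a ppr_graph")
  if (!seed %in% graph$concepts) {
    stop(sprintf("missing concept: '%s' is not in the PPR graph", seed))
  }
  if (damping <= 0 || damping >= 1) stop("damping must lie strictly in (0, 1)")
  n <- graph$n
  si <- match(seed, graph$concepts)
  deg <- unname(graph$degree)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  # M %*% P with column-normalized adjacency; adj is symmetric so
  # M P = adj %*% (P / deg)
  dangling <- deg == 0

  v <- numeric(n); v[si] <- 1
  P <- v
  iters <- 0L
  resid <- Inf
  while (iters < max_iter) {
    iters <- iters + 1L
    flow <- as.numeric(graph$adj %*% (P * inv_deg))
    lost <- sum(P[dangling])
    Pn <- damping * flow + (1 - damping) * v
    Pn[si] <- Pn[si] + damping * lost
    resid <- sum(abs(Pn - P))
    P <- Pn
    if (resid < tol) break
  }
  if (resid >= tol) {
    warning(sprintf("PPR did not converge in %d iterations (L1 residual %.3e)",
                    max_iter, resid))
  }
  P[P < 1e-12] <- 0
  P <- P / sum(P)
  structure(list(scores = stats::setNames(P, graph$concepts), seed = seed,
                 damping = damping, iterations = iters, residual = resid,
                 concepts = graph$concepts),
            class = "ppr_vector")
}

#' Cosine relatedness of two personalized PageRank vectors
#'
#' The relatedness of two concepts is the cosine of the angle between
#' their PPR probability vectors; both vectors must come from the same
#' graph. Since the vectors are non-negative, the score lies in `[0, 1]`.
#'
#' @param a,b `ppr_vector` objects over the same graph.
#' @return Numeric relatedness in `[0, 1]`.
#' @export
ppr_relatedness <- function(a, b) {
  if (!inherits(a, "ppr_vector") || !inherits(b, "ppr_vector")) {
    stop("a and b must be ppr_vector objects")
  }
  if (!identical(a$concepts, b$concepts)) {
    stop("PPR graph mismatch: the two vectors were computed over different graphs")
  }
  x <- unname(a$scores); y <- unname(b$scores)
  num <- sum(x * y)
  if (num == 0) return(0)
  num / sqrt(sum(x^2) * sum(y^2))
}

#' One-call PPR relatedness for a concept pair
#'
#' @param graph a `ppr_graph`.
#' @param c1,c2 concept ids.
#' @inheritParams ppr_vector
#' @return Numeric relatedness in `[0, 1]`.
#' @export
ppr_similarity <- function(graph, c1, c2, damping = 0.85, tol = 1e-9,
                           max_iter = 100L) {
  ppr_relatedness(ppr_vector(graph, c1, damping, tol, max_iter),
                  ppr_vector(graph, c2, damping, tol, max_iter))
}
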