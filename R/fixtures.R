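#' The toy taxonomy T0
#'
#' Five concepts `{R, A, B, C, D}` with taxonomic edges `C -> A`,
#' `D -> A`, `A -> R`, `B -> R`: a single root `R`, an inner concept `A`
#' with two leaf children, and a leaf `B` directly under the root. Every
#' worked example in the package documentation refers to the taxonomy
#' built from T0 (depths `R:1, A:2, B:2, C:3, D:3`; maximum depth 3;
#' leaves `{B, C, D}`).
#'
#' @return A [concept_graph()].
#' @export
toy_T0 <- function() {
  concept_graph(
    taxonomic_edges = data.frame(
      child = c("C", "D", "A", "B"),
      parent = c("A", "A", "R", "R"),
      stringsAsFactors = FALSE),
    metadata = list(source = "toy_T0")
  )
}

# run fn with a private, restored RNG state seeded with `seed`
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Random rooted DAG generator
#'
#' Concepts are created in a fixed order; every concept after the first
#' draws between 1 and `max_parents` parents uniformly from the earlier
#' concepts, so the taxonomic edge set respects a topological order and
#' is acyclic and single-rooted by construction. Labelled non-taxonomic
#' edges are added independently with probability `p_extra_edge` per
#' concept (to a uniformly drawn non-adjacent concept, label
#' `"related_to"`). Deterministic: the same `seed` yields the identical
#' graph; the caller's RNG state is untouched.
#'
#' @param n_concepts number of concepts (`>= 1`).
#' @param max_parents maximum parents per concept.
#' @param p_extra_edge probability of one extra non-taxonomic edge per
#'   concept.
#' @param seed integer RNG seed.
#' @return A [concept_graph()].
#' @export
random_dag <- function(n_concepts = 20L, max_parents = 2L, p_extra_edge = 0,
                       seed = 1L) {
  stopifnot(n_concepts >= 1L, max_parents >= 1L)
  ids <- sprintf("N%03d", seq_len(n_concepts))
  .with_seed(seed, function() {
    child <- character(0); parent <- character(0)
    for (i in seq_len(n_concepts)[-1L]) {
      k <- sample.int(min(max_parents, i - 1L), 1L)
      ps <- sample.int(i - 1L, k)
      child <- c(child, rep(ids[i], k))
      parent <- c(parent, ids[ps])
    }
    oc1 <- character(0); oc2 <- character(0)
    if (p_extra_edge > 0 && n_concepts >= 2L) {
      for (i in seq_len(n_concepts)) {
        if (stats::runif(1) < p_extra_edge) {
          j <- sample(seq_len(n_concepts)[-i], 1L)
          oc1 <- c(oc1, ids[i]); oc2 <- c(oc2, ids[j])
        }
      }
    }
    oe <- if (length(oc1)) {
      data.frame(c1 = oc1, c2 = oc2, label = "related_to",
                 stringsAsFactors = FALSE)
    } else NULL
    concept_graph(concepts = ids,
                  taxonomic_edges = data.frame(child = child, parent = parent,
                                               stringsAsFactors = FALSE),
                  other_edges = oe,
                  metadata = list(source = sprintf("random_dag(seed=%d)", seed)))
  })
}

#' Synthetic benchmark generated from a similarity measure
#'
#' Samples `n_pairs` distinct unordered concept pairs and sets each rating
#' to a strictly increasing transform of the generating measure plus
#' Gaussian noise: `rating = 10 * sim + rnorm(sd = noise_sd)`. With
#' `noise_sd = 0` the generating measure (and any measure monotone in the
#' same underlying quantity) recovers Spearman correlation exactly 1.
#'
#' @param t a `taxonomy`.
#' @param measure generating measure name (see [concept_similarity()]).
#' @param noise_sd standard deviation of the additive Gaussian noise, on
#'   the rating scale (ratings span roughly 0-10).
#' @param n_pairs number of pairs (capped at the number of distinct
#'   unordered pairs).
#' @param seed integer RNG seed.
#' @param ic,ppr_graph passed to [concept_similarity()] when needed.
#' @return A `benchmark` data frame (see [read_benchmark()]).
#' @export
synthetic_benchmark <- function(t, measure = "path", noise_sd = 0,
                                n_pairs = 50L, seed = 1L, ic = NULL,
                                ppr_graph = NULL) {
  n <- length(t$concepts)
  all_pairs <- utils::combn(n, 2L)
  n_pairs <- min(n_pairs, ncol(all_pairs))
  .with_seed(seed, function() {
    take <- sample.int(ncol(all_pairs), n_pairs)
    b <- data.frame(concept1 = t$concepts[all_pairs[1L, take]],
                    concept2 = t$concepts[all_pairs[2L, take]],
                    stringsAsFactors = FALSE)
    s <- concept_similarity(t, b, measures = measure, ic = ic,
                            ppr_graph = ppr_graph)[[measure]]
    b$rating <- 10 * s + stats::rnorm(n_pairs, sd = noise_sd)
    attr(b, "name") <- sprintf("synthetic(%s, sd=%g, seed=%d)",
                               measure, noise_sd, seed)
    class(b) <- c("benchmark", "data.frame")
    b
  })
}
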