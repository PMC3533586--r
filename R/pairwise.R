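#' Ancestors of a concept with minimum edge distances
#'
#' Traverses parent links upward from `c` and returns the minimum number of
#' edges to every subsumer, including `c` itself at distance 0. Results are
#' memoized inside the taxonomy's cache environment, so repeated pairwise
#' queries over the same taxonomy are cheap.
#'
#' @param t a `taxonomy`.
#' @param c a concept id.
#' @return Named integer vector: ancestor id -> minimum edge distance.
#' @export
ancestors_with_distance <- function(t, c) {
  .check_concept(t, c)
  key <- paste0("anc:", c)
  hit <- t$cache[[key]]
  if (!is.null(hit)) return(hit)
  dist <- stats::setNames(0L, c)
  frontier <- c
  lvl <- 0L
  while (length(frontier)) {
    lvl <- lvl + 1L
    up <- unique(unlist(t$parents[frontier], use.names = FALSE))
    up <- up[!up %in% names(dist)]
    if (!length(up)) break
    dist[up] <- lvl
    frontier <- up
  }
  t$cache[[key]] <- dist
  dist
}

#' Shortest taxonomic path between two concepts
#'
#' The path runs from `c1` up to a common subsumer and down to `c2`; its
#' length `p` is a node count, so `p = 1` iff the concepts are identical.
#' Among common subsumers minimizing the path, ties are broken by greater
#' depth, then by lexicographic id.
#'
#' @param t a `taxonomy`.
#' @param c1,c2 concept ids.
#' @return A list of class `path_result` with fields `p` (node count) and
#'   `lcs` (the least common subsumer on the minimizing path).
#' @export
shortest_path <- function(t, c1, c2) {
  a1 <- ancestors_with_distance(t, c1)
  a2 <- ancestors_with_distance(t, c2)
  common <- intersect(names(a1), names(a2))
  tot <- a1[common] + a2[common]
  best <- tot == min(tot)
  cand <- common[best]
  cand <- cand[t$depth[cand] == max(t$depth[cand])]
  lcs <- min(cand)
  structure(list(p = unname(min(tot)) + 1L, lcs = lcs), class = "path_result")
}

#' Least common subsumer by maximal information content
#'
#' Returns the common subsumer of `c1` and `c2` with the greatest IC;
#' ties are broken lexicographically. This is the subsumer used by the
#' IC-based measures; the path-based measures use the subsumer on the
#' shortest path, which may differ.
#'
#' @param t a `taxonomy`.
#' @param ic an `ic_table` covering all concepts (see [intrinsic_ic()]).
#' @param c1,c2 concept ids.
#' @return A concept id.
#' @export
lcs_by_ic <- function(t, ic, c1, c2) {
  a1 <- ancestors_with_distance(t, c1)
  a2 <- ancestors_with_distance(t, c2)
  common <- intersect(names(a1), names(a2))
  v <- ic$values[common]
  min(common[v == max(v)])
}
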