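#' Pairwise similarity measures
#'
#' Seven measures over a rooted taxonomy, all symmetric, all equal to 1
#' for a concept paired with itself, and all mapping into `[0, 1]` (the
#' Jiang-Conrath distance excepted, which is a distance `>= 0`).
#'
#' With `p` the node count of the shortest taxonomic path, `d` the maximum
#' taxonomy depth, and `IC` an intrinsic or corpus information-content
#' table with maximum `ic_max`:
#' \describe{
#'   \item{`sim_path`}{`1/p`.}
#'   \item{`sim_lch`}{`1 - log(p)/log(2d)` — Leacock-Chodorow, scaled to
#'     the unit interval (dividing by the constant `log(2d)` leaves rank
#'     orderings, hence Spearman correlations, unchanged).}
#'   \item{`sim_wupalmer`}{`2*depth(lcs) / ((p - 1) + 2*depth(lcs))`, with
#'     the least common subsumer on the shortest path; equals 1 when the
#'     concepts are identical since then `p - 1 = 0`.}
#'   \item{`sim_lin`}{`2*IC(lcs) / (IC(c1) + IC(c2))` with the
#'     maximum-IC common subsumer; 1 by convention for identical concepts,
#'     0 when the denominator vanishes (both concepts at IC 0).}
#'   \item{`dist_jc`}{`IC(c1) + IC(c2) - 2*IC(lcs)` — Jiang-Conrath
#'     semantic distance, 0 for identical concepts.}
#'   \item{`sim_lch_ic`}{`1 - log(dist_jc + 1)/log(2*ic_max + 1)` — the
#'     IC reformulation of LCH (the `+1` terms keep the logarithms
#'     defined and the value in the unit interval).}
#'   \item{`sim_path_ic`}{`1 / (dist_jc + 1)` — the IC reformulation of
#'     Path.}
#' }
#'
#' @param t a `taxonomy`.
#' @param ic an `ic_table` ([intrinsic_ic()] or [corpus_ic()]).
#' @param c1,c2 concept ids; unknown ids raise a missing-concept error.
#' @return A single numeric score.
#' @name similarity-measures
NULL

#' @rdname similarity-measures
#' @export
sim_path <- function(t, c1, c2) {
  1 / shortest_path(t, c1, c2)$p
}

#' @rdname similarity-measures
#' @export
sim_lch <- function(t, c1, c2) {
  p <- shortest_path(t, c1, c2)$p
  1 - log(p) / log(2 * t$d)
}

#' @rdname similarity-measures
#' @export
sim_wupalmer <- function(t, c1, c2) {
  pr <- shortest_path(t, c1, c2)
  dl <- unname(t$depth[pr$lcs])
  2 * dl / ((pr$p - 1) + 2 * dl)
}

#' @rdname similarity-measures
#' @export
sim_lin <- function(t, ic, c1, c2) {
  .check_concept(t, c1); .check_concept(t, c2)
  if (c1 == c2) return(1)
  denom <- ic$values[[c1]] + ic$values[[c2]]
  if (denom == 0) return(0)
  2 * ic$values[[lcs_by_ic(t, ic, c1, c2)]] / denom
}

#' @rdname similarity-measures
#' @export
dist_jc <- function(t, ic, c1, c2) {
  .check_concept(t, c1); .check_concept(t, c2)
  if (c1 == c2) return(0)
  d <- ic$values[[c1]] + ic$values[[c2]] - 2 * ic$values[[lcs_by_ic(t, ic, c1, c2)]]
  if (d < -1e-9) stop("negative Jiang-Conrath distance: IC table violates ancestry monotonicity")
  max(d, 0)
}

#' @rdname similarity-measures
#' @export
sim_lch_ic <- function(t, ic, c1, c2) {
  d <- dist_jc(t, ic, c1, c2)
  if (d == 0) return(1)
  1 - log(d + 1) / log(2 * ic$ic_max + 1)
}

#' @rdname similarity-measures
#' @export
sim_path_ic <- function(t, ic, c1, c2) {
  1 / (dist_jc(t, ic, c1, c2) + 1)
}

.MEASURES <- c("path", "lch", "wupalmer", "lin", "jc", "lch_ic", "path_ic", "ppr")
.IC_MEASURES <- c("lin", "jc", "lch_ic", "path_ic")

#' Compute similarity measures for a table of concept pairs
#'
#' Vectorized front-end over the individual measures; used by the CLI and
#' by benchmark evaluation. Measure names: `"path"`, `"lch"`,
#' `"wupalmer"`, `"lin"`, `"jc"` (Jiang-Conrath distance), `"lch_ic"`,
#' `"path_ic"`, `"ppr"` (personalized-PageRank cosine relatedness, needs
#' `ppr_graph`).
#'
#' @param t a `taxonomy`.
#' @param pairs data frame (or 2-column matrix) whose first two columns
#'   are concept ids.
#' @param measures character vector of measure names.
#' @param ic an `ic_table`; required for the IC-based measures.
#' @param ppr_graph a `ppr_graph` (see [build_ppr_graph()]); required for
#'   `"ppr"`.
#' @param damping,tol,max_iter PageRank parameters, see [ppr_vector()].
#' @return `pairs` with one numeric column appended per measure.
#' @export
concept_similarity <- function(t, pairs, measures = c("path", "lch", "wupalmer"),
                               ic = NULL, ppr_graph = NULL,
                               damping = 0.85, tol = 1e-9, max_iter = 100L) {
  bad <- setdiff(measures, .MEASURES)
  if (length(bad)) {
    stop("unknown measure(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(.MEASURES, collapse = ", "), ")")
  }
  if (any(measures %in% .IC_MEASURES) && is.null(ic)) {
    stop("measures ", paste(intersect(measures, .IC_MEASURES), collapse = ", "),
         " require an ic_table")
  }
  if ("ppr" %in% measures && is.null(ppr_graph)) {
    stop("measure 'ppr' requires a ppr_graph")
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  c1 <- as.character(pairs[[1L]])
  c2 <- as.character(pairs[[2L]])

  ppr_cache <- new.env(parent = emptyenv())
  get_ppr <- function(c) {
    v <- ppr_cache[[c]]
    if (is.null(v)) {
      v <- ppr_vector(ppr_graph, c, damping = damping, tol = tol,
                      max_iter = max_iter)
      ppr_cache[[c]] <- v
    }
    v
  }
  one <- function(m, i) {
    switch(m,
      path     = sim_path(t, c1[i], c2[i]),
      lch      = sim_lch(t, c1[i], c2[i]),
      wupalmer = sim_wupalmer(t, c1[i], c2[i]),
      lin      = sim_lin(t, ic, c1[i], c2[i]),
      jc       = dist_jc(t, ic, c1[i], c2[i]),
      lch_ic   = sim_lch_ic(t, ic, c1[i], c2[i]),
      path_ic  = sim_path_ic(t, ic, c1[i], c2[i]),
      ppr      = ppr_relatedness(get_ppr(c1[i]), get_ppr(c2[i]))
    )
  }
  for (m in measures) {
    pairs[[m]] <- vapply(seq_along(c1), function(i) one(m, i), numeric(1))
  }
  pairs
}
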