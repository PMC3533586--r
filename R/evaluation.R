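#' Read a similarity benchmark
#'
#' Format: `concept1<TAB>concept2<TAB>rating` per line, `#` comments
#' allowed; ratings are the (mean) human judgements. Duplicate unordered
#' pairs are a validation error; malformed lines are reported with their
#' line numbers.
#'
#' @param x file path, connection, or character vector of lines.
#' @param name benchmark name (attached as attribute).
#' @return A data frame of class `benchmark` with columns `concept1`,
#'   `concept2`, `rating`, in file order.
#' @export
read_benchmark <- function(x, name = "benchmark") {
  lines <- .read_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop(sprintf("benchmark parse error at line %d: expected concept1<TAB>concept2<TAB>rating",
                 idx[which(bad)[1L]]))
  }
  c1 <- vapply(fields, `[`, "", 1L)
  c2 <- vapply(fields, `[`, "", 2L)
  rating <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(rating) || any(!is.finite(rating))) {
    stop(sprintf("benchmark parse error at line %d: non-numeric rating",
                 idx[which(!is.finite(rating))[1L]]))
  }
  key <- paste(pmin(c1, c2), pmax(c1, c2))
  if (anyDuplicated(key)) {
    stop(sprintf("benchmark validation error: duplicate unordered pair at line %d",
                 idx[which(duplicated(key))[1L]]))
  }
  b <- data.frame(concept1 = c1, concept2 = c2, rating = rating,
                  stringsAsFactors = FALSE)
  attr(b, "name") <- name
  class(b) <- c("benchmark", "data.frame")
  b
}

#' Spearman rank correlation
#'
#' Ties get average (fractional) ranks; the coefficient is the Pearson
#' correlation of the rank vectors, which is exact under ties. Invariant
#' under strictly increasing transforms of either variable.
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("spearman correlation requires at least 3 observations")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0) {
    stop("spearman correlation undefined: zero rank variance")
  }
  stats::cor(x, y, method = "spearman")
}

#' Fisher r-to-z test for the difference of two correlations
#'
#' Independent-samples form: `z = (atanh(r1) - atanh(r2)) /
#' sqrt(1/(n1-3) + 1/(n2-3))`, with a two-sided p-value from the standard
#' normal. Note that correlations of different measures against the *same*
#' benchmark are dependent; this test (the one classically reported for
#' such comparisons) ignores that dependence and is conservative-to-
#' anticonservative depending on the inter-measure correlation.
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n1,n2 sample sizes, both `> 3`.
#' @return List with `z` and two-sided `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("fisher r-to-z requires n > 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("fisher r-to-z undefined for |r| = 1 (infinite transform)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Evaluate similarity measures against a benchmark
#'
#' Computes each measure on the benchmark's concept pairs and reports the
#' Spearman correlation with the human ratings. Pairs with concepts
#' missing from the taxonomy (or PPR graph, for `"ppr"`) are skipped, not
#' scored 0, and reported, so the effective `n` is always explicit.
#'
#' @param t a `taxonomy`.
#' @param benchmark a `benchmark` (see [read_benchmark()]).
#' @param measures measure names, see [concept_similarity()] (`"jc"` is a
#'   distance and not meaningful here; similarities only).
#' @param ic an `ic_table`; required for IC-based measures.
#' @param ppr_graph a `ppr_graph`; required for `"ppr"`.
#' @param compare if `TRUE`, attach pairwise Fisher r-to-z statistics
#'   between all measure correlations as attributes `fisher_z` /
#'   `fisher_p`.
#' @param damping,tol,max_iter PageRank parameters.
#' @return Data frame with one row per measure: `measure`, `rho`, `n`,
#'   `skipped`. The skipped pair indices are attached as attribute
#'   `skipped_pairs`.
#' @export
evaluate_benchmark <- function(t, benchmark, measures = c("path", "lch", "wupalmer"),
                               ic = NULL, ppr_graph = NULL, compare = FALSE,
                               damping = 0.85, tol = 1e-9, max_iter = 100L) {
  known <- benchmark$concept1 %in% t$concepts & benchmark$concept2 %in% t$concepts
  if ("ppr" %in% measures) {
    known <- known & benchmark$concept1 %in% ppr_graph$concepts &
      benchmark$concept2 %in% ppr_graph$concepts
  }
  skipped <- which(!known)
  if (length(skipped)) {
    message(sprintf("evaluate_benchmark: skipped %d pair(s) with unresolvable concepts",
                    length(skipped)))
  }
  bm <- benchmark[known, , drop = FALSE]
  scores <- concept_similarity(t, bm[, c("concept1", "concept2")],
                               measures = measures, ic = ic,
                               ppr_graph = ppr_graph, damping = damping,
                               tol = tol, max_iter = max_iter)
  res <- data.frame(
    measure = measures,
    rho = vapply(measures, function(m) spearman_rho(scores[[m]], bm$rating),
                 numeric(1)),
    n = nrow(bm),
    skipped = length(skipped),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  attr(res, "skipped_pairs") <- skipped
  if (compare && length(measures) > 1L) {
    k <- length(measures)
    zmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) { zmat[i, j] <- 0; pmat[i, j] <- 1; next }
      # |rho| = 1 makes the transform infinite; report NA rather than fail
      fz <- tryCatch(fisher_r_to_z(res$rho[i], res$n[i], res$rho[j], res$n[j]),
                     error = function(e) list(z = NA_real_, p = NA_real_))
      zmat[i, j] <- fz$z; pmat[i, j] <- fz$p
    }
    attr(res, "fisher_z") <- zmat
    attr(res, "fisher_p") <- pmat
  }
  res
}
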