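#' All-pairs similarity matrices
#'
#' Computes the full concept-by-concept matrix for each requested measure
#' in one pass: the pairwise structural quantities (shortest-path node
#' count, path-LCS depth, maximum common-subsumer IC) are computed once
#' per unordered pair and shared across measures, and PPR vectors for all
#' seeds are power-iterated simultaneously as one matrix. Self-similarity
#' conventions (diagonal 1; Jiang-Conrath diagonal 0) are applied exactly.
#'
#' @param t a `taxonomy`.
#' @param measures measure names, see [concept_similarity()].
#' @param ic an `ic_table`; required for IC-based measures.
#' @param ppr_graph a `ppr_graph`; required for `"ppr"`.
#' @param damping,tol,max_iter PageRank parameters.
#' @return Named list of symmetric numeric matrices, one per measure,
#'   with concept ids as dimnames.
#' @export
similarity_matrices <- function(t, measures = c("path", "lch", "wupalmer"),
                                ic = NULL, ppr_graph = NULL,
                                damping = 0.85, tol = 1e-9, max_iter = 100L) {
  bad <- setdiff(measures, .MEASURES)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  need_ic <- any(measures %in% .IC_MEASURES)
  if (need_ic && is.null(ic)) stop("IC-based measures require an ic_table")
  if ("ppr" %in% measures && is.null(ppr_graph)) stop("measure 'ppr' requires a ppr_graph")

  cs <- t$concepts
  n <- length(cs)
  need_path <- any(measures %in% c("path", "lch", "wupalmer"))
  out <- list()

  if (need_path || need_ic) {
    anc <- lapply(cs, function(c) ancestors_with_distance(t, c))
    P <- matrix(1L, n, n, dimnames = list(cs, cs))
    DL <- matrix(0L, n, n, dimnames = list(cs, cs))
    ICL <- if (need_ic) matrix(0, n, n, dimnames = list(cs, cs))
    for (i in seq_len(n)) {
      a1 <- anc[[i]]
      for (j in i:n) {
        a2 <- anc[[j]]
        common <- intersect(names(a1), names(a2))
        tot <- a1[common] + a2[common]
        m <- min(tot)
        P[i, j] <- P[j, i] <- m + 1L
        if (need_path) {
          cand <- common[tot == m]
          cand <- cand[t$depth[cand] == max(t$depth[cand])]
          dl <- t$depth[[min(cand)]]
          DL[i, j] <- DL[j, i] <- dl
        }
        if (need_ic) {
          v <- max(ic$values[common])
          ICL[i, j] <- ICL[j, i] <- v
        }
      }
    }
    if ("path" %in% measures) out$path <- 1 / P
    if ("lch" %in% measures) out$lch <- 1 - log(P) / log(2 * t$d)
    if ("wupalmer" %in% measures) out$wupalmer <- 2 * DL / ((P - 1) + 2 * DL)
    if (need_ic) {
      icv <- ic$values[cs]
      denom <- outer(icv, icv, "+")
      D <- denom - 2 * ICL
      D[D < 0] <- 0
      diag(D) <- 0
      if ("lin" %in% measures) {
        lin <- ifelse(denom > 0, 2 * ICL / pmax(denom, .Machine$double.xmin), 0)
        diag(lin) <- 1
        dimnames(lin) <- list(cs, cs)
        out$lin <- lin
      }
      if ("jc" %in% measures) out$jc <- D
      if ("lch_ic" %in% measures) {
        out$lch_ic <- if (ic$ic_max > 0) {
          1 - log(D + 1) / log(2 * ic$ic_max + 1)
        } else matrix(1, n, n, dimnames = list(cs, cs))
      }
      if ("path_ic" %in% measures) out$path_ic <- 1 / (D + 1)
    }
  }
  if ("ppr" %in% measures) {
    V <- .ppr_matrix(ppr_graph, damping, tol, max_iter)
    norms <- sqrt(colSums(V^2))
    C <- crossprod(V) / outer(norms, norms)
    C[C > 1] <- 1
    diag(C) <- 1
    dimnames(C) <- list(ppr_graph$concepts, ppr_graph$concepts)
    out$ppr <- C
  }
  out[measures]
}

# PPR vectors for every seed at once: columns of P follow the same update
# as ppr_vector(), with each column's dangling mass returned to its own seed.
.ppr_matrix <- function(graph, damping = 0.85, tol = 1e-9, max_iter = 100L) {
  n <- graph$n
  deg <- unname(graph$degree)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  dangling <- deg == 0
  P <- diag(n)
  resid <- Inf
  iters <- 0L
  while (iters < max_iter) {
    iters <- iters + 1L
    flow <- as.matrix(graph$adj %*% (P * inv_deg))
    lost <- colSums(P[dangling, , drop = FALSE])
    Pn <- damping * flow
    diag(Pn) <- diag(Pn) + (1 - damping) + damping * lost
    resid <- max(colSums(abs(Pn - P)))
    P <- Pn
    if (resid < tol) break
  }
  if (resid >= tol) {
    warning(sprintf("PPR did not converge in %d iterations (max L1 residual %.3e)",
                    max_iter, resid))
  }
  P[P < 1e-12] <- 0
  P <- sweep(P, 2L, colSums(P), "/")
  colnames(P) <- rownames(P) <- graph$concepts
  P
}
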