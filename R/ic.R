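#' Intrinsic information content from taxonomy structure
#'
#' IC is estimated from the taxonomy alone, following the
#' leaves-to-subsumers formulation:
#' \deqn{IC(c) = -\log\frac{|leaves(c)|/|subsumers(c)| + 1}{max\_leaves + 1}}
#' with natural logarithm. The more leaves a concept subsumes relative to
#' its number of ancestors, the less information it carries; the root has
#' IC exactly 0 and every child has strictly greater IC than each parent.
#'
#' @param t a `taxonomy` (leaf/subsumer counts are precomputed by
#'   [build_taxonomy()]).
#' @return An object of class `ic_table`: list with `values` (named
#'   numeric, all finite and >= 0), `kind = "intrinsic"`, and `ic_max`.
#' @export
intrinsic_ic <- function(t) {
  if (!inherits(t, "taxonomy")) stop("t must be a taxonomy")
  v <- -log((t$n_leaves / t$n_subsumers + 1) / (t$max_leaves + 1))
  v[v < 0] <- 0  # guard against -0 / rounding at the root
  structure(list(values = v, kind = "intrinsic", ic_max = max(v)),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("ic_table (%s): %d concepts, ic_max = %.4f\n",
              x$kind, length(x$values), x$ic_max))
  invisible(x)
}

#' Aggregate raw concept frequencies over descendants
#'
#' The aggregated frequency of a concept is the sum of raw corpus counts
#' over the concept and the *set* of its descendants: a descendant
#' reachable by several parent paths is counted once. Concepts absent from
#' `raw` get a raw count of 0; counts for ids not in the taxonomy are
#' dropped with a warning.
#'
#' @param t a `taxonomy`.
#' @param raw named non-negative numeric vector of raw counts.
#' @return An object of class `frequency_table`: list with `raw` and
#'   `aggregated` (both named over all concepts) and `root`.
#' @export
aggregate_frequencies <- function(t, raw) {
  if (!inherits(t, "taxonomy")) stop("t must be a taxonomy")
  raw <- unlist(raw)
  if (any(raw < 0)) stop("frequency validation error: negative raw count")
  unknown <- setdiff(names(raw), t$concepts)
  if (length(unknown)) {
    warning(sprintf("ignoring counts for %d concept(s) not in the taxonomy: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5L), collapse = ", ")))
    raw <- raw[!names(raw) %in% unknown]
  }
  full <- stats::setNames(numeric(length(t$concepts)), t$concepts)
  full[names(raw)] <- raw

  n <- length(t$concepts)
  id <- stats::setNames(seq_len(n), t$concepts)
  children_idx <- lapply(t$children, function(v) unname(id[v]))
  parents_idx <- lapply(t$parents, function(v) unname(id[v]))
  topo <- .topo_order(parents_idx, children_idx, unname(id[t$root]), n)

  # descendant sets leaf-up, set semantics (no multi-path double counting)
  desc <- vector("list", n)
  agg <- numeric(n)
  for (i in rev(topo)) {
    kids <- children_idx[[i]]
    desc[[i]] <- if (length(kids)) {
      sort(unique(c(kids, unlist(desc[kids], use.names = FALSE))))
    } else integer(0)
    agg[i] <- full[i] + sum(full[desc[[i]]])
  }
  structure(list(raw = full,
                 aggregated = stats::setNames(agg, t$concepts),
                 root = t$root),
            class = "frequency_table")
}

#' Corpus information content from aggregated frequencies
#'
#' \eqn{IC(c) = -\log(freq(c)/freq(root))}, natural logarithm, so the root
#' has IC 0 and IC is non-negative. Concepts with aggregated frequency 0
#' are capped at the maximum finite IC observed rather than infinity, so
#' downstream IC measures stay defined.
#'
#' @param f a `frequency_table` from [aggregate_frequencies()].
#' @return An `ic_table` with `kind = "corpus"`.
#' @export
corpus_ic <- function(f) {
  if (!inherits(f, "frequency_table")) stop("f must be a frequency_table")
  total <- f$aggregated[[f$root]]
  if (total <= 0) {
    stop("corpus IC is undefined: total raw frequency mass is 0; supply non-zero counts")
  }
  v <- -log(f$aggregated / total)
  finite_max <- max(v[is.finite(v)])
  v[!is.finite(v)] <- finite_max
  v[v < 0] <- 0
  structure(list(values = v, kind = "corpus", ic_max = max(v)),
            class = "ic_table")
}
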