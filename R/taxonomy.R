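#' Build a rooted taxonomy from a concept graph
#'
#' Uses only the taxonomic (child, parent) edges of `g`. Cycle-inducing
#' edges are removed deterministically (depth-first traversal over
#' child-to-parent edges, concepts and parent lists visited in
#' lexicographic order; an edge into a node still on the traversal stack
#' is dropped) and recorded in `removed_edges`. If more than one concept
#' ends up parentless, a synthetic root `VROOT` is added as parent of each.
#'
#' The builder precomputes, for every concept `c`:
#' \describe{
#'   \item{depth}{node count of the shortest parent path to the root
#'     (root has depth 1; with multiple parents the minimum is taken).}
#'   \item{n_leaves}{number of leaf (childless) concepts among `c` and its
#'     descendants; a leaf counts itself, so `n_leaves >= 1`.}
#'   \item{n_subsumers}{size of the subsumer set: `c` plus all ancestors
#'     reachable via any parent path.}
#' }
#' together with the taxonomy-wide maximum depth `d` and total leaf count
#' `max_leaves`.
#'
#' @param g a [concept_graph()].
#' @return An object of class `taxonomy` with fields `concepts`, `parents`,
#'   `children` (named lists of character vectors), `root`, `depth`, `d`,
#'   `n_leaves`, `n_subsumers`, `max_leaves`, `removed_edges`, and a
#'   private cache environment used to memoize ancestor traversals.
#' @export
build_taxonomy <- function(g) {
  if (!inherits(g, "concept_graph")) stop("g must be a concept_graph")
  if (length(g$concepts) == 0L) stop("cannot build a taxonomy from an empty concept graph")

  concepts <- sort(g$concepts)
  n <- length(concepts)
  id <- stats::setNames(seq_len(n), concepts)
  te <- g$taxonomic_edges

  parents_idx <- rep(list(integer()), n)
  if (nrow(te)) {
    ci <- id[te$child]; pi <- id[te$parent]
    ord <- order(ci, pi)
    sp <- split(pi[ord], ci[ord])
    parents_idx[as.integer(names(sp))] <- lapply(sp, function(v) sort(unique(v)))
  }

  rm_edges <- .remove_cycles(parents_idx, n)
  parents_idx <- rm_edges$parents
  removed <- data.frame(child = concepts[rm_edges$removed_child],
                        parent = concepts[rm_edges$removed_parent],
                        stringsAsFactors = FALSE)

  roots <- which(lengths(parents_idx) == 0L)
  if (length(roots) > 1L) {
    if ("VROOT" %in% concepts) {
      stop("concept id 'VROOT' collides with the synthetic root; rename it")
    }
    concepts <- c(concepts, "VROOT")
    n <- n + 1L
    parents_idx <- c(parents_idx, list(integer()))
    for (r in roots) parents_idx[[r]] <- n
    root_i <- n
    if (nrow(removed) && all(lengths(parents_idx[-n]) == 1L) &&
        all(vapply(parents_idx[-n], identical, TRUE, n))) {
      warning("cycle removal orphaned all taxonomic edges; all concepts placed under VROOT")
    }
  } else {
    root_i <- roots
  }

  children_idx <- rep(list(integer()), n)
  ev_child <- rep.int(seq_len(n), lengths(parents_idx))
  ev_parent <- unlist(parents_idx, use.names = FALSE)
  if (length(ev_parent)) {
    ord <- order(ev_parent, ev_child)
    sp <- split(ev_child[ord], ev_parent[ord])
    children_idx[as.integer(names(sp))] <- sp
  }

  # depth: BFS from root, following parent->child edges; node count so root = 1
  depth <- rep(NA_integer_, n)
  depth[root_i] <- 1L
  frontier <- root_i
  while (length(frontier)) {
    nxt <- unique(unlist(children_idx[frontier], use.names = FALSE))
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- depth[frontier[1L]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) stop("internal error: concepts unreachable from root")

  topo <- .topo_order(parents_idx, children_idx, root_i, n)

  # subsumer sets propagate root-down; leaf sets propagate leaf-up
  n_subsumers <- integer(n)
  subs <- vector("list", n)
  for (i in topo) {
    ps <- parents_idx[[i]]
    subs[[i]] <- if (length(ps)) {
      sort(unique(c(i, unlist(subs[ps], use.names = FALSE))))
    } else i
    n_subsumers[i] <- length(subs[[i]])
  }

  is_leaf <- lengths(children_idx) == 0L
  n_leaves <- integer(n)
  leafsets <- vector("list", n)
  for (i in rev(topo)) {
    leafsets[[i]] <- if (is_leaf[i]) i else {
      sort(unique(unlist(leafsets[children_idx[[i]]], use.names = FALSE)))
    }
    n_leaves[i] <- length(leafsets[[i]])
  }

  t <- structure(list(
    concepts = concepts,
    parents = stats::setNames(lapply(parents_idx, function(v) concepts[v]), concepts),
    children = stats::setNames(lapply(children_idx, function(v) concepts[v]), concepts),
    root = concepts[root_i],
    depth = stats::setNames(depth, concepts),
    d = max(depth),
    n_leaves = stats::setNames(n_leaves, concepts),
    n_subsumers = stats::setNames(n_subsumers, concepts),
    max_leaves = sum(is_leaf),
    removed_edges = removed,
    cache = new.env(parent = emptyenv())
  ), class = "taxonomy")
  stopifnot(identical(unname(t$n_leaves[t$root]), t$max_leaves))
  t
}

# Deterministic cycle removal on the directed child->parent graph.
# Iterative DFS; colors 0 = unvisited, 1 = on stack, 2 = done.
# An edge whose head is gray closes a cycle and is dropped.
.remove_cycles <- function(parents_idx, n) {
  color <- integer(n)
  rem_c <- integer(0)
  rem_p <- integer(0)
  drop <- vector("list", n)  # per-child indices into parents_idx to drop
  stack_node <- integer(0)
  stack_ptr <- integer(0)
  for (s in seq_len(n)) {
    if (color[s] != 0L) next
    stack_node <- s; stack_ptr <- 1L
    color[s] <- 1L
    while (length(stack_node)) {
      top <- length(stack_node)
      u <- stack_node[top]
      ps <- parents_idx[[u]]
      i <- stack_ptr[top]
      if (i > length(ps)) {
        color[u] <- 2L
        stack_node <- stack_node[-top]
        stack_ptr <- stack_ptr[-top]
        next
      }
      stack_ptr[top] <- i + 1L
      v <- ps[i]
      if (color[v] == 0L) {
        color[v] <- 1L
        stack_node <- c(stack_node, v)
        stack_ptr <- c(stack_ptr, 1L)
      } else if (color[v] == 1L) {
        drop[[u]] <- c(drop[[u]], i)
        rem_c <- c(rem_c, u)
        rem_p <- c(rem_p, v)
      } # black: forward/cross edge, no cycle
    }
  }
  for (u in which(lengths(drop) > 0L)) {
    parents_idx[[u]] <- parents_idx[[u]][-drop[[u]]]
  }
  list(parents = parents_idx, removed_child = rem_c, removed_parent = rem_p)
}

# Kahn's algorithm: ancestors before descendants. Also the acyclicity check.
.topo_order <- function(parents_idx, children_idx, root_i, n) {
  remaining <- lengths(parents_idx)
  queue <- which(remaining == 0L)
  out <- integer(0)
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    out <- c(out, u)
    for (v in children_idx[[u]]) {
      remaining[v] <- remaining[v] - 1L
      if (remaining[v] == 0L) queue <- c(queue, v)
    }
  }
  if (length(out) != n) stop("internal error: taxonomy contains a cycle after removal")
  out
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("taxonomy: %d concepts, root '%s', max depth %d, %d leaves, %d removed edge(s)\n",
              length(x$concepts), x$root, x$d, x$max_leaves, nrow(x$removed_edges)))
  invisible(x)
}

.check_concept <- function(t, c) {
  if (!c %in% t$concepts) stop(sprintf("missing concept: '%s' is not in the taxonomy", c))
}

.TAXONOMY_FORMAT <- "ontosim_taxonomy"
.TAXONOMY_VERSION <- 1L

#' Save / load a taxonomy artifact
#'
#' The artifact is a serialized binary file embedding a format identifier
#' and version tag; `load_taxonomy()` refuses files written by a future
#' format version and reports corrupted files as format errors. The
#' memoization cache is not serialized; a fresh one is attached on load.
#'
#' @param t a `taxonomy`.
#' @param path file path for the artifact.
#' @return `save_taxonomy()` returns `path` invisibly; `load_taxonomy()`
#'   returns the restored `taxonomy`.
#' @export
save_taxonomy <- function(t, path) {
  if (!inherits(t, "taxonomy")) stop("t must be a taxonomy")
  payload <- unclass(t)
  payload$cache <- NULL
  obj <- list(format = .TAXONOMY_FORMAT, version = .TAXONOMY_VERSION,
              payload = payload)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_taxonomy
#' @export
load_taxonomy <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("taxonomy format error: cannot read '%s' (%s)",
                 path, conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, .TAXONOMY_FORMAT)) {
    stop(sprintf("taxonomy format error: '%s' is not a taxonomy artifact", path))
  }
  if (obj$version > .TAXONOMY_VERSION) {
    stop(sprintf("taxonomy version error: artifact version %d is newer than supported version %d",
                 obj$version, .TAXONOMY_VERSION))
  }
  t <- obj$payload
  t$cache <- new.env(parent = emptyenv())
  class(t) <- "taxonomy"
  t
}
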