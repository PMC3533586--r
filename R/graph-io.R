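#' Construct a concept graph
#'
#' A concept graph is the raw parsed form of a semantic network: a set of
#' concept identifiers, a set of directed taxonomic (child, parent) edges,
#' and a set of undirected labelled non-taxonomic edges. It is the common
#' output of all readers and the input to [build_taxonomy()] and
#' [build_ppr_graph()].
#'
#' Self-edges are rejected with a warning; duplicate edges collapse to one
#' (non-taxonomic edges are deduplicated on the unordered pair plus label).
#' Edge endpoints absent from `concepts` are added to it.
#'
#' @param concepts character vector of concept identifiers.
#' @param taxonomic_edges data frame with columns `child`, `parent`.
#' @param other_edges data frame with columns `c1`, `c2`, `label`.
#' @param metadata named list of free-form source information.
#' @return An object of class `concept_graph`.
#' @export
concept_graph <- function(concepts = character(),
                          taxonomic_edges = NULL,
                          other_edges = NULL,
                          metadata = list()) {
  te <- .edge_frame(taxonomic_edges, c("child", "parent"))
  oe <- .edge_frame(other_edges, c("c1", "c2", "label"))

  self_tax <- te$child == te$parent
  if (any(self_tax)) {
    warning(sprintf("rejected %d self-edge(s): %s", sum(self_tax),
                    paste(unique(te$child[self_tax]), collapse = ", ")))
    te <- te[!self_tax, , drop = FALSE]
  }
  self_oth <- oe$c1 == oe$c2
  if (any(self_oth)) {
    warning(sprintf("rejected %d non-taxonomic self-edge(s)", sum(self_oth)))
    oe <- oe[!self_oth, , drop = FALSE]
  }

  te <- unique(te)
  # undirected semantics: normalize endpoint order before deduplication
  if (nrow(oe)) {
    a <- pmin(oe$c1, oe$c2)
    b <- pmax(oe$c1, oe$c2)
    oe <- unique(data.frame(c1 = a, c2 = b, label = oe$label,
                            stringsAsFactors = FALSE))
  }

  concepts <- sort(unique(c(as.character(concepts),
                            te$child, te$parent, oe$c1, oe$c2)))
  rownames(te) <- NULL
  rownames(oe) <- NULL
  structure(list(concepts = concepts,
                 taxonomic_edges = te,
                 other_edges = oe,
                 metadata = metadata),
            class = "concept_graph")
}

.edge_frame <- function(x, cols) {
  if (is.null(x)) {
    x <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                       cols))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(cols %in% names(x))) {
    stop("edge table must have columns: ", paste(cols, collapse = ", "))
  }
  x <- x[, cols, drop = FALSE]
  x[] <- lapply(x, as.character)
  x
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf("concept_graph: %d concepts, %d taxonomic edges, %d other edges\n",
              length(x$concepts), nrow(x$taxonomic_edges), nrow(x$other_edges)))
  invisible(x)
}

.read_lines <- function(x) {
  if (inherits(x, "connection")) readLines(x, warn = FALSE)
  else if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
  else as.character(x)
}

#' Read a concept graph from a tab-separated edge list
#'
#' Each non-comment line is `child<TAB>parent[<TAB>relation-label]`.
#' Lines without a label are taxonomic (is-a) edges; labelled lines become
#' undirected non-taxonomic edges. Lines starting with `#` and blank lines
#' are ignored. Duplicate lines collapse; a line whose child equals its
#' parent is reported and skipped.
#'
#' @param x file path, connection, or character vector of lines.
#' @return A [concept_graph()].
#' @export
read_edge_list <- function(x) {
  lines <- .read_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("edge list parse error at line %d: expected at least 2 tab-separated fields",
                 idx[which(nf < 2L)[1L]]))
  }
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  lab <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")
  tax <- is.na(lab) | lab == ""
  concept_graph(
    taxonomic_edges = data.frame(child = a[tax], parent = b[tax],
                                 stringsAsFactors = FALSE),
    other_edges = data.frame(c1 = a[!tax], c2 = b[!tax], label = lab[!tax],
                             stringsAsFactors = FALSE),
    metadata = list(source = "edge_list")
  )
}

#' Read a concept graph from an OBO 1.2 document
#'
#' `[Term]` stanzas become concepts; `is_a` tags become taxonomic edges and
#' `relationship:` tags become labelled non-taxonomic edges. Terms flagged
#' `is_obsolete: true` are skipped (with their edges); the count of skipped
#' terms is reported via [message()].
#'
#' @param x file path, connection, or character vector of lines.
#' @return A [concept_graph()].
#' @export
read_obo <- function(x) {
  lines <- .read_lines(x)
  # strip trailing OBO comments, then whitespace
  lines <- sub("\\s*!.*$", "", lines)
  lines <- trimws(lines)

  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) stop("OBO format error: no stanzas found")

  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- if (identical(ln, "[Term]")) {
        list(id = NULL, is_a = character(), rel = list(), obsolete = FALSE)
      } else NULL
      next
    }
    if (is.null(cur)) next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) < 3L) next
    tag <- m[2L]; val <- trimws(m[3L])
    if (tag == "id") cur$id <- val
    else if (tag == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (tag == "is_obsolete" && tolower(val) == "true") cur$obsolete <- TRUE
    else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L) {
        cur$rel[[length(cur$rel) + 1L]] <- c(parts[1L], parts[2L])
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("OBO format error: no [Term] stanzas with ids")

  obsolete <- vapply(terms, `[[`, TRUE, "obsolete")
  n_skipped <- sum(obsolete)
  if (n_skipped) message(sprintf("read_obo: skipped %d obsolete term(s)", n_skipped))
  live <- terms[!obsolete]
  live_ids <- vapply(live, `[[`, "", "id")
  ok_target <- function(id) !(id %in% vapply(terms[obsolete], `[[`, "", "id"))

  te <- do.call(rbind, lapply(live, function(t) {
    p <- Filter(ok_target, t$is_a)
    if (!length(p)) return(NULL)
    data.frame(child = t$id, parent = p, stringsAsFactors = FALSE)
  }))
  oe <- do.call(rbind, lapply(live, function(t) {
    if (!length(t$rel)) return(NULL)
    rel <- do.call(rbind, t$rel)
    keep <- ok_target(rel[, 2L])
    if (!any(keep)) return(NULL)
    data.frame(c1 = t$id, c2 = rel[keep, 2L], label = rel[keep, 1L],
               stringsAsFactors = FALSE)
  }))
  concept_graph(concepts = live_ids, taxonomic_edges = te, other_edges = oe,
                metadata = list(source = "obo", skipped_obsolete = n_skipped))
}

#' Read a concept graph from a pipe-delimited relationship table
#'
#' A minimal dialect of the RRF relationship format (e.g. UMLS MRREL):
#' rows are pipe-delimited, and a configuration names the columns holding
#' the two concept identifiers and the relation label, plus the set of
#' labels that count as hierarchical. Hierarchical rows become taxonomic
#' edges oriented per `child_col`; all rows also become labelled
#' non-taxonomic edges.
#'
#' @param x file path, connection, or character vector of lines.
#' @param config list with integer fields `col_c1`, `col_c2`, `col_rel`
#'   (1-based column indices), character `hierarchical` (labels treated as
#'   hierarchical), and `child_col` (`"c1"` or `"c2"`: which concept column
#'   holds the child on hierarchical rows; default `"c1"`).
#' @return A [concept_graph()].
#' @export
read_rrf_relations <- function(x, config) {
  req <- c("col_c1", "col_c2", "col_rel", "hierarchical")
  miss <- setdiff(req, names(config))
  if (length(miss)) {
    stop("rrf config error: missing field(s): ", paste(miss, collapse = ", "))
  }
  child_col <- if (is.null(config$child_col)) "c1" else config$child_col
  if (!child_col %in% c("c1", "c2")) stop("rrf config error: child_col must be 'c1' or 'c2'")

  lines <- .read_lines(x)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    warning("read_rrf_relations: empty input, returning empty graph")
    return(concept_graph(metadata = list(source = "rrf")))
  }
  fields <- strsplit(lines, "|", fixed = TRUE)
  need <- max(config$col_c1, config$col_c2, config$col_rel)
  if (any(lengths(fields) < need)) {
    stop(sprintf("rrf config error: configured column %d absent from row %d",
                 need, which(lengths(fields) < need)[1L]))
  }
  c1 <- vapply(fields, `[`, "", config$col_c1)
  c2 <- vapply(fields, `[`, "", config$col_c2)
  rel <- vapply(fields, `[`, "", config$col_rel)

  hier <- rel %in% config$hierarchical
  child <- if (child_col == "c1") c1 else c2
  parent <- if (child_col == "c1") c2 else c1
  concept_graph(
    taxonomic_edges = data.frame(child = child[hier], parent = parent[hier],
                                 stringsAsFactors = FALSE),
    other_edges = data.frame(c1 = c1, c2 = c2, label = rel,
                             stringsAsFactors = FALSE),
    metadata = list(source = "rrf")
  )
}

#' Read per-concept raw frequencies
#'
#' Format: `concept<TAB>count` per line, `#` comments allowed. Counts must
#' be non-negative numbers; duplicate concepts are summed.
#'
#' @param x file path, connection, or character vector of lines.
#' @return Named numeric vector of raw counts.
#' @export
read_frequencies <- function(x) {
  lines <- .read_lines(x)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad)) {
    stop(sprintf("frequency parse error at line %d: expected concept<TAB>count",
                 idx[which(bad)[1L]]))
  }
  ids <- vapply(fields, `[`, "", 1L)
  cnt <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(cnt)) {
    stop(sprintf("frequency parse error at line %d: non-numeric count",
                 idx[which(is.na(cnt))[1L]]))
  }
  if (any(cnt < 0)) stop("frequency validation error: negative count")
  tapply(cnt, ids, sum)[unique(ids)]
}
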