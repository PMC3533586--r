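test_that("T0 structural quantities match the hand-derived values", {
  expect_equal(T0$root, "R")
  expect_equal(T0$d, 3L)
  expect_equal(T0$max_leaves, 3L)
  expect_equal(unname(T0$depth[c("R", "A", "B", "C", "D")]), c(1L, 2L, 2L, 3L, 3L))
  expect_equal(unname(T0$n_leaves[c("R", "A", "C")]), c(3L, 2L, 1L))
  expect_equal(unname(T0$n_subsumers[c("R", "A", "C")]), c(1L, 2L, 3L))
  expect_equal(nrow(T0$removed_edges), 0L)
  # leaves are exactly {B, C, D}: childless concepts
  expect_setequal(names(which(lengths(T0$children) == 0L)), c("B", "C", "D"))
})

test_that("cycle removal is deterministic and acyclic", {
  g <- concept_graph(taxonomic_edges = data.frame(
    child = c("A", "B"), parent = c("B", "A")))
  t1 <- build_taxonomy(g)
  expect_equal(nrow(t1$removed_edges), 1L)
  t2 <- build_taxonomy(g)
  expect_identical(t1$removed_edges, t2$removed_edges)

  # a larger cycle embedded in a normal hierarchy
  g2 <- read_edge_list(c("B\tA", "C\tB", "A\tC", "D\tA"))
  t3 <- build_taxonomy(g2)
  expect_gte(nrow(t3$removed_edges), 1L)
  # acyclicity: depth defined everywhere and every concept reaches root
  expect_false(anyNA(t3$depth))
  for (c in t3$concepts) {
    anc <- ancestors_with_distance(t3, c)
    expect_true(t3$root %in% names(anc))
  }
})

test_that("multiple parentless concepts get a synthetic VROOT at depth 1", {
  g <- read_edge_list(c("a1\ta0", "b1\tb0"))  # two disjoint chains
  t <- build_taxonomy(g)
  expect_equal(t$root, "VROOT")
  expect_equal(unname(t$depth["VROOT"]), 1L)
  expect_equal(unname(t$depth[c("a0", "b0")]), c(2L, 2L))
  # single-rooted input is left unchanged
  expect_false("VROOT" %in% T0$concepts)
})

test_that("depth and n_leaves agree with brute force on random DAGs", {
  for (s in 1:25) {
    n <- 5L + (s * 7L) %% 36L
    t <- build_taxonomy(random_dag(n, max_parents = 3L, seed = s))
    U <- oracle_up_distances(t)
    # depth = min node-count path to root = up-distance to root + 1
    expect_equal(unname(t$depth), unname(U[, t$root]) + 1,
                 info = sprintf("seed %d", s))
    # n_leaves = count of childless concepts at finite down-distance
    leaves <- t$concepts[lengths(t$children) == 0L]
    for (c in t$concepts) {
      brute <- sum(is.finite(U[leaves, c]))
      expect_equal(unname(t$n_leaves[c]), brute, info = sprintf("seed %d %s", s, c))
    }
    # n_subsumers = finite up-distances
    expect_equal(unname(t$n_subsumers), unname(rowSums(is.finite(U))))
  }
})

test_that("taxonomy invariant bounds hold on random DAGs", {
  for (t in random_taxonomies(1:10)) {
    expect_equal(t$d, max(t$depth))
    expect_equal(unname(t$n_leaves[t$root]), t$max_leaves)
    expect_true(all(t$n_subsumers >= 1L & t$n_subsumers <= length(t$concepts)))
    expect_true(all(t$n_leaves >= 1L & t$n_leaves <= t$max_leaves))
    expect_equal(unname(t$depth[t$root]), 1L)
  }
})

test_that("empty and degenerate inputs are rejected or handled", {
  expect_error(build_taxonomy(concept_graph()), "empty")
  t <- build_taxonomy(concept_graph(concepts = "only"))
  expect_equal(t$root, "only")
  expect_equal(t$max_leaves, 1L)
})

test_that("taxonomy artifacts round-trip and reject bad files", {
  path <- tempfile(fileext = ".tax")
  save_taxonomy(T0, path)
  t2 <- load_taxonomy(path)
  for (f in setdiff(names(T0), "cache")) {
    expect_identical(t2[[f]], T0[[f]], info = f)
  }
  # corrupted file -> format error, not silent garbage
  writeLines("not an artifact", path)
  expect_error(load_taxonomy(path), "format error")
  # future version tag -> version error
  saveRDS(list(format = "ontosim_taxonomy", version = 99L, payload = list()), path)
  expect_error(load_taxonomy(path), "version error")
  # wrong RDS payload -> format error
  saveRDS(1:3, path)
  expect_error(load_taxonomy(path), "format error")
  unlink(path)
})
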