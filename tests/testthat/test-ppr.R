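test_that("PPR graph modes and deduplication behave as documented", {
  g <- toy_T0()
  pg <- build_ppr_graph(g, "taxonomy")
  expect_equal(pg$n, 5L)
  expect_equal(sum(pg$degree) / 2, 4)  # T0's 4 taxonomic edges, undirected

  # is_a + part_of between the same pair collapse to one undirected edge
  g2 <- concept_graph(
    taxonomic_edges = data.frame(child = "A", parent = "B"),
    other_edges = data.frame(c1 = "A", c2 = "B", label = "part_of"))
  expect_equal(sum(build_ppr_graph(g2, "all")$degree) / 2, 1)

  # mode=all adds exactly the distinct non-taxonomic pairs
  g3 <- concept_graph(
    taxonomic_edges = data.frame(child = c("C", "D"), parent = c("A", "A")),
    other_edges = data.frame(c1 = c("C", "C"), c2 = c("D", "D"),
                             label = c("ro", "rq")))
  tax_e <- sum(build_ppr_graph(g3, "taxonomy")$degree) / 2
  all_e <- sum(build_ppr_graph(g3, "all")$degree) / 2
  expect_equal(all_e - tax_e, 1)
})

test_that("2-vertex PPR matches the closed-form solution at damping 0.85", {
  pg <- build_ppr_graph(read_edge_list("x\ty"), "taxonomy")
  v <- suppressWarnings(ppr_vector(pg, "x"))
  expect_equal(formals(ppr_vector)$damping, 0.85)  # paper default is the default
  px <- 0.15 / (1 - 0.85^2)
  expect_equal(unname(v$scores["x"]), px, tolerance = 1e-6)
  expect_equal(unname(v$scores["y"]), 1 - px, tolerance = 1e-6)
  w <- suppressWarnings(ppr_vector(pg, "y"))
  expect_equal(ppr_relatedness(v, w), 0.9869, tolerance = 1e-4)
  expect_equal(ppr_relatedness(v, v), 1)
})

test_that("PPR vectors are probability distributions; dangling mass returns to seed", {
  g <- concept_graph(concepts = c("iso", "x", "y"),
                     taxonomic_edges = data.frame(child = "x", parent = "y"))
  pg <- build_ppr_graph(g, "taxonomy")
  v <- suppressWarnings(ppr_vector(pg, "iso"))
  expect_equal(unname(v$scores["iso"]), 1)  # isolated seed keeps all mass
  expect_equal(sum(v$scores), 1, tolerance = 1e-8)

  for (s in 1:5) {
    pg2 <- build_ppr_graph(random_dag(30L, p_extra_edge = 0.3, seed = s), "all")
    v2 <- suppressWarnings(ppr_vector(pg2, pg2$concepts[s]))
    expect_equal(sum(v2$scores), 1, tolerance = 1e-8)
    expect_true(all(v2$scores >= 0))
    expect_gt(v2$scores[[pg2$concepts[s]]], 0)
  }
})

test_that("power iteration agrees with the dense linear-solve oracle", {
  for (s in 1:6) {
    n <- 20L + 10L * s
    pg <- build_ppr_graph(random_dag(n, max_parents = 3L,
                                     p_extra_edge = 0.2, seed = s),
                          mode = if (s %% 2) "all" else "taxonomy")
    seed_concept <- pg$concepts[(s * 3L) %% n + 1L]
    v <- suppressWarnings(ppr_vector(pg, seed_concept))
    o <- oracle_ppr_dense(pg, seed_concept)
    expect_lt(max(abs(v$scores - o)), 1e-6)
  }
})

test_that("relatedness is a symmetric cosine with the documented edge cases", {
  pg <- build_ppr_graph(random_dag(15L, seed = 3L), "taxonomy")
  a <- suppressWarnings(ppr_vector(pg, "N003"))
  b <- suppressWarnings(ppr_vector(pg, "N011"))
  expect_equal(ppr_relatedness(a, b), ppr_relatedness(b, a))
  expect_gte(ppr_relatedness(a, b), 0)
  expect_lte(ppr_relatedness(a, b), 1)

  # disjoint support -> 0 (two isolated seeds in the same graph)
  g <- concept_graph(concepts = c("i1", "i2", "x", "y"),
                     taxonomic_edges = data.frame(child = "x", parent = "y"))
  pg2 <- build_ppr_graph(g, "taxonomy")
  expect_equal(ppr_relatedness(suppressWarnings(ppr_vector(pg2, "i1")),
                               suppressWarnings(ppr_vector(pg2, "i2"))), 0)

  # graph mismatch is an error
  expect_error(ppr_relatedness(a, suppressWarnings(ppr_vector(pg2, "i1"))),
               "mismatch")
  expect_error(ppr_vector(pg, "nope"), "missing concept")
  expect_error(ppr_vector(pg, "N001", damping = 1), "damping")
})
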