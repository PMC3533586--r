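test_that("all seven measures reproduce the T0 hand evaluations", {
  expect_equal(sim_path(T0, "C", "C"), 1)
  expect_equal(sim_path(T0, "C", "D"), 1 / 3, tolerance = 1e-12)
  expect_equal(sim_path(T0, "C", "B"), 0.25)

  expect_equal(sim_lch(T0, "C", "C"), 1)
  expect_equal(sim_lch(T0, "C", "D"), 1 - log(3) / log(6), tolerance = 1e-12)
  expect_equal(round(sim_lch(T0, "C", "D"), 4), 0.3869)

  expect_equal(sim_wupalmer(T0, "C", "C"), 1)
  expect_equal(sim_wupalmer(T0, "C", "D"), 4 / 6, tolerance = 1e-12)
  expect_equal(sim_wupalmer(T0, "C", "B"), 0.4)

  expect_equal(sim_lin(T0, T0_IC, "C", "C"), 1)
  expect_equal(sim_lin(T0, T0_IC, "C", "D"), 0.6309, tolerance = 1e-4)
  expect_equal(sim_lin(T0, T0_IC, "C", "B"), 0)  # lcs = R has IC 0

  expect_equal(dist_jc(T0, T0_IC, "C", "C"), 0)
  expect_equal(dist_jc(T0, T0_IC, "C", "D"), 0.8109, tolerance = 1e-4)
  expect_equal(dist_jc(T0, T0_IC, "C", "B"), 2.0794, tolerance = 1e-4)

  expect_equal(sim_lch_ic(T0, T0_IC, "C", "C"), 1)
  expect_equal(sim_lch_ic(T0, T0_IC, "C", "D"), 0.489, tolerance = 1e-3)

  expect_equal(sim_path_ic(T0, T0_IC, "C", "C"), 1)
  expect_equal(sim_path_ic(T0, T0_IC, "C", "D"), 0.5522, tolerance = 1e-4)
  # exact: 1/(1 + IC(C) + IC(B)) = 1/3.0794415 = 0.3247341
  expect_equal(sim_path_ic(T0, T0_IC, "C", "B"),
               1 / (1 + log(3) - log(0.375)), tolerance = 1e-12)

  expect_error(sim_lin(T0, T0_IC, "C", "nope"), "missing concept")
})

test_that("bounds, self-similarity and symmetry hold across random DAGs and IC kinds", {
  sims <- list(
    path = function(t, ic, a, b) sim_path(t, a, b),
    lch = function(t, ic, a, b) sim_lch(t, a, b),
    wupalmer = function(t, ic, a, b) sim_wupalmer(t, a, b),
    lin = sim_lin, lch_ic = sim_lch_ic, path_ic = sim_path_ic
  )
  for (s in 1:8) {
    t <- build_taxonomy(random_dag(20L, max_parents = 3L, seed = s))
    raw <- stats::setNames((seq_along(t$concepts) * 13L) %% 17L, t$concepts)
    ics <- list(intrinsic_ic(t),
                corpus_ic(aggregate_frequencies(t, raw + 1)))
    cs <- t$concepts
    for (ic in ics) {
      for (nm in names(sims)) {
        f <- sims[[nm]]
        for (i in seq(1, length(cs), by = 4)) {
          a <- cs[i]; b <- cs[length(cs) + 1L - i]
          v <- f(t, ic, a, b)
          expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
          expect_equal(v, f(t, ic, b, a), info = paste(nm, s))
          expect_equal(f(t, ic, a, a), 1, info = paste(nm, s))
        }
      }
      # distance: non-negative, zero on the diagonal
      for (i in seq(1, length(cs), by = 4)) {
        a <- cs[i]; b <- cs[length(cs) + 1L - i]
        expect_gte(dist_jc(t, ic, a, b), 0)
        expect_equal(dist_jc(t, ic, a, a), 0)
      }
    }
  }
})

test_that("self-similarity is 1 even at the root (Lin 0/0 convention)", {
  expect_equal(sim_lin(T0, T0_IC, "R", "R"), 1)
  expect_equal(sim_lch_ic(T0, T0_IC, "R", "R"), 1)
  expect_equal(sim_path_ic(T0, T0_IC, "R", "R"), 1)
})

test_that("path-family and IC-family twins are monotone in their shared quantity", {
  t <- build_taxonomy(random_dag(30L, max_parents = 2L, seed = 42L))
  ic <- intrinsic_ic(t)
  pairs <- all_ordered_pairs(t)
  pairs <- pairs[seq(1, nrow(pairs), by = 7L), ]
  sc <- concept_similarity(t, pairs,
                           measures = c("path", "lch", "jc", "lch_ic", "path_ic"),
                           ic = ic)
  # identical rank orderings within each monotone family
  expect_equal(oracle_spearman(sc$path, sc$lch), 1, tolerance = 1e-12)
  # IC twins: analytically tied distances can differ at ~1 ulp and the log
  # transform may collapse some of them, perturbing ranks at fp level
  expect_equal(oracle_spearman(sc$path_ic, sc$lch_ic), 1, tolerance = 1e-5)
  expect_equal(oracle_spearman(-sc$jc, sc$path_ic), 1, tolerance = 1e-12)
})

test_that("scaling LCH by the constant log(2d) leaves Spearman unchanged", {
  t <- build_taxonomy(random_dag(25L, max_parents = 3L, seed = 7L))
  pairs <- all_ordered_pairs(t)[seq(1, 625, by = 5L), ]
  p <- vapply(seq_len(nrow(pairs)),
              function(i) shortest_path(t, pairs[i, 1L], pairs[i, 2L])$p,
              integer(1))
  scaled <- 1 - log(p) / log(2 * t$d)
  unscaled <- log(2 * t$d) - log(p)
  ratings <- rev(seq_len(length(p))) + rep(c(0.5, -0.5), length.out = length(p))
  expect_equal(spearman_rho(scaled, ratings), spearman_rho(unscaled, ratings),
               tolerance = 1e-12)
})

test_that("concept_similarity validates its configuration", {
  pairs <- data.frame(concept1 = "C", concept2 = "D")
  expect_error(concept_similarity(T0, pairs, measures = "bogus"), "unknown measure")
  expect_error(concept_similarity(T0, pairs, measures = "lin"), "require an ic_table")
  expect_error(concept_similarity(T0, pairs, measures = "ppr"), "ppr_graph")
  out <- concept_similarity(T0, pairs, measures = c("path", "lin"), ic = T0_IC)
  expect_equal(out$path, 1 / 3, tolerance = 1e-12)
  expect_equal(out$lin, 0.6309, tolerance = 1e-4)
})
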