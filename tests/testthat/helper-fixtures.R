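# shared fixtures: the toy taxonomy and a pool of random DAG taxonomies
T0 <- build_taxonomy(toy_T0())
T0_IC <- intrinsic_ic(T0)

# a small deterministic battery of random taxonomies for property tests
random_taxonomies <- function(seeds, n_concepts = 30L, max_parents = 3L,
                              p_extra_edge = 0) {
  lapply(seeds, function(s) {
    build_taxonomy(random_dag(n_concepts, max_parents, p_extra_edge, seed = s))
  })
}

all_ordered_pairs <- function(t) {
  expand.grid(concept1 = t$concepts, concept2 = t$concepts,
              stringsAsFactors = FALSE)
}

expect_no_warning_ppr <- function(expr) suppressWarnings(expr)
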