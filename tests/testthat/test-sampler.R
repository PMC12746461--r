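test_that("initial graphs satisfy all protomolecule invariants", {
  set.seed(21)
  for (i in 1:200) {
    d <- random_degree_seq(max_atoms = 10L, max_val = 5L)
    g <- initial_graph(d)
    expect_silent(rrspace:::validate_protomolecule(g))
  }
  # single realization cases
  expect_equal(nrow(initial_graph(degree_seq(1, 2))$edges), 1L)
  star <- initial_graph(degree_seq(c(4, 1), c(1, 4)))
  expect_equal(sum(star$edges[star$edges[, 1L] == 1L |
                              star$edges[, 2L] == 1L, 3L]), 4L)
  expect_error(initial_graph(degree_seq(c(4, 1), c(1, 2))), "realizable")
})

test_that("mcmc steps preserve degrees and reject illegal moves", {
  set.seed(31)
  d <- degree_seq(c(4, 1, 1), c(2, 3, 3))
  g <- initial_graph(d)
  for (k in 1:50) {
    g2 <- mcmc_step(g)
    expect_equal(rrspace:::edge_degrees(g2$edges, length(g2$degree)),
                 g$degree)
    # accepted moves change at least two bonded-pair entries
    if (!identical(g2$edges, g$edges)) {
      A1 <- adjacency_multiplicity(g); A2 <- adjacency_multiplicity(g2)
      expect_gte(sum(A1 != A2) / 2, 2)
    }
    g <- g2
  }
  # size-one universe: the state never changes
  g1 <- initial_graph(degree_seq(c(4, 1), c(1, 4)))
  for (k in 1:10) expect_identical(mcmc_step(g1)$edges, g1$edges)
})

test_that("seeded sampling is reproducible", {
  d <- degree_seq(c(4, 1), c(3, 8))
  a <- sample_graphs(d, 10L, sampler_config(seed = 77L))
  b <- sample_graphs(d, 10L, sampler_config(seed = 77L))
  expect_identical(lapply(a, function(m) m$protomolecule$edges),
                   lapply(b, function(m) m$protomolecule$edges))
  # samples from a size-one universe are all identical
  ones <- sample_graphs(degree_seq(1, 2), 5L, sampler_config(seed = 1L))
  expect_length(unique(proto_keys(lapply(ones, `[[`, "protomolecule"))), 1L)
})

test_that("the corrected chain visits isomorphism classes uniformly", {
  # C4H10: two classes; long-run frequencies within 3 sigma of 1/2
  d <- degree_seq(c(4, 1), c(4, 10))
  uni <- enumerate_protomolecules(d, cap = 14L)
  keys <- proto_keys(uni)
  gs <- sample_graphs(d, 400L, sampler_config(seed = 13L))
  got <- table(factor(proto_keys(lapply(gs, `[[`, "protomolecule")),
                      levels = keys))
  p <- 0.5
  expect_lt(abs(got[1L] - 400 * p), 3 * sqrt(400 * p * (1 - p)))

  # without correction the labeled-graph law applies: classes weighted by
  # 1/|Aut|; check the direction of the bias on the same universe
  auts <- vapply(uni, proto_automorphisms, numeric(1))
  p_lab <- (1 / auts) / sum(1 / auts)
  gs2 <- sample_graphs(d, 400L,
                       sampler_config(seed = 14L, aut_correction = FALSE))
  got2 <- table(factor(proto_keys(lapply(gs2, `[[`, "protomolecule")),
                       levels = keys))
  expect_lt(abs(got2[1L] - 400 * p_lab[1L]),
            3 * sqrt(400 * p_lab[1L] * (1 - p_lab[1L])))
})

test_that("space sampling follows class-count weights", {
  sp <- chemical_space(c("C", "H"), c(4, 1), c(2, 5))
  cons <- space_constitutions(sp)
  keys <- vapply(cons, formula_string, character(1))
  counts <- stats::setNames(rep(1, length(keys)), keys)
  counts[1L] <- 3  # weight one formula 3x
  set.seed(91)
  smp <- sample_space(sp, 300L, counts = counts,
                      config = sampler_config(seed = 91L))
  got <- table(factor(vapply(smp, function(m) formula_string(m$stoichiometry),
                             character(1)), levels = keys))
  p1 <- 3 / sum(counts)
  expect_lt(abs(got[1L] - 300 * p1), 3 * sqrt(300 * p1 * (1 - p1)))

  # single-formula restriction: all samples share it
  smp2 <- sample_space(sp, 8L, counts = counts,
                       config = sampler_config(seed = 2L),
                       formulas = keys[1L])
  expect_true(all(vapply(smp2, function(m)
    formula_string(m$stoichiometry), character(1)) == keys[1L]))
})

test_that("element assignment is uniform over interchangeable slots", {
  s <- stoichiometry(c("C", "H", "F"), c(4, 1, 1), c(1, 2, 2))
  d <- degree_sequence_of(s)
  g <- enumerate_protomolecules(d, cap = 6L)[[1L]]
  set.seed(8)
  firsts <- replicate(400, {
    ms <- assign_elements(g, s)
    # which element landed on the first monovalent vertex
    ms$protomolecule$elements[which(ms$protomolecule$degree == 1L)[1L]]
  })
  tab <- table(firsts)
  expect_setequal(names(tab), c("F", "H"))
  expect_lt(abs(tab[["H"]] - 200), 3 * sqrt(400 * 0.25))

  # incompatible stoichiometry errors
  s2 <- stoichiometry(c("C", "H"), c(4, 1), c(1, 4))
  expect_error(assign_elements(g, s2), "incompatible")
  # pure stoichiometry: deterministic
  g2 <- enumerate_protomolecules(degree_sequence_of(s2))[[1L]]
  ms <- assign_elements(g2, s2)
  expect_equal(sort(unique(ms$protomolecule$elements)), c("C", "H"))
})
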