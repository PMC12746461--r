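test_that("canonical keys are isomorphism invariants", {
  # random vertex permutation within type classes leaves the key unchanged
  set.seed(11)
  for (i in 1:10) {
    d <- random_degree_seq(max_atoms = 7L)
    uni <- enumerate_protomolecules(d, cap = 10L)
    if (length(uni) == 0L) next
    g <- uni[[sample.int(length(uni), 1L)]]
    at <- ds_atoms(d)
    perm <- seq_along(at$degree)
    for (tt in unique(at$type)) {
      ix <- which(at$type == tt)
      if (length(ix) > 1L) perm[ix] <- ix[sample.int(length(ix))]
    }
    e2 <- g$edges
    e2[, 1L] <- perm[g$edges[, 1L]]; e2[, 2L] <- perm[g$edges[, 2L]]
    g2 <- protomolecule(d, e2)
    expect_identical(proto_key(g), proto_key(g2))
  }

  # butane vs isobutane skeletons (with hydrogens) are distinct
  d <- degree_seq(c(4, 1), c(4, 10))
  uni <- enumerate_protomolecules(d, cap = 14L)
  expect_length(uni, 2L)
  expect_length(unique(proto_keys(uni)), 2L)

  # single vs double bond between divalent atoms differ:
  # O3 ring/chain universe contains multiplicity variation
  d2 <- degree_seq(2, 2)
  uni2 <- enumerate_protomolecules(d2)  # double-bonded pair only
  expect_length(uni2, 1L)
  expect_equal(as.integer(uni2[[1L]]$edges[1L, 3L]), 2L)
})

test_that("enumeration reproduces the worked monovalent examples", {
  # one element, two monovalent atoms: a single protomolecule
  expect_equal(count_exact(degree_seq(1, 2)), 1L)
  # two elements: X2, XY, Y2 - three protomolecules across constitutions
  sp <- chemical_space(c("X", "Y"), c(1, 1), c(2, 2))
  cons <- space_constitutions(sp)
  total <- sum(vapply(cons, function(s)
    count_exact(degree_sequence_of(s)), integer(1)))
  expect_equal(total, 3L)
})

test_that("enumeration matches known alkane isomer counts", {
  expect_equal(count_exact(degree_seq(c(4, 1), c(4, 10)), cap = 14L), 2L)
  expect_equal(count_exact(degree_seq(c(4, 1), c(5, 12)), cap = 17L), 3L)
  expect_equal(count_exact(degree_seq(2, 3)), 1L)    # triangle
  expect_equal(count_exact(degree_seq(c(4, 1), c(1, 4))), 1L)  # star
  # unrealizable: count 0
  expect_equal(count_exact(degree_seq(c(4, 1), c(1, 2))), 0L)
})

test_that("enumeration refuses above the cap and output is valid", {
  d <- degree_seq(c(4, 1), c(4, 10))
  expect_error(enumerate_protomolecules(d), "cap")
  for (g in enumerate_protomolecules(degree_seq(c(4, 1, 1), c(2, 3, 3)),
                                     cap = 8L)) {
    expect_silent(rrspace:::validate_protomolecule(g))
  }
})

test_that("counts are invariant under renaming equal-valence elements", {
  a <- degree_sequence_of(stoichiometry(c("C", "H", "F"), c(4, 1, 1),
                                        c(2, 4, 2)))
  b <- degree_sequence_of(stoichiometry(c("C", "Br", "Cl"), c(4, 1, 1),
                                        c(2, 4, 2)))
  expect_equal(count_exact(a, cap = 8L), count_exact(b, cap = 8L))
})

test_that("universes are closed under double edge swaps", {
  fx <- small_fixtures()
  for (nm in c("hydrocarbon", "halomethane")) {
    for (key in names(fx[[nm]]$universes)) {
      uni <- fx[[nm]]$universes[[key]]
      if (length(uni) == 0L) next
      # swap_reachability errors if any swap leaves the enumerated set
      expect_true(as.logical(swap_reachability(uni)), info = paste(nm, key))
    }
  }
})
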