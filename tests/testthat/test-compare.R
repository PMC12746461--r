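test_that("stoichiometry is derived from realized valences", {
  # methane built directly as an element-labeled graph
  edges <- cbind(1L, 2:5, 1L)
  m <- rrspace:::molecule_from_atoms(c("C", "H", "H", "H", "H"),
                                     c(4, 1, 1, 1, 1), edges)
  expect_equal(formula_string(stoichiometry_of(m)), "C1H4")
  # carbon dioxide: two double bonds, realized valences C4, O2
  co2 <- rrspace:::molecule_from_atoms(c("O", "C", "O"), c(2, 4, 2),
                                       rbind(c(1L, 2L, 2L), c(2L, 3L, 2L)))
  expect_equal(formula_string(stoichiometry_of(co2)), "C1O2")
})

test_that("paired CDFs share a size-sorted support with zero fill", {
  space_counts <- c(A1 = 10, B1 = 30, C1 = 60)
  # identical distributions
  cd <- build_cdfs(space_counts, space_counts)
  expect_equal(cd$space_cdf, cd$db_cdf)
  expect_equal(ks_statistic(cd), 0)
  expect_equal(sum(cd$space_p), 1, tolerance = 1e-12)
  # db covering only the largest stoichiometry: late step function
  cd2 <- build_cdfs(c(C1 = 5), space_counts)
  expect_equal(cd2$db_cdf, c(0, 0, 1))
  expect_equal(ks_statistic(cd2), max(abs(cd2$space_cdf - cd2$db_cdf)))
  # ties in size break by canonical key, deterministically
  sc <- c(B1 = 10, A1 = 10, C1 = 20)
  expect_equal(build_cdfs(sc, sc)$key, c("A1", "B1", "C1"))
  expect_error(build_cdfs(c(Z9 = 1), space_counts), "outside")
})

test_that("KS matches hand-computed toy values and bounds", {
  expect_equal(ks_statistic(c(0.5, 1), c(1, 1)), 0.5)
  # disjoint supports within the union give KS = 1
  sc <- c(A1 = 1, B1 = 1)
  expect_equal(ks_statistic(build_cdfs(c(A1 = 7), sc)), 0.5)
  d1 <- c(1, 1, 1, 1); d2 <- c(0, 0, 0, 1)
  expect_equal(ks_statistic(cumsum(d1 / sum(d1)), cumsum(d2 / sum(d2))), 0.75)
  set.seed(4)
  for (i in 1:20) {
    p <- stats::runif(5); p <- p / sum(p)
    q <- stats::runif(5); q <- q / sum(q)
    ks <- ks_statistic(cumsum(p), cumsum(q))
    expect_gte(ks, 0); expect_lte(ks, 1)
  }
})

test_that("KL divergence matches closed forms and flags the eps floor", {
  expect_equal(as.numeric(kl_divergence(c(0.5, 0.5), c(0.5, 0.5))), 0)
  v <- kl_divergence(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(as.numeric(v), 0.5 * log(2 / 3) + 0.5 * log(2))
  expect_false(attr(v, "eps_triggered"))
  w <- kl_divergence(c(0.5, 0.5), c(1, 0), eps = 1e-6)
  expect_true(attr(w, "eps_triggered"))
  expect_true(is.finite(as.numeric(w)))
  # Gibbs inequality on random distributions
  set.seed(12)
  for (i in 1:20) {
    p <- stats::runif(6); p <- p / sum(p)
    q <- stats::runif(6); q <- q / sum(q)
    expect_gte(as.numeric(kl_divergence(p, q)), 0)
  }
})

test_that("comparison metrics are invariant to database scale", {
  space_counts <- c(A1 = 4, B1 = 16, C1 = 30)
  db <- c(A1 = 2, B1 = 10)
  r1 <- compare_database(db, space_counts)
  r2 <- compare_database(10 * db, space_counts)
  expect_equal(r1$ks, r2$ks)
  expect_equal(r1$kl, r2$kl)
})

test_that("subsample curves are seeded and shrink toward full coverage", {
  set.seed(2)
  space_counts <- c(A1 = 5, B1 = 10, C1 = 25, D1 = 60)
  p <- space_counts / sum(space_counts)
  db_keys <- sample(names(p), 4000L, replace = TRUE, prob = p)
  cur1 <- subsample_curve(db_keys, space_counts,
                          fractions = c(0.02, 0.2, 1), reps = 4L, seed = 9L)
  cur2 <- subsample_curve(db_keys, space_counts,
                          fractions = c(0.02, 0.2, 1), reps = 4L, seed = 9L)
  expect_identical(cur1, cur2)
  # KS non-increasing in fraction within noise
  expect_lte(cur1$mean_ks[3L], cur1$mean_ks[1L] + 0.05)
  # a faithful large sample of the space itself scores near zero
  expect_lt(cur1$mean_ks[3L], 0.05)
})
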