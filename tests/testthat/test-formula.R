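test_that("integer compositions are exhaustive, unique, deterministic", {
  m <- integer_compositions(2, 2)
  expect_equal(nrow(m), 3L)
  expect_true(all(rowSums(m) == 2))
  expect_equal(integer_compositions(0, 3), matrix(c(0L, 0L, 0L), 1L))
  expect_equal(nrow(integer_compositions(4, 2)), 5L)
  expect_equal(nrow(integer_compositions(5, 3)), choose(5 + 2, 2))
  expect_false(any(duplicated(apply(integer_compositions(4, 3), 1L, paste,
                                    collapse = ","))))
  expect_identical(integer_compositions(3, 2), integer_compositions(3, 2))
  expect_error(integer_compositions(2, 0), "0 parts")
})

test_that("realizability matches the brute-force multigraph oracle", {
  expect_true(is_realizable(c(1, 1)))
  expect_false(is_realizable(c(4, 1, 1)))
  expect_false(is_realizable(c(3, 1, 1)))
  expect_true(is_realizable(c(2, 2, 2)))
  expect_false(is_realizable(c(1, 1, 1, 1)))  # cannot connect two bonds
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:4, 1L)
    degs <- sample(1:4, n, replace = TRUE)
    expect_identical(is_realizable(degs), oracle_realizable(degs),
                     info = paste(degs, collapse = ","))
  }
})

test_that("valence compositions apply parity and saturation", {
  sp <- chemical_space(c("C", "H"), c(4, 1), c(2, 10))
  q5 <- valence_compositions(sp, 5)   # columns: valence 4, valence 1
  got <- apply(q5, 1L, paste, collapse = ",")
  expect_setequal(got, c("1,4", "3,2", "5,0"))

  spH <- chemical_space(c("H", "X"), c(1, 1), c(2, 10))
  expect_equal(nrow(valence_compositions(spH, 3)), 0L)  # odd degree sum
  expect_equal(nrow(valence_compositions(spH, 2)), 1L)
})

test_that("constitutions match the one-stage brute-force oracle", {
  sp <- chemical_space(c("C", "H", "F"), c(4, 1, 1), c(2, 8))
  cons5 <- constitutions(sp, 5)
  keys5 <- vapply(cons5, formula_string, character(1))
  # the CX4 family: 5 constitutions from distributing 4 monovalents
  expect_length(grep("^C1", keys5), 5L)
  for (n in 2:8) {
    got <- sort(vapply(constitutions(sp, n), formula_string, character(1)))
    expect_identical(got, oracle_constitutions(sp, n), info = paste("n =", n))
  }
  spB <- chemical_space(c("F", "H", "Cl", "O", "N", "P", "C"),
                        c(1, 1, 1, 2, 3, 3, 4), c(2, 6))
  for (n in c(3, 4)) {
    got <- sort(vapply(constitutions(spB, n), formula_string, character(1)))
    expect_identical(got, oracle_constitutions(spB, n))
  }
})

test_that("every constitution is realizable with even degree sum", {
  fx <- small_fixtures()
  for (nm in names(fx)) {
    for (s in fx[[nm]]$constitutions) {
      degs <- ds_atoms(degree_sequence_of(s))$degree
      expect_equal(sum(degs) %% 2L, 0L)
      expect_true(is_realizable(degs))
    }
  }
})

test_that("adding an element of an existing valence grows the formula set", {
  sp1 <- chemical_space(c("C", "H"), c(4, 1), c(2, 6))
  sp2 <- chemical_space(c("C", "H", "F"), c(4, 1, 1), c(2, 6))
  for (n in 2:6) {
    k1 <- vapply(constitutions(sp1, n), formula_string, character(1))
    k2 <- vapply(constitutions(sp2, n), formula_string, character(1))
    expect_true(all(k1 %in% k2))
    expect_gte(length(k2), length(k1))
  }
})

test_that("formula tables export the expected columns", {
  sp <- chemical_space(c("C", "H"), c(4, 1), c(2, 5))
  tf <- tempfile(fileext = ".csv")
  df <- formula_table(sp)
  expect_named(df, c("formula", "ds_key", "natoms"))
  formula_table(sp, file = tf)
  expect_identical(utils::read.csv(tf, stringsAsFactors = FALSE)$formula,
                   df$formula)
  unlink(tf)
})
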