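#' All weak compositions of n into k parts
#'
#' Ordered tuples of k nonnegative integers summing to n (weak
#' compositions; the parts are indexed, matching partitioning an atom count
#' over an *ordered* set of valence types or elements).  Exhaustive,
#' duplicate-free, deterministic lexicographic order.
#'
#' @param n nonnegative integer total.
#' @param k number of parts (>= 1 unless n == 0).
#' @return integer matrix with k columns, one row per composition;
#'   `choose(n + k - 1, k - 1)` rows.
#' @examples
#' integer_compositions(2, 2)  # (0,2) (1,1) (2,0)
#' @export
integer_compositions <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 0L) stop("n must be >= 0")
  if (k < 1L) {
    if (n > 0L) stop("cannot partition n > 0 into 0 parts")
    return(matrix(integer(0), nrow = 1L, ncol = 0L))
  }
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- integer_compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

#' Can a degree multiset be realized as a molecule skeleton?
#'
#' Tests whether a connected, loop-free undirected multigraph exists whose
#' vertex degrees (counting bond orders) are exactly `degrees`.  The
#' criterion: at least two atoms, even degree sum M, maximum degree at most
#' the sum of the others (stubs of the largest atom must find partners on
#' distinct atoms), and M/2 >= n - 1 bonds to allow connectivity.  Validated
#' against exhaustive enumeration on small cases.
#'
#' @param degrees positive integer vector of vertex degrees.
#' @return logical scalar.
#' @examples
#' is_realizable(c(1, 1))      # TRUE: one bond
#' is_realizable(c(4, 1, 1))   # FALSE: two stubs stranded
#' @export
is_realizable <- function(degrees) {
  degrees <- as.integer(degrees)
  if (length(degrees) < 2L || any(degrees <= 0L)) return(FALSE)
  m <- sum(degrees)
  if (m %% 2L != 0L) return(FALSE)
  if (max(degrees) > m - max(degrees)) return(FALSE)
  m %/% 2L >= length(degrees) - 1L
}

#' Feasible valence compositions of an atom count
#'
#' Distributes `n_atoms` over the ordered valence types of the space and
#' keeps the compositions whose degree multiset has an even sum and is
#' realizable as a connected loop-free multigraph.  At this stage only
#' valences matter, not which element carries them.
#'
#' @param space a [chemical_space()].
#' @param n_atoms total atom count within the space's `natoms` window.
#' @return integer matrix, one row per feasible composition, one column per
#'   valence type (columns follow `space$valence_types`), with attribute
#'   `degree_sum` per row.
#' @export
valence_compositions <- function(space, n_atoms) {
  stopifnot(inherits(space, "chemical_space"))
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < space$natoms[1] || n_atoms > space$natoms[2])
    stop("n_atoms outside the space's natoms window")
  vt <- space$valence_types
  q <- integer_compositions(n_atoms, length(vt))
  ms <- as.vector(q %*% vt)
  keep <- ms %% 2L == 0L
  for (i in which(keep)) {
    keep[i] <- is_realizable(rep(vt, q[i, ]))
  }
  res <- q[keep, , drop = FALSE]
  colnames(res) <- as.character(vt)
  attr(res, "degree_sum") <- ms[keep]
  res
}

#' All constitutions (sum formulas) of an atom count
#'
#' Second stage of the nested partition: every feasible valence composition
#' is refined by partitioning the atoms of each valence type over the
#' elements of that type (Cartesian product across valence types).  This is
#' equivalent to directly partitioning `n_atoms` atoms over all atom types
#' and filtering by parity and realizability, but only generates distinct
#' cases once.
#'
#' @param space a [chemical_space()].
#' @param n_atoms total atom count.
#' @return list of [stoichiometry()] objects, deterministically ordered,
#'   duplicate-free.
#' @examples
#' sp <- chemical_space(c("C","H","F"), c(4,1,1), c(2, 8))
#' length(constitutions(sp, 5))  # 5: CH4, CH3F, CH2F2, CHF3, CF4
#' @export
constitutions <- function(space, n_atoms) {
  stopifnot(inherits(space, "chemical_space"))
  q <- valence_compositions(space, n_atoms)
  vt <- space$valence_types
  out <- list()
  for (r in seq_len(nrow(q))) {
    per_type <- vector("list", length(vt))
    for (i in seq_along(vt)) {
      els <- space_elements(space, vt[i])
      per_type[[i]] <- integer_compositions(q[r, i], length(els))
    }
    idx <- do.call(expand.grid, lapply(per_type, function(m) seq_len(nrow(m))))
    for (rr in seq_len(nrow(idx))) {
      el <- character(0); va <- integer(0); ct <- integer(0)
      for (i in seq_along(vt)) {
        cnts <- per_type[[i]][idx[rr, i], ]
        els <- space_elements(space, vt[i])
        pos <- which(cnts > 0L)
        el <- c(el, els[pos]); va <- c(va, rep(vt[i], length(pos)))
        ct <- c(ct, cnts[pos])
      }
      if (length(el) > 0L)
        out[[length(out) + 1L]] <- stoichiometry(el, va, ct)
    }
  }
  # deterministic order and duplicate guard by formula string
  keys <- vapply(out, formula_string, character(1))
  out <- out[!duplicated(keys)]
  out[order(vapply(out, formula_string, character(1)))]
}

#' All constitutions over the space's full atom-count window
#'
#' @param space a [chemical_space()].
#' @return list of `stoichiometry`, concatenated over
#'   `natoms[1]:natoms[2]`.
#' @export
space_constitutions <- function(space) {
  stopifnot(inherits(space, "chemical_space"))
  do.call(c, lapply(space$natoms[1]:space$natoms[2],
                    function(n) constitutions(space, n)))
}

#' Export a formula list as a data.frame / CSV
#'
#' @param space a [chemical_space()].
#' @param file optional path; when given, written as CSV.
#' @return data.frame with columns `formula`, `ds_key`, `natoms`
#'   (invisibly when `file` is given).
#' @export
formula_table <- function(space, file = NULL) {
  cons <- space_constitutions(space)
  df <- data.frame(
    formula = vapply(cons, formula_string, character(1)),
    ds_key = vapply(cons, function(s) ds_key(degree_sequence_of(s)),
                    character(1)),
    natoms = vapply(cons, function(s) attr(s, "natoms"), integer(1)),
    stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
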