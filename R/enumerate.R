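#' Exhaustively enumerate protomolecules of a degree sequence
#'
#' Generates every connected loop-free multigraph (up to isomorphism
#' respecting element slots and bond orders) whose vertex degrees realize
#' the labeled degree sequence.  Partial graphs are grown one bond unit at a
#' time, always incident to the lowest-index unsaturated vertex, and
#' deduplicated per level by canonical form — completeness follows because
#' any target graph admits a build order obeying that rule, and isomorphic
#' partial states have isomorphic completion sets.  This enumerator is the
#' correctness oracle for every estimator in the package; it favors
#' simplicity over speed and refuses beyond a configurable atom cap.
#'
#' @param d a `degree_seq`.
#' @param cap refuse when the total atom count exceeds this (default 10);
#'   raise explicitly for known-small universes with more atoms.
#' @return list of `protomolecule` objects (possibly empty when `d` is not
#'   realizable); duplicate-free up to isomorphism.
#' @examples
#' enumerate_protomolecules(degree_seq(1, 2))       # the single-bond graph
#' length(enumerate_protomolecules(degree_seq(c(4, 1), c(4, 10)), cap = 14))
#' @export
enumerate_protomolecules <- function(d, cap = 10L) {
  stopifnot(inherits(d, "degree_seq"))
  at <- ds_atoms(d)
  n <- length(at$degree)
  if (n > cap)
    stop(sprintf(paste0("degree sequence has %d atoms, above the exact-",
                        "enumeration cap (%d); use the count estimators ",
                        "or raise `cap`"), n, cap))
  if (!is_realizable(at$degree)) return(list())
  munits <- sum(at$degree) %/% 2L
  empty <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "mult")))
  states <- list(empty)
  for (level in seq_len(munits)) {
    seen <- new.env(parent = emptyenv())
    nxt <- list()
    for (st in states) {
      rem <- at$degree - edge_degrees(st, n)
      v <- which(rem > 0L)[1L]
      for (u in which(rem > 0L)) {
        if (u == v) next
        cand <- bump_edge(st, v, u)
        rem2 <- rem; rem2[v] <- rem2[v] - 1L; rem2[u] <- rem2[u] - 1L
        if (!completable(cand, rem2, n)) next
        key <- partial_key(d, at, cand)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    states <- nxt
    if (length(states) == 0L) break
  }
  lapply(states, function(e) protomolecule(d, e, check = FALSE))
}

edge_degrees <- function(edges, n) {
  deg <- integer(n)
  for (r in seq_len(nrow(edges))) {
    deg[edges[r, 1L]] <- deg[edges[r, 1L]] + edges[r, 3L]
    deg[edges[r, 2L]] <- deg[edges[r, 2L]] + edges[r, 3L]
  }
  deg
}

bump_edge <- function(edges, v, u) {
  i <- min(v, u); j <- max(v, u)
  hit <- which(edges[, 1L] == i & edges[, 2L] == j)
  if (length(hit) == 1L) {
    edges[hit, 3L] <- edges[hit, 3L] + 1L
    edges
  } else {
    rbind(edges, c(i, j, 1L))
  }
}

# prune: remaining stubs must pair across distinct vertices, and no
# component may close off before absorbing all vertices
completable <- function(edges, rem, n) {
  s <- sum(rem)
  if (s > 0L && max(rem) > s - max(rem)) return(FALSE)
  comp <- components_of(edges, n)
  open <- tapply(rem, comp, sum)
  ncomp <- length(open)
  if (s == 0L) return(ncomp == 1L)
  if (any(open == 0L) && ncomp > 1L) return(FALSE)
  # joining k components needs k-1 bonds; each consumes 2 stubs
  if (s %/% 2L < ncomp - 1L) return(FALSE)
  TRUE
}

components_of <- function(edges, n) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1L]); b <- find(edges[r, 2L])
    if (a != b) comp[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

partial_key <- function(d, at, edges) {
  g <- structure(list(d = d, degree = at$degree, type = at$type,
                      edges = edges, elements = NULL),
                 class = "protomolecule")
  proto_key(g)
}

#' Exact protomolecule count of a degree sequence
#'
#' Cardinality of [enumerate_protomolecules()]; 0 for unrealizable input.
#' @inheritParams enumerate_protomolecules
#' @return nonnegative integer.
#' @examples
#' count_exact(degree_seq(1, 2))  # 1
#' @export
count_exact <- function(d, cap = 10L) {
  length(enumerate_protomolecules(d, cap = cap))
}
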