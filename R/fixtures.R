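#' Generate the fixture suite of exactly enumerable chemical spaces
#'
#' Emits small chemical spaces whose full universes can be enumerated
#' exhaustively, together with their exact counts — the ground truth
#' against which the estimators, the sampler and the comparison metrics
#' are validated.  One fixture ("fig3_scale") is a joint set of five
#' stoichiometries with 162 molecular graphs in total, mirroring the scale
#' of the canonical uniformity test (five stoichiometries, ~175 graphs).
#'
#' All content is deterministic; `seed` is accepted for interface
#' uniformity and regeneration with any fixed seed is byte-identical.
#'
#' @param seed unused beyond provenance stamping.
#' @param enumerate when TRUE (default) each fixture carries its
#'   enumerated universes; FALSE returns the definitions only.
#' @return named list of fixtures; each is a list with `name`, `space`,
#'   `formulas` (character keys), `constitutions`, and (when enumerated)
#'   `universes` (named list of protomolecule lists) and `counts` (named
#'   numeric).
#' @export
make_fixtures <- function(seed = 1L, enumerate = TRUE) {
  defs <- list(
    # the two-monovalent-atom worked example: X2, XY, Y2
    monovalent_pair = list(
      space = chemical_space(c("H", "F"), c(1, 1), c(2, 2)),
      formulas = NULL, cap = 10L),
    # pure carbon-hydride space: alkane/alkene/alkyne analogues
    hydrocarbon = list(
      space = chemical_space(c("C", "H"), c(4, 1), c(2, 8)),
      formulas = NULL, cap = 10L),
    # two divalent elements plus hydrogen: chain/ring mixing
    chalcogen_mix = list(
      space = chemical_space(c("O", "S", "H"), c(2, 2, 1), c(3, 6)),
      formulas = NULL, cap = 10L),
    # halomethane-like: 9 formulas at 5 atoms incl. the CH4..CF4 family
    halomethane = list(
      space = chemical_space(c("C", "H", "F"), c(4, 1, 1), c(5, 5)),
      formulas = NULL, cap = 10L),
    # five stoichiometries, 162 graphs in total (8 atoms each)
    fig3_scale = list(
      space = chemical_space(c("C", "H", "F"), c(4, 1, 1), c(8, 8)),
      formulas = c("C4F1H3", "C4F2H2", "C4F3H1", "C4H4", "C6H2"),
      cap = 10L)
  )
  out <- lapply(names(defs), function(nm) {
    def <- defs[[nm]]
    cons <- space_constitutions(def$space)
    keys <- vapply(cons, formula_string, character(1))
    if (!is.null(def$formulas)) {
      cons <- cons[keys %in% def$formulas]
      keys <- keys[keys %in% def$formulas]
    }
    fx <- list(name = nm, space = def$space, formulas = keys,
               constitutions = cons, seed = seed)
    if (enumerate) {
      fx$universes <- lapply(cons, function(s)
        enumerate_protomolecules(degree_sequence_of(s), cap = def$cap))
      names(fx$universes) <- keys
      fx$counts <- stats::setNames(
        vapply(fx$universes, length, integer(1)), keys)
    }
    fx
  })
  names(out) <- names(defs)
  out
}

#' Universe reachability check for the edge-swap chain
#'
#' Verifies ergodicity on an enumerable universe: starting from each graph,
#' the transitive closure of all valid double edge swaps (loop-free,
#' connectivity-preserving) must cover the entire enumerated universe.
#'
#' @param universe list of `protomolecule`s of one degree sequence.
#' @return TRUE when the swap graph over the universe is connected;
#'   attribute `n_reached` carries the closure size from the first graph.
#' @export
swap_reachability <- function(universe) {
  stopifnot(length(universe) > 0L)
  keys <- vapply(universe, proto_key, character(1))
  if (length(universe) == 1L) {
    return(structure(TRUE, n_reached = 1L))
  }
  n <- length(universe[[1L]]$degree)
  d <- universe[[1L]]$d
  neighbors <- function(g) {
    inst <- edges_to_instances(g$edges)
    E <- nrow(inst)
    nbr <- character(0)
    if (E < 2L) return(nbr)
    for (r in seq_len(E - 1L)) for (s in (r + 1L):E) {
      for (flip in c(FALSE, TRUE)) {
        p1 <- inst[r, ]; p2 <- inst[s, ]
        if (flip) p2 <- rev(p2)
        a <- p1[1L]; b <- p1[2L]; cc <- p2[1L]; dd <- p2[2L]
        if (a == cc || b == dd || b == cc || a == dd) next
        inst2 <- inst
        inst2[r, ] <- c(min(a, cc), max(a, cc))
        inst2[s, ] <- c(min(b, dd), max(b, dd))
        if (!inst_connected(inst2, n)) next
        g2 <- protomolecule(d, collapse_edges(inst2[, 1L], inst2[, 2L]),
                            check = FALSE)
        nbr <- c(nbr, proto_key(g2))
      }
    }
    unique(nbr)
  }
  seen <- logical(length(universe))
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (i in frontier) {
      for (k in neighbors(universe[[i]])) {
        j <- match(k, keys)
        if (is.na(j)) stop("swap produced a graph outside the universe")
        if (!seen[j]) { seen[j] <- TRUE; nxt <- c(nxt, j) }
      }
    }
    frontier <- nxt
  }
  structure(all(seen), n_reached = sum(seen))
}
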