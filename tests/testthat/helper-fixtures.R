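# shared fixtures, built once per test run on first use
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  v <- .fixture_cache[[name]]
  if (is.null(v)) {
    v <- force(expr)
    .fixture_cache[[name]] <- v
  }
  v
}

# the cheap fixture suite (no fig3 universes): definitions + universes for
# the four small spaces
small_fixtures <- function() memo("small", {
  fx <- make_fixtures(enumerate = FALSE)
  fx$fig3_scale <- NULL
  for (nm in names(fx)) {
    cons <- fx[[nm]]$constitutions
    fx[[nm]]$universes <- lapply(cons, function(s)
      enumerate_protomolecules(degree_sequence_of(s), cap = 10L))
    names(fx[[nm]]$universes) <- fx[[nm]]$formulas
    fx[[nm]]$counts <- vapply(fx[[nm]]$universes, length, integer(1))
  }
  fx
})

fig3_fixture <- function() memo("fig3", make_fixtures(enumerate = TRUE)$fig3_scale)

# brute-force one-stage constitution oracle: partition n atoms over ALL
# atom types directly, filter by parity + realizability
oracle_constitutions <- function(space, n_atoms) {
  k <- length(space$elements)
  parts <- integer_compositions(n_atoms, k)
  out <- list()
  for (r in seq_len(nrow(parts))) {
    cnt <- parts[r, ]
    keep <- cnt > 0L
    if (!any(keep)) next
    degs <- rep(space$valences[keep], cnt[keep])
    if (sum(degs) %% 2L != 0L) next
    if (!is_realizable(degs)) next
    out[[length(out) + 1L]] <- stoichiometry(space$elements[keep],
                                             space$valences[keep],
                                             cnt[keep])
  }
  sort(vapply(out, formula_string, character(1)))
}

# brute-force realizability oracle: enumerate all multigraphs on n <= 5
# vertices by multiplicity vectors over vertex pairs
oracle_realizable <- function(degrees) {
  n <- length(degrees)
  if (n < 2L) return(FALSE)
  pairs <- t(utils::combn(n, 2L))
  maxm <- min(degrees[pairs[, 1L]], degrees[pairs[, 2L]])
  grid <- as.matrix(do.call(expand.grid, lapply(seq_len(nrow(pairs)),
    function(r) 0:min(degrees[pairs[r, 1L]], degrees[pairs[r, 2L]]))))
  for (g in seq_len(nrow(grid))) {
    m <- grid[g, ]
    deg <- integer(n)
    for (r in seq_len(nrow(pairs))) {
      deg[pairs[r, 1L]] <- deg[pairs[r, 1L]] + m[r]
      deg[pairs[r, 2L]] <- deg[pairs[r, 2L]] + m[r]
    }
    if (!all(deg == degrees)) next
    e <- cbind(pairs[m > 0L, 1L], pairs[m > 0L, 2L], m[m > 0L])
    if (proto_connected(matrix(e, ncol = 3L), n)) return(TRUE)
  }
  FALSE
}

# random realizable degree sequence generator for property tests
random_degree_seq <- function(max_atoms = 8L, max_val = 4L) {
  repeat {
    n_slots <- sample(1:3, 1L)
    vals <- sample(seq_len(max_val), n_slots, replace = TRUE)
    cnts <- vapply(seq_len(n_slots), function(i) sample(1:4, 1L), integer(1))
    if (sum(cnts) < 2L || sum(cnts) > max_atoms) next
    d <- tryCatch(degree_seq(vals, cnts), error = function(e) NULL)
    if (is.null(d)) next
    if (is_realizable(ds_atoms(d)$degree)) return(d)
  }
}

proto_keys <- function(gs) vapply(gs, proto_key, character(1))
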