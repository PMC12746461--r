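#' Sampler configuration
#'
#' @param burn_in chain steps discarded before the first sample; default
#'   `10 * E` where `E` is the bond-unit count (set when `NULL`).
#' @param thinning steps between retained samples; default `5 * E`, which
#'   makes consecutive draws nearly independent (lag-1 autocorrelation a
#'   few percent on the validation fixtures).
#' @param seed optional master seed; per-chain seeds are derived by counter.
#' @param aut_correction target uniformity over isomorphism classes by
#'   weighting states with their automorphism-group order inside the
#'   Metropolis-Hastings acceptance (default TRUE).  With FALSE the chain
#'   targets the uniform law over vertex-labeled multigraphs instead —
#'   adequate for large molecules where nontrivial automorphisms are rare.
#' @param max_mult optional cap on bond multiplicity (default unbounded,
#'   i.e. limited only by endpoint valences).
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(burn_in = NULL, thinning = NULL, seed = NULL,
                           aut_correction = TRUE, max_mult = Inf) {
  if (!is.null(burn_in) && burn_in < 1L) stop("burn_in must be >= 1")
  if (!is.null(thinning) && thinning < 1L) stop("thinning must be >= 1")
  structure(list(burn_in = burn_in, thinning = thinning, seed = seed,
                 aut_correction = isTRUE(aut_correction),
                 max_mult = max_mult),
            class = "sampler_config")
}

#' Initial graph realizing a degree sequence
#'
#' Builds one connected loop-free multigraph with the requested degrees:
#' stub matching (random pairing of bond endpoints) with rejection of loops
#' and disconnected outcomes, falling back to a deterministic
#' spanning-tree-plus-greedy-pairing construction.  The result is biased;
#' the Markov chain removes the bias.
#'
#' @param d a realizable `degree_seq`.
#' @param tries stub-matching attempts before the deterministic fallback.
#' @return a `protomolecule`.
#' @export
initial_graph <- function(d, tries = 30L) {
  stopifnot(inherits(d, "degree_seq"))
  at <- ds_atoms(d)
  if (!is_realizable(at$degree)) stop("degree sequence is not realizable")
  n <- length(at$degree)
  for (k in seq_len(tries)) {
    stubs <- sample(rep(seq_len(n), at$degree))
    i <- stubs[seq(1L, length(stubs), 2L)]
    j <- stubs[seq(2L, length(stubs), 2L)]
    if (any(i == j)) next
    e <- collapse_edges(i, j)
    if (!proto_connected(e, n)) next
    return(protomolecule(d, e, check = FALSE))
  }
  protomolecule(d, greedy_realization(at$degree), check = FALSE)
}

collapse_edges <- function(i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  key <- paste(a, b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  cbind(i = as.integer(vapply(parts, `[`, "", 1L)),
        j = as.integer(vapply(parts, `[`, "", 2L)),
        mult = as.integer(tab))
}

# deterministic fallback: spanning tree over all vertices, then repeatedly
# bond the two vertices with the most remaining stubs
greedy_realization <- function(degree) {
  n <- length(degree)
  rem <- degree
  i <- integer(0); j <- integer(0)
  for (v in 2:n) {
    u <- which(rem > if (v < n) 1L else 0L)
    u <- u[u < v]
    if (length(u) == 0L) u <- which(rem > 0L); u <- u[u < v]
    if (length(u) == 0L) stop("greedy realization failed")  # unreachable for realizable input
    u <- u[which.max(rem[u])]
    i <- c(i, u); j <- c(j, v)
    rem[u] <- rem[u] - 1L; rem[v] <- rem[v] - 1L
  }
  while (sum(rem) > 0L) {
    o <- order(rem, decreasing = TRUE)
    a <- o[1L]; b <- o[2L]
    if (rem[b] == 0L) stop("greedy realization failed")
    i <- c(i, a); j <- c(j, b)
    rem[a] <- rem[a] - 1L; rem[b] <- rem[b] - 1L
  }
  collapse_edges(i, j)
}

# One Metropolis-Hastings double-edge-swap step on the edge-instance list.
# state: list(inst = E x 2 matrix of bond-unit endpoints, rows sorted
# (min, max); aut = |Aut| of the current graph).
# Proposal: pick two bond units uniformly, rewire one of the two ways;
# reject loops, disconnection, multiplicity-cap violations.  The proposal
# probability of a specific rewiring is proportional to m_ab * m_cd
# (instance choices) while the reverse needs (m_ac + 1)(m_bd + 1), so the
# acceptance ratio corrects for that asymmetry; with the automorphism
# correction the target is pi(G) proportional to |Aut(G)| over
# vertex-labeled multigraphs, which makes isomorphism classes
# equiprobable.
mcmc_step_state <- function(state, n, cfg, aut_cache) {
  inst <- state$inst
  E <- nrow(inst)
  pick <- sample.int(E, 2L)
  p1 <- inst[pick[1L], ]; p2 <- inst[pick[2L], ]
  if (stats::runif(1) < 0.5) p2 <- rev(p2)
  a <- p1[1L]; b <- p1[2L]; cc <- p2[1L]; dd <- p2[2L]
  if (a == cc || b == dd) return(state)   # rewiring would create a loop
  if (b == cc || a == dd) return(state)   # rewiring is the identity
  i1 <- inst[, 1L]; i2 <- inst[, 2L]
  cnt <- function(x, y) {
    lo <- if (x < y) x else y; hi <- if (x < y) y else x
    sum(i1 == lo & i2 == hi)
  }
  m_ab <- cnt(a, b); m_cd <- cnt(cc, dd)
  m_ac <- cnt(a, cc); m_bd <- cnt(b, dd)
  if (m_ac + 1L > cfg$max_mult || m_bd + 1L > cfg$max_mult) return(state)
  inst2 <- inst
  inst2[pick[1L], ] <- c(min(a, cc), max(a, cc))
  inst2[pick[2L], ] <- c(min(b, dd), max(b, dd))
  if (!inst_connected(inst2, n)) return(state)
  log_alpha <- log(m_ac + 1) + log(m_bd + 1) - log(m_ab) - log(m_cd)
  aut2 <- NULL
  if (cfg$aut_correction) {
    aut2 <- aut_cache(inst2)
    log_alpha <- log_alpha + log(aut2) - log(state$aut)
  }
  if (log(stats::runif(1)) < log_alpha) {
    list(inst = inst2, aut = if (is.null(aut2)) state$aut else aut2)
  } else state
}

# connectivity over the instance list (E x 2), vertices 1..n
inst_connected <- function(inst, n) {
  seen <- logical(n)
  seen[inst[1L, 1L]] <- TRUE
  frontier <- inst[1L, 1L]
  while (length(frontier) > 0L) {
    hit <- inst[, 1L] %in% frontier | inst[, 2L] %in% frontier
    nb <- unique(c(inst[hit, 1L], inst[hit, 2L]))
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

#' One double-edge-swap MCMC step
#'
#' Exposed single-step interface over the chain used by [sample_graphs()].
#' Degrees are preserved exactly; proposals creating loops or disconnecting
#' the graph are rejected (the state repeats).
#' @param g a `protomolecule`.
#' @param config a [sampler_config()] (the automorphism flag and bond cap
#'   are honored; burn-in/thinning are irrelevant for a single step).
#' @return a `protomolecule` (possibly identical to `g`).
#' @export
mcmc_step <- function(g, config = sampler_config()) {
  n <- length(g$degree)
  cache <- make_aut_cache(g$d)
  inst <- edges_to_instances(g$edges)
  st <- list(inst = inst,
             aut = if (config$aut_correction) cache(inst) else 1)
  if (nrow(st$inst) >= 2L) st <- mcmc_step_state(st, n, config, cache)
  protomolecule(g$d, collapse_edges(st$inst[, 1L], st$inst[, 2L]),
                elements = g$elements, check = FALSE)
}

edges_to_instances <- function(edges) {
  cbind(rep(edges[, 1L], edges[, 3L]), rep(edges[, 2L], edges[, 3L]))
}

# memoized |Aut| over vertex-labeled states, keyed by the sorted
# instance-pair serialization
make_aut_cache <- function(d) {
  env <- new.env(parent = emptyenv())
  at <- ds_atoms(d)
  function(inst) {
    k <- paste(sort(paste0(inst[, 1L], "_", inst[, 2L])), collapse = "|")
    v <- env[[k]]
    if (is.null(v)) {
      edges <- collapse_edges(inst[, 1L], inst[, 2L])
      g <- structure(list(d = d, degree = at$degree, type = at$type,
                          edges = edges, elements = NULL),
                     class = "protomolecule")
      v <- proto_automorphisms(g)
      env[[k]] <- v
    }
    v
  }
}

#' Sample protomolecules of one degree sequence
#'
#' Runs the degree-preserving double-edge-swap Markov chain from a
#' stub-seeded start and returns `n` states after burn-in, one every
#' `thinning` steps.  With the automorphism correction on (default) the
#' stationary law is uniform over isomorphism classes.
#'
#' @param d a realizable `degree_seq`.
#' @param n number of samples.
#' @param config a [sampler_config()].
#' @return list of `molecule_sample` objects: each carries the
#'   `protomolecule` plus `seed` and chain statistics.
#' @export
sample_graphs <- function(d, n, config = sampler_config()) {
  stopifnot(inherits(d, "degree_seq"), n >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  g0 <- initial_graph(d)
  nv <- length(g0$degree)
  E <- sum(g0$edges[, 3L])
  burn <- if (is.null(config$burn_in)) 10L * E else config$burn_in
  thin <- if (is.null(config$thinning)) 5L * E else config$thinning
  cache <- make_aut_cache(d)
  inst0 <- edges_to_instances(g0$edges)
  st <- list(inst = inst0,
             aut = if (config$aut_correction) cache(inst0) else 1)
  out <- vector("list", n)
  single_bond <- E < 2L  # no swap possible: universe of one labeled state
  step <- function(s) if (single_bond) s else mcmc_step_state(s, nv, config, cache)
  for (k in seq_len(burn)) st <- step(st)
  for (s in seq_len(n)) {
    for (k in seq_len(thin)) st <- step(st)
    ecoll <- collapse_edges(st$inst[, 1L], st$inst[, 2L])
    out[[s]] <- structure(list(
      protomolecule = protomolecule(d, ecoll, check = FALSE),
      stoichiometry = NULL, seed = config$seed,
      chain = list(burn_in = burn, thinning = thin, step = burn + s * thin)),
      class = "molecule_sample")
  }
  out
}

#' @export
print.molecule_sample <- function(x, ...) {
  cat("Molecule sample:", length(x$protomolecule$degree), "atoms")
  if (!is.null(x$stoichiometry))
    cat(",", formula_string(x$stoichiometry))
  cat("\n")
  invisible(x)
}

#' Randomly assign concrete elements to a protomolecule
#'
#' Maps the element-slot vertices of `g` onto the concrete elements of a
#' compatible stoichiometry, uniformly at random among same-valence slots
#' of equal multiplicity patterns.
#' @param g a `protomolecule`.
#' @param s a `stoichiometry` whose degree sequence matches `g$d`.
#' @return a `molecule_sample` with `elements` filled in.
#' @export
assign_elements <- function(g, s) {
  ds <- degree_sequence_of(s)
  if (!identical(ds_key(ds), ds_key(g$d)))
    stop("stoichiometry incompatible with the protomolecule's degree sequence")
  # slot -> element: within each valence, slots with equal counts are
  # interchangeable; permute them uniformly
  slot_el <- attr(ds, "elements")
  perm <- seq_len(nrow(ds))
  for (v in unique(ds$valence)) {
    ix <- which(ds$valence == v)
    for (cval in unique(ds$count[ix])) {
      grp <- ix[ds$count[ix] == cval]
      if (length(grp) > 1L) perm[grp] <- grp[sample.int(length(grp))]
    }
  }
  els <- slot_el[perm][g$type]
  structure(list(
    protomolecule = protomolecule(g$d, g$edges, elements = els, check = FALSE),
    stoichiometry = s, seed = NULL, chain = NULL),
    class = "molecule_sample")
}

#' Sample molecules from a whole chemical space
#'
#' Two-stage sampling: a stoichiometry is drawn with probability
#' proportional to its (estimated) protomolecule count, then a graph is
#' drawn within it by [sample_graphs()]; finally concrete elements are
#' assigned.  One chain per stoichiometry is maintained; draws across
#' stoichiometries are independent.
#'
#' @param space a [chemical_space()].
#' @param n number of molecules.
#' @param counts optional named numeric vector of per-formula weights
#'   (names = [formula_string()] of each constitution).  When `NULL`,
#'   counts are computed on demand via [estimate_count()] against `db`.
#' @param db optional counts database (see [counts_db()]).
#' @param config a [sampler_config()].
#' @param cap exact-enumeration cap forwarded to on-demand counting.
#' @param formulas optional character vector of formula keys
#'   ([formula_string()]) restricting sampling to a subset of the space's
#'   constitutions (a joint sample over chosen stoichiometries).
#' @return list of `molecule_sample`s.
#' @export
sample_space <- function(space, n, counts = NULL, db = NULL,
                         config = sampler_config(), cap = 10L,
                         formulas = NULL) {
  stopifnot(inherits(space, "chemical_space"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cons <- space_constitutions(space)
  if (!is.null(formulas)) {
    have <- vapply(cons, formula_string, character(1))
    missing <- setdiff(formulas, have)
    if (length(missing) > 0L)
      stop("formulas not in the space: ", paste(missing, collapse = ", "))
    cons <- cons[have %in% formulas]
  }
  if (length(cons) == 0L) stop("no feasible formulas in the space")
  keys <- vapply(cons, formula_string, character(1))
  if (is.null(counts)) {
    if (is.null(db)) db <- counts_db()
    w <- vapply(cons, function(s) {
      estimate_count(degree_sequence_of(s), db = db, cap = cap)$count
    }, numeric(1))
  } else {
    w <- as.numeric(counts[keys])
    if (anyNA(w)) stop("counts missing for some formulas: ",
                       paste(keys[is.na(w)], collapse = ", "))
  }
  keep <- w > 0
  cons <- cons[keep]; w <- w[keep]; keys <- keys[keep]
  if (length(cons) == 0L) stop("no formula has a positive count")
  pick <- sample.int(length(cons), n, replace = TRUE, prob = w)
  out <- vector("list", n)
  per <- table(factor(pick, levels = seq_along(cons)))
  slots <- split(seq_len(n), pick)
  for (ci in which(per > 0L)) {
    d <- degree_sequence_of(cons[[ci]])
    sub_cfg <- config; sub_cfg$seed <- NULL  # master seed already applied
    gs <- sample_graphs(d, per[ci], sub_cfg)
    tgt <- slots[[as.character(ci)]]
    for (k in seq_along(tgt)) {
      ms <- assign_elements(gs[[k]]$protomolecule, cons[[ci]])
      ms$chain <- gs[[k]]$chain; ms$seed <- config$seed
      out[[tgt[k]]] <- ms
    }
  }
  out
}
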