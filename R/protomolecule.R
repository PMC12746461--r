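#' Construct a protomolecule
#'
#' A protomolecule is a connected, loop-free undirected multigraph whose
#' vertices are atom-type slots and whose edge multiplicities are bond
#' orders; every vertex's degree (summing bond orders) equals its valence.
#' Vertices are typed by the entry index of a labeled degree sequence;
#' concrete element labels are optional decoration added at sampling time.
#'
#' @param d the `degree_seq` the graph realizes.
#' @param edges integer matrix with columns `i`, `j`, `mult` (1-based vertex
#'   indices, i < j, one row per bonded pair).  Vertex order follows
#'   [ds_atoms()].
#' @param elements optional character vector of concrete element labels per
#'   vertex.
#' @param check verify invariants (degree saturation, connectivity).
#' @return object of class `protomolecule`: list with `d`, `degree`, `type`,
#'   `edges`, `elements`.
#' @export
protomolecule <- function(d, edges, elements = NULL, check = TRUE) {
  stopifnot(inherits(d, "degree_seq"))
  at <- ds_atoms(d)
  edges <- matrix(as.integer(edges), ncol = 3L,
                  dimnames = list(NULL, c("i", "j", "mult")))
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    if (any(swap)) edges[swap, 1:2] <- edges[swap, 2:1]
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
  }
  g <- structure(list(d = d, degree = at$degree, type = at$type,
                      edges = edges, elements = elements),
                 class = "protomolecule")
  if (check) validate_protomolecule(g)
  g
}

validate_protomolecule <- function(g) {
  e <- g$edges
  n <- length(g$degree)
  if (nrow(e) > 0L) {
    if (any(e[, 1L] == e[, 2L])) stop("self-loop in protomolecule")
    if (any(e[, 3L] <= 0L)) stop("nonpositive bond order")
    if (anyDuplicated(e[, 1L] * (n + 1L) + e[, 2L]))
      stop("duplicate edge rows; use multiplicity")
  }
  deg <- integer(n)
  for (r in seq_len(nrow(e))) {
    deg[e[r, 1L]] <- deg[e[r, 1L]] + e[r, 3L]
    deg[e[r, 2L]] <- deg[e[r, 2L]] + e[r, 3L]
  }
  if (!all(deg == g$degree)) stop("vertex degree does not match valence")
  if (!proto_connected(e, n)) stop("protomolecule not connected")
  if (!is.null(g$elements) && length(g$elements) != n)
    stop("elements length mismatch")
  invisible(g)
}

# connectivity of an edge list over n vertices (multiplicities irrelevant)
proto_connected <- function(edges, n) {
  if (n == 1L) return(TRUE)
  if (nrow(edges) < n - 1L) return(FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); seen[1L] <- TRUE; stack <- 1L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]; new <- nb[!seen[nb]]
    seen[new] <- TRUE; stack <- c(stack, new)
  }
  all(seen)
}

#' @export
print.protomolecule <- function(x, ...) {
  cat("Protomolecule:", length(x$degree), "atoms,",
      sum(x$edges[, 3L]), "bond units,", nrow(x$edges), "bonded pairs\n")
  invisible(x)
}

#' Bond-order adjacency matrix
#' @param g a `protomolecule`.
#' @return symmetric integer matrix of bond multiplicities.
#' @export
adjacency_multiplicity <- function(g) {
  n <- length(g$degree)
  A <- matrix(0L, n, n)
  for (r in seq_len(nrow(g$edges))) {
    i <- g$edges[r, 1L]; j <- g$edges[r, 2L]; m <- g$edges[r, 3L]
    A[i, j] <- m; A[j, i] <- m
  }
  A
}

# Expand a typed multigraph into a vertex-colored *simple* graph for
# igraph/BLISS: real vertices keep color = type id; each bonded pair gets
# one auxiliary vertex colored (n_types + multiplicity) linked to both
# endpoints.  Isomorphism of the expansions (color-preserving) is exactly
# element-slot-respecting multigraph isomorphism.
proto_expand <- function(g) {
  n <- length(g$degree)
  ntype <- nrow(g$d)
  ne <- nrow(g$edges)
  if (ne > 0L) {
    aux <- n + seq_len(ne)
    el <- rbind(cbind(g$edges[, 1L], aux), cbind(g$edges[, 2L], aux))
    colors <- c(g$type, ntype + g$edges[, 3L])
  } else {
    el <- matrix(integer(0), ncol = 2L)
    colors <- g$type
  }
  gr <- igraph::make_empty_graph(n + ne, directed = FALSE)
  if (nrow(el) > 0L) gr <- igraph::add_edges(gr, t(el))
  list(graph = gr, colors = colors, n = n)
}

#' Canonical text key of a protomolecule
#'
#' Two protomolecules of the same degree sequence receive equal keys if and
#' only if they are isomorphic respecting element slots and bond orders
#' (canonical labeling via igraph/BLISS on a colored expansion).
#' @param g a `protomolecule`.
#' @return character scalar.
#' @export
proto_key <- function(g) {
  n <- length(g$degree)
  if (nrow(g$edges) == 0L) return(paste0("n", n, ";"))
  ex <- proto_expand(g)
  perm <- igraph::canonical_permutation(ex$graph, colors = ex$colors)$labeling
  # rank of each real vertex in the canonical labeling of the expansion;
  # BLISS colors keep real/aux vertices distinguishable, so ranks are
  # isomorphism-invariant
  pos <- rank(perm[seq_len(n)])
  ed <- g$edges
  a <- pmin(pos[ed[, 1L]], pos[ed[, 2L]])
  b <- pmax(pos[ed[, 1L]], pos[ed[, 2L]])
  ord <- order(a, b)
  paste0("n", n, ";t", paste(g$type[order(pos)], collapse = ","), ";",
         paste(sprintf("%d-%d:%d", a[ord], b[ord], ed[ord, 3L]),
               collapse = "|"))
}

#' Order of the slot-respecting automorphism group
#'
#' Counts automorphisms of the protomolecule that preserve vertex types and
#' bond orders (exact, via igraph/BLISS on the colored expansion).
#' @param g a `protomolecule`.
#' @return numeric scalar (group order).
#' @export
proto_automorphisms <- function(g) {
  if (nrow(g$edges) == 0L) return(factorial(length(g$degree)))
  ex <- proto_expand(g)
  as.numeric(igraph::count_automorphisms(ex$graph, colors = ex$colors)$group_size)
}

#' Serialize a protomolecule to graph JSON
#'
#' Format: object with `vertices` (list of `{element, valence}`; element is
#' the slot tag when no concrete elements are assigned) and `edges` (list of
#' `[i, j, multiplicity]`, 1-based).
#' @param g a `protomolecule`.
#' @param file optional path; when given the JSON is written there.
#' @return JSON string (invisibly when `file` is given).
#' @export
proto_to_json <- function(g, file = NULL) {
  els <- if (!is.null(g$elements)) g$elements
         else sprintf("X%d", g$type)
  obj <- list(
    vertices = lapply(seq_along(g$degree), function(i)
      list(element = els[i], valence = g$degree[i])),
    edges = lapply(seq_len(nrow(g$edges)), function(r)
      as.integer(g$edges[r, ])))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' Read a protomolecule from graph JSON
#' @param txt JSON string or path to a JSON file.
#' @return a `protomolecule` (with `elements` set).
#' @export
proto_from_json <- function(txt) {
  if (length(txt) == 1L && file.exists(txt)) txt <- paste(readLines(txt), collapse = "")
  obj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  val <- vapply(obj$vertices, function(v) as.integer(v$valence), integer(1))
  els <- vapply(obj$vertices, function(v) as.character(v$element), character(1))
  edges <- do.call(rbind, lapply(obj$edges, as.integer))
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 3L)
  molecule_from_atoms(els, val, edges)
}

# build a protomolecule from explicit atoms: derive the degree sequence from
# (element, valence) pairs, then reorder vertices canonically
molecule_from_atoms <- function(elements, valences, edges, check = TRUE) {
  tab <- stats::aggregate(list(count = seq_along(elements)),
                          by = list(element = elements, valence = valences),
                          FUN = length)
  s <- stoichiometry(tab$element, tab$valence, tab$count)
  d <- degree_sequence_of(s)
  slot_el <- attr(d, "elements")
  # assign each atom to the vertex positions of its (element,valence) slot
  at <- ds_atoms(d)
  n <- length(elements)
  perm <- integer(n)  # old index -> new index
  used <- logical(n)
  for (v in seq_len(n)) {
    ent <- at$type[v]
    want_el <- slot_el[ent]; want_va <- d$valence[ent]
    cand <- which(!used & elements == want_el & valences == want_va)[1L]
    used[cand] <- TRUE
    perm[cand] <- v
  }
  ne <- edges
  if (nrow(ne) > 0L) {
    ne[, 1L] <- perm[edges[, 1L]]; ne[, 2L] <- perm[edges[, 2L]]
  }
  protomolecule(d, ne, elements = elements[order(perm)], check = check)
}
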