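#' Define a chemical space
#'
#' A chemical space is the set of all molecules (connected, loop-free,
#' valence-saturated multigraphs) that can be built from a set of atom
#' types within an atom-count window.  An atom type is a pair
#' (element, valence); the same element symbol with two different valences
#' counts as two distinct atom types.  Element labels are opaque: no
#' periodic-table knowledge is used, and relabeling elements of equal
#' valence does not change the set of distinct molecular graphs.
#'
#' @param elements character vector of element labels.
#' @param valences integer vector of valences, parallel to `elements`.
#' @param natoms length-2 integer vector `c(min, max)` of total atom counts;
#'   `min` must be at least 2 (a lone atom has no bonds).
#' @return An object of class `chemical_space` with components
#'   `elements`, `valences`, `natoms`, plus the derived ordered valence
#'   types `valence_types` (descending) and their multiplicities
#'   `multiplicity` (number of elements sharing each valence).
#' @examples
#' sp <- chemical_space(c("C", "H"), c(4, 1), c(2, 10))
#' sp$valence_types   # 4 1
#' sp$multiplicity    # 1 1
#' @export
chemical_space <- function(elements, valences, natoms) {
  if (length(elements) == 0L) stop("empty chemical space: no atom types")
  if (length(elements) != length(valences))
    stop("elements and valences must have equal length")
  valences <- as.integer(valences)
  if (anyNA(valences) || any(valences <= 0L))
    stop("valences must be positive integers")
  if (anyDuplicated(paste(elements, valences, sep = "\r")))
    stop("duplicate (element, valence) atom types")
  natoms <- as.integer(natoms)
  if (length(natoms) != 2L || anyNA(natoms))
    stop("natoms must be c(min, max)")
  if (natoms[1] < 2L) stop("natoms min must be >= 2")
  if (natoms[1] > natoms[2]) stop("natoms min exceeds max")
  ord <- order(-valences, elements)
  elements <- as.character(elements)[ord]
  valences <- valences[ord]
  vt <- sort(unique(valences), decreasing = TRUE)
  mult <- vapply(vt, function(v) sum(valences == v), integer(1))
  structure(list(
    elements = elements, valences = valences, natoms = natoms,
    valence_types = vt, multiplicity = mult
  ), class = "chemical_space")
}

#' @export
print.chemical_space <- function(x, ...) {
  cat("Chemical space:", length(x$elements), "atom types,",
      x$natoms[1], "to", x$natoms[2], "atoms\n")
  for (i in seq_along(x$valence_types)) {
    v <- x$valence_types[i]
    cat(sprintf("  valence %d (multiplicity %d): %s\n", v, x$multiplicity[i],
                paste(x$elements[x$valences == v], collapse = ", ")))
  }
  invisible(x)
}

#' Elements of a given valence
#' @param space a `chemical_space`.
#' @param v a valence present in the space.
#' @return character vector of element labels with valence `v`.
#' @export
space_elements <- function(space, v) {
  stopifnot(inherits(space, "chemical_space"))
  space$elements[space$valences == v]
}

#' Construct a stoichiometry (constitution)
#'
#' A stoichiometry is a multiset of atom types: for each (element, valence)
#' pair, how many atoms of that type the molecule contains.  Entries are
#' stored canonically sorted by descending valence, then element label.
#'
#' @param elements character vector of element labels.
#' @param valences integer vector of valences.
#' @param counts positive integer vector of atom counts.
#' @return An object of class `stoichiometry`: a data.frame with columns
#'   `element`, `valence`, `count` plus attributes `natoms` and `degree_sum`.
#' @examples
#' methane <- stoichiometry(c("C", "H"), c(4, 1), c(1, 4))
#' formula_string(methane)
#' @export
stoichiometry <- function(elements, valences, counts) {
  stopifnot(length(elements) == length(valences),
            length(elements) == length(counts))
  if (length(elements) == 0L) stop("empty stoichiometry")
  valences <- as.integer(valences); counts <- as.integer(counts)
  if (any(counts <= 0L)) stop("counts must be positive")
  if (any(valences <= 0L)) stop("valences must be positive")
  if (anyDuplicated(paste(elements, valences, sep = "\r")))
    stop("duplicate atom type in stoichiometry")
  ord <- order(-valences, elements)
  s <- data.frame(element = as.character(elements)[ord],
                  valence = valences[ord], count = counts[ord],
                  stringsAsFactors = FALSE)
  attr(s, "natoms") <- sum(s$count)
  attr(s, "degree_sum") <- sum(s$count * s$valence)
  class(s) <- c("stoichiometry", "data.frame")
  s
}

#' Sum-formula string of a stoichiometry
#'
#' Hill-like deterministic ordering: descending valence, then element label.
#' The valence is appended in square brackets when an element appears with
#' more than one valence, keeping the string unambiguous.
#' @param s a `stoichiometry`.
#' @return a single character string such as `"C1H4"`.
#' @export
formula_string <- function(s) {
  stopifnot(inherits(s, "stoichiometry"))
  amb <- s$element[duplicated(s$element)]
  paste0(vapply(seq_len(nrow(s)), function(i) {
    e <- s$element[i]
    tag <- if (e %in% amb) sprintf("%s[%d]", e, s$valence[i]) else e
    paste0(tag, s$count[i])
  }, character(1)), collapse = "")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat("Stoichiometry", formula_string(x), "(", attr(x, "natoms"), "atoms )\n")
  invisible(x)
}

#' Labeled degree sequence of a stoichiometry
#'
#' Atoms are grouped into element slots per valence.  Slots are positional
#' placeholders, not chemical symbols: within each valence, slots are
#' ordered by descending atom count (ties by element label), so two
#' stoichiometries that differ only by renaming elements of equal valence
#' map to the same degree sequence.  A degree sequence is *pure* when every
#' valence has a single slot.
#'
#' @param s a `stoichiometry`.
#' @return An object of class `degree_seq`: data.frame with columns
#'   `valence`, `slot`, `count` (canonically ordered by descending valence
#'   then slot), with attributes `pure`, `natoms`, `degree_sum` and
#'   `elements` (the element label behind each slot, for re-expansion).
#' @examples
#' d <- degree_sequence_of(stoichiometry(c("C","H","F"), c(4,1,1), c(1,2,2)))
#' attr(d, "pure")   # FALSE: two monovalent slots
#' @export
degree_sequence_of <- function(s) {
  stopifnot(inherits(s, "stoichiometry"))
  vt <- sort(unique(s$valence), decreasing = TRUE)
  rows <- list(); elems <- character(0)
  for (v in vt) {
    sub <- s[s$valence == v, , drop = FALSE]
    sub <- sub[order(-sub$count, sub$element), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      valence = v, slot = seq_len(nrow(sub)), count = sub$count)
    elems <- c(elems, sub$element)
  }
  d <- do.call(rbind, rows)
  class(d) <- c("degree_seq", "data.frame")
  attr(d, "pure") <- !any(duplicated(d$valence))
  attr(d, "natoms") <- sum(d$count)
  attr(d, "degree_sum") <- sum(d$count * d$valence)
  attr(d, "elements") <- elems
  d
}

#' Construct a labeled degree sequence directly
#'
#' @param valences integer vector, one entry per slot.
#' @param counts atom count per slot.
#' @return a `degree_seq` (see [degree_sequence_of()]); slots carry no
#'   element labels.
#' @export
degree_seq <- function(valences, counts) {
  stopifnot(length(valences) == length(counts))
  valences <- as.integer(valences); counts <- as.integer(counts)
  if (any(valences <= 0L) || any(counts <= 0L))
    stop("valences and counts must be positive")
  fake <- sprintf("s%02d", seq_along(valences))
  degree_sequence_of(stoichiometry(fake, valences, counts))
}

#' @export
print.degree_seq <- function(x, ...) {
  cat("Degree sequence", ds_key(x),
      if (attr(x, "pure")) "(pure)" else "(nonpure)", "\n")
  invisible(x)
}

#' Pure counterpart of a labeled degree sequence
#'
#' Merges all element slots of each valence into a single slot, preserving
#' the per-valence atom counts.  Idempotent; pure sequences are returned
#' unchanged (up to slot labels).
#' @param d a `degree_seq`.
#' @return a pure `degree_seq`.
#' @export
pure_counterpart <- function(d) {
  stopifnot(inherits(d, "degree_seq"))
  vt <- sort(unique(d$valence), decreasing = TRUE)
  cnt <- vapply(vt, function(v) sum(d$count[d$valence == v]), integer(1))
  degree_seq(vt, cnt)
}

#' Canonical text key of a degree sequence
#'
#' Deterministic across sessions (no hash-order dependence); used as the
#' primary key of the counts database.  Format: per valence, descending,
#' `"v:c1,c2"` with slot counts in canonical order, joined by `"|"`,
#' e.g. `"4:1|1:2,2"` for the CH2F2 family.
#' @param d a `degree_seq`.
#' @return character scalar.
#' @export
ds_key <- function(d) {
  stopifnot(inherits(d, "degree_seq"))
  vt <- sort(unique(d$valence), decreasing = TRUE)
  paste(vapply(vt, function(v) {
    paste0(v, ":", paste(d$count[d$valence == v], collapse = ","))
  }, character(1)), collapse = "|")
}

#' Expanded per-atom degree vector of a degree sequence
#'
#' One entry per atom, vertex order: degree-sequence entries in canonical
#' order, each repeated `count` times.  The parallel `type` vector gives the
#' entry (slot) index of each atom.
#' @param d a `degree_seq`.
#' @return list with `degree` (integer vector) and `type` (integer vector).
#' @export
ds_atoms <- function(d) {
  stopifnot(inherits(d, "degree_seq"))
  list(degree = rep(d$valence, d$count), type = rep(seq_len(nrow(d)), d$count))
}
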