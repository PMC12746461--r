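#' Stoichiometry of a parsed molecule
#'
#' Assigns each atom the atom type (element, realized valence), where the
#' realized valence is the sum of incident bond orders — molecules must
#' carry explicit hydrogens and bonds (see [read_molecules()], which
#' converts SMILES accordingly).  An amine nitrogen (N, 3 bonds) and a
#' nitro nitrogen (N, 5 bonds) therefore map to distinct atom types,
#' matching valence-explicit space definitions.
#'
#' @param mol a `protomolecule` with `elements` set, or a `molecule_sample`.
#' @return a [stoichiometry()].
#' @export
stoichiometry_of <- function(mol) {
  if (inherits(mol, "molecule_sample")) {
    if (!is.null(mol$stoichiometry)) return(mol$stoichiometry)
    mol <- mol$protomolecule
  }
  stopifnot(inherits(mol, "protomolecule"))
  if (is.null(mol$elements)) stop("molecule carries no element labels")
  key <- paste(mol$elements, mol$degree, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  stoichiometry(vapply(parts, `[`, "", 1L),
                as.integer(vapply(parts, `[`, "", 2L)),
                as.integer(tab))
}

#' Paired CDFs of a database and its reference space
#'
#' Orders all stoichiometries of the reference space by their (estimated)
#' size in the space — ascending, ties broken by the canonical formula
#' key — and accumulates both the space counts and the database counts
#' over that common support, each normalized by its own total.
#' Database stoichiometries absent from `space_counts` are an error;
#' space stoichiometries absent from the database get probability 0.
#'
#' @param db_counts named numeric vector: molecule count per formula key in
#'   the database.
#' @param space_counts named numeric vector: (estimated) protomolecule
#'   count per formula key in the space; defines the support.
#' @return object of class `paired_cdfs`: data.frame with columns `key`,
#'   `space_p`, `db_p`, `space_cdf`, `db_cdf` in support order.
#' @export
build_cdfs <- function(db_counts, space_counts) {
  if (length(space_counts) == 0L) stop("empty space")
  if (is.null(names(space_counts)) ||
      (length(db_counts) > 0L && is.null(names(db_counts))))
    stop("counts must be named by formula key")
  extra <- setdiff(names(db_counts), names(space_counts))
  if (length(extra) > 0L)
    stop("database stoichiometries outside the space: ",
         paste(extra, collapse = ", "))
  ord <- order(space_counts, names(space_counts))
  keys <- names(space_counts)[ord]
  sp <- as.numeric(space_counts[ord]); sp <- sp / sum(sp)
  dbv <- as.numeric(db_counts[keys]); dbv[is.na(dbv)] <- 0
  tot <- sum(dbv)
  if (tot > 0) dbv <- dbv / tot
  out <- data.frame(key = keys, space_p = sp, db_p = dbv,
                    space_cdf = cumsum(sp), db_cdf = cumsum(dbv),
                    stringsAsFactors = FALSE)
  class(out) <- c("paired_cdfs", "data.frame")
  out
}

#' Kolmogorov-Smirnov statistic of paired CDFs
#'
#' Maximum absolute difference between the two cumulative distribution
#' functions over their common, size-ordered support; 0 for identical
#' distributions, 1 for disjoint supports.
#' @param cdfs a [build_cdfs()] result, or a numeric vector of CDF values
#'   for `P` (then `q` must be the CDF of `Q` on the same support).
#' @param q optional second CDF vector.
#' @return value in \[0, 1\].
#' @export
ks_statistic <- function(cdfs, q = NULL) {
  if (inherits(cdfs, "paired_cdfs"))
    return(max(abs(cdfs$space_cdf - cdfs$db_cdf)))
  if (is.null(q) || length(q) != length(cdfs))
    stop("need two CDF vectors on the same support")
  max(abs(cdfs - q))
}

#' Kullback-Leibler divergence KL(P || Q) over a discrete support
#'
#' `sum_x P(x) log(P(x) / max(Q(x), eps))`, natural log.  Zero-probability
#' bins of `Q` that carry `P` mass are floored at `eps`; the result then
#' carries attribute `eps_triggered = TRUE` because such terms inflate the
#' divergence and make cross-database comparison delicate.
#'
#' @param p,q probability vectors on the same support (each summing to 1),
#'   or a [build_cdfs()] result as `p` (then `space_p`/`db_p` are used,
#'   with the space as `P` and the database as `Q`).
#' @param eps floor for `Q`; default `NULL` means `1 / (10 * length(p))`
#'   scaled — see Details — or supply e.g. `1 / (10 * total_space_count)`.
#' @return nonnegative number with attributes `eps` and `eps_triggered`.
#' @export
kl_divergence <- function(p, q = NULL, eps = NULL) {
  if (inherits(p, "paired_cdfs")) { q <- p$db_p; p <- p$space_p }
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must be normalized")
  if (is.null(eps)) eps <- 1 / (10 * length(p))
  triggered <- any(p > 0 & q < eps)
  qf <- pmax(q, eps)
  ix <- p > 0
  out <- sum(p[ix] * log(p[ix] / qf[ix]))
  attr(out, "eps") <- eps
  attr(out, "eps_triggered") <- triggered
  out
}

#' Representativeness report of a molecule set against a space
#'
#' Groups molecules by stoichiometry, builds the paired CDFs against the
#' space's (estimated) per-formula counts, and reports the KS statistic
#' and KL divergence.
#'
#' @param molecules list of molecules (`protomolecule` with elements, or
#'   `molecule_sample`), or a precomputed named count vector.
#' @param space_counts named numeric vector of per-formula space counts.
#' @param eps KL floor; default `1 / (10 * sum(space_counts))`.
#' @return list with `ks`, `kl`, `cdfs`, `n_db`, `eps_triggered`.
#' @export
compare_database <- function(molecules, space_counts, eps = NULL) {
  db_counts <- if (is.numeric(molecules)) molecules else {
    keys <- vapply(molecules, function(m) formula_string(stoichiometry_of(m)),
                   character(1))
    tab <- table(keys)
    stats::setNames(as.numeric(tab), names(tab))
  }
  if (sum(db_counts) == 0) stop("empty database")
  cdfs <- build_cdfs(db_counts, space_counts)
  if (is.null(eps)) eps <- 1 / (10 * sum(space_counts))
  kl <- kl_divergence(cdfs$space_p, cdfs$db_p, eps = eps)
  list(ks = ks_statistic(cdfs), kl = as.numeric(kl), cdfs = cdfs,
       n_db = sum(db_counts), eps_triggered = attr(kl, "eps_triggered"))
}

#' KS statistic as a function of the sampled fraction
#'
#' Draws random subsets of the database without replacement at each
#' fraction, compares each against the full space, and averages the KS
#' statistic over repetitions — the lower-bound-on-database-size
#' diagnostic.
#'
#' @param db_keys character vector of formula keys, one entry per database
#'   molecule (or a named count vector, expanded internally).
#' @param space_counts named numeric vector of space counts.
#' @param fractions numeric vector in (0, 1].
#' @param reps repetitions per fraction.
#' @param seed optional seed.
#' @return data.frame with columns `fraction`, `mean_ks`, `sd_ks`.
#' @export
subsample_curve <- function(db_keys, space_counts, fractions = c(0.01, 0.1, 1),
                            reps = 5L, seed = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(names(db_keys)) && is.numeric(db_keys))
    db_keys <- rep(names(db_keys), db_keys)
  n <- length(db_keys)
  res <- lapply(fractions, function(f) {
    m <- max(1L, round(f * n))
    ks <- vapply(seq_len(reps), function(r) {
      sub <- db_keys[sample.int(n, m)]
      tab <- table(sub)
      ks_statistic(build_cdfs(stats::setNames(as.numeric(tab), names(tab)),
                              space_counts))
    }, numeric(1))
    data.frame(fraction = f, mean_ks = mean(ks), sd_ks = stats::sd(ks))
  })
  do.call(rbind, res)
}
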