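#' Calibration constants of the size-estimation cascade
#'
#' Two fitted linear relations connect universe sizes and average path
#' lengths (natural logarithms throughout): `log|U(d)| = a7 * l_G + b7`
#' maps a measured average path length to a count, and
#' `l_G = a10 * log(G) + b10` maps the asymptotic degree-sequence count
#' `G` to a path length.  The shipped defaults are the database-scale fits
#' (285,656 degree sequences; 148,620 pure sequences above 20 atoms);
#' [refit_calibration()] re-estimates them from local exact data.
#'
#' @param a7,b7 slope/intercept of the count-from-path-length relation.
#' @param a10,b10 slope/intercept of the path-length-from-asymptotics
#'   relation.
#' @return list of class `calibration_constants`.
#' @export
calibration_constants <- function(a7 = 1.220, b7 = -0.7295,
                                  a10 = 0.7561, b10 = -14.40) {
  if (a7 <= 0 || a10 <= 0) stop("slopes must be positive")
  structure(list(a7 = a7, b7 = b7, a10 = a10, b10 = b10, log_base = "e"),
            class = "calibration_constants")
}

#' Average path length of a universe by pair sampling
#'
#' The universe U(d) has one vertex per protomolecule of `d` and edges
#' between graphs at minimal edit distance; for small-world networks its
#' average shortest-path length grows with the log of its size.  The mean
#' pairwise minimal edit distance is used as the path-length proxy and is
#' estimated by drawing independent protomolecule pairs from the MCMC
#' sampler.  Sampling is adaptive: it stops once the running mean's
#' standard error drops below `rel_se` of the mean, or after `n_pairs`
#' pairs.
#'
#' @param d a realizable `degree_seq`.
#' @param n_pairs maximum number of sampled pairs.
#' @param rel_se relative standard-error stopping rule (default 0.05).
#' @param min_pairs pairs drawn before the stopping rule applies.
#' @param seed optional seed.
#' @param budget per-heuristic budget for [edit_distance()].
#' @return list with `l_G` (the estimate; 0 by convention when every
#'   sampled pair coincides, as in a single-graph universe), `n_pairs`
#'   used, `se`, and the vector of sampled `distances`.
#' @export
average_path_length <- function(d, n_pairs = 200L, rel_se = 0.05,
                                min_pairs = 25L, seed = NULL, budget = 20L) {
  stopifnot(inherits(d, "degree_seq"))
  at <- ds_atoms(d)
  if (!is_realizable(at$degree)) stop("degree sequence is not realizable")
  cfg <- sampler_config(seed = seed)
  # one long chain; consecutive thinned samples are paired with a gap
  vals <- numeric(0)
  batch <- max(min_pairs, 10L)
  while (length(vals) < n_pairs) {
    m <- min(batch, n_pairs - length(vals))
    gs <- sample_graphs(d, 2L * m, cfg)
    cfg$seed <- NULL  # only seed the first batch
    for (k in seq_len(m)) {
      # pair chain-distant samples (k, m + k), not adjacent ones
      g1 <- gs[[k]]$protomolecule
      g2 <- gs[[m + k]]$protomolecule
      vals <- c(vals, edit_distance(g1, g2, budget = budget)$value)
    }
    if (length(vals) >= min_pairs) {
      mu <- mean(vals); se <- stats::sd(vals) / sqrt(length(vals))
      if (mu == 0 || se <= rel_se * mu) break
    }
  }
  mu <- mean(vals)
  list(l_G = mu, n_pairs = length(vals),
       se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else 0,
       distances = vals)
}

#' Universe size from an average path length
#'
#' Inverts the small-world relation: `|U| = exp(a7 * l_G + b7)`.
#' @param l_G average path length (unit bond edits).
#' @param cal a [calibration_constants()].
#' @return positive count estimate (real).
#' @export
count_from_path_length <- function(l_G, cal = calibration_constants()) {
  stopifnot(l_G >= 0)
  exp(cal$a7 * l_G + cal$b7)
}

#' Nonpure combinatorial multiplier N_P(d)
#'
#' Counts how many distinct protomolecules a nonpure degree sequence is
#' expected to generate per protomolecule of its pure counterpart, under
#' the assumption that atom sites of large molecules are asymmetric:
#' `N_P(d) = prod_v prod_i choose(sum_{j >= i} c_j, c_i)` with `c_i` the
#' atom counts of the elements of valence `v`.  Equals 1 for pure
#' sequences.
#' @param d a `degree_seq`.
#' @return positive number.
#' @examples
#' nonpure_multiplier(degree_seq(c(1, 1), c(1, 1)))  # 2
#' @export
nonpure_multiplier <- function(d) {
  stopifnot(inherits(d, "degree_seq"))
  out <- 1
  for (v in unique(d$valence)) {
    cc <- d$count[d$valence == v]
    for (i in seq_along(cc)) {
      out <- out * choose(sum(cc[i:length(cc)]), cc[i])
    }
  }
  out
}

#' Path length of a nonpure sequence from its pure counterpart
#'
#' `l_G(d) = (1 + log(N_P(d)) / sum_i d_i) * l_G(d_U)`, where the sum runs
#' over all atom degrees; no fitting is involved.
#' @param d a `degree_seq`.
#' @param l_G_pure average path length of the pure counterpart.
#' @return estimated path length of `d`.
#' @export
nonpure_path_length <- function(d, l_G_pure) {
  stopifnot(l_G_pure >= 0)
  np <- nonpure_multiplier(d)
  (1 + log(np) / attr(d, "degree_sum")) * l_G_pure
}

#' Falling-factorial degree sums M_r
#'
#' `M_r = sum_i k_i (k_i - 1) ... (k_i - r + 1)`; `M_1` is the degree sum.
#' @param k integer degree vector.
#' @param r order (>= 1).
#' @return nonnegative number.
#' @export
falling_factorial_sums <- function(k, r) {
  stopifnot(r >= 1)
  terms <- rep(1, length(k))
  for (s in 0:(r - 1L)) terms <- terms * (k - s)
  sum(pmax(terms, 0))
}

#' Asymptotic count of multigraphs with a pure degree sequence
#'
#' Evaluates the asymptotic enumeration formula for loop-free multigraphs
#' with unbounded edge multiplicities (all nonloop multiplicities allowed,
#' no loops): prefactor `M! / ((M/2)! 2^(M/2) k_1! ... k_n!)` times the
#' exponential of the correction terms
#' `-M2/(2M) + M2^2/(4M^2) + M2^4/(4M^5) - M2^2 M3/(2M^4) + M3^2/(6M^3)`,
#' dropping the `O(kmax^3/M)` remainder.  Computed in log space.
#'
#' @param k positive integer degree vector (one entry per atom).
#' @param log logical; return log(G) instead of G.
#' @return estimate of the number of (not necessarily connected)
#'   multigraphs, `G`.
#' @examples
#' asymptotic_count(c(1, 1))  # 1
#' @export
asymptotic_count <- function(k, log = FALSE) {
  k <- as.integer(k)
  M <- sum(k)
  if (M %% 2L != 0L) stop("degree sum must be even")
  M2 <- falling_factorial_sums(k, 2)
  M3 <- falling_factorial_sums(k, 3)
  lg <- lgamma(M + 1) - lgamma(M / 2 + 1) - (M / 2) * base::log(2) -
    sum(lgamma(k + 1))
  corr <- -M2 / (2 * M) + M2^2 / (4 * M^2) + M2^4 / (4 * M^5) -
    M2^2 * M3 / (2 * M^4) + M3^2 / (6 * M^3)
  lg <- lg + corr
  if (log) lg else exp(lg)
}

#' Saturation correction for monovalent-rich formulas
#'
#' The asymptotic relation keeps growing as monovalent atoms (hydrogens)
#' are added to a heavy-atom skeleton, while the true count must fall once
#' the double-bond equivalents approach zero; empirically the
#' overestimation factor is `t!`.  `t` counts the monovalent atoms in
#' excess of the minimum feasible for the sequence's heavy-atom profile.
#' @param G asymptotic count.
#' @param t number of excess monovalent atoms (>= 0).
#' @return corrected count `G / t!`.
#' @export
hydrogen_correction <- function(G, t) {
  stopifnot(t >= 0)
  G / factorial(t)
}

#' Excess monovalent atom count of a degree sequence
#'
#' The `t` entering [hydrogen_correction()]: the number of monovalent
#' atoms beyond the smallest monovalent count that still yields a
#' realizable connected multigraph with the same multiset of heavier
#' degrees.
#' @param d a `degree_seq`.
#' @return nonnegative integer.
#' @export
excess_monovalent <- function(d) {
  at <- ds_atoms(d)
  heavy <- at$degree[at$degree > 1L]
  n1 <- sum(at$degree == 1L)
  if (n1 == 0L) return(0L)
  if (length(heavy) == 0L) return(max(0L, n1 - 2L))  # H2 is the minimum
  m <- n1 %% 2L
  if ((sum(heavy) + m) %% 2L != 0L) m <- m + 1L
  while (m <= n1 && !is_realizable(c(heavy, rep(1L, m)))) m <- m + 2L
  if (m > n1) return(0L)
  n1 - m
}

#' Counts database
#'
#' An in-memory, append-only table of count records keyed by the canonical
#' degree-sequence key; persisted as a plain CSV with a JSON sidecar for
#' calibration constants (see [write_counts_db()]).
#' @param records optional data.frame with columns `key`, `tier`, `count`,
#'   `l_G`, `n_pairs`, `seed`.
#' @return object of class `counts_db`.
#' @export
counts_db <- function(records = NULL) {
  if (is.null(records)) {
    records <- data.frame(key = character(0), tier = character(0),
                          count = numeric(0), l_G = numeric(0),
                          n_pairs = integer(0), seed = integer(0),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("key", "tier", "count") %in% names(records)))
  if (anyDuplicated(records$key)) stop("duplicate degree-sequence keys")
  structure(list(records = records), class = "counts_db")
}

#' @export
print.counts_db <- function(x, ...) {
  cat("Counts database:", nrow(x$records), "records\n")
  if (nrow(x$records) > 0L) print(table(x$records$tier))
  invisible(x)
}

#' Append a record to a counts database (dedup on key)
#' @param db a [counts_db()].
#' @param key canonical degree-sequence key ([ds_key()]).
#' @param tier one of `"exact"`, `"base"`, `"pure"`, `"asymptotic"`.
#' @param count the count (integral for the exact tier).
#' @param l_G,n_pairs,seed provenance fields (optional).
#' @return the updated `counts_db`; an existing record for `key` wins and
#'   the call is a no-op.
#' @export
db_append <- function(db, key, tier, count, l_G = NA_real_,
                      n_pairs = NA_integer_, seed = NA_integer_) {
  stopifnot(inherits(db, "counts_db"))
  if (key %in% db$records$key) return(db)
  db$records <- rbind(db$records, data.frame(
    key = key, tier = tier, count = count, l_G = l_G,
    n_pairs = n_pairs, seed = seed, stringsAsFactors = FALSE))
  db
}

db_lookup <- function(db, key) {
  hit <- which(db$records$key == key)
  if (length(hit) == 0L) NULL else db$records[hit[1L], ]
}

#' Estimate the protomolecule count of a degree sequence
#'
#' Dispatches across the estimation tiers, most accurate first:
#' \describe{
#'   \item{exact}{within the enumeration cap, or stored: exhaustive count.}
#'   \item{base}{a stored measured path length for `d` itself, mapped
#'     through the calibrated small-world relation.}
#'   \item{pure}{a stored or freshly measured path length of the pure
#'     counterpart, scaled by the nonpure multiplier, then mapped.}
#'   \item{asymptotic}{the asymptotic degree-sequence count with the
#'     saturation (`t!`) correction, mapped to a path length by the second
#'     calibration, then treated as the pure tier.}
#' }
#'
#' @param d a `degree_seq`.
#' @param db a [counts_db()] consulted for stored records (optional).
#' @param cal [calibration_constants()].
#' @param cap exact-enumeration atom cap.
#' @param tier force a tier (`"auto"` default).
#' @param measure when TRUE (default) the pure tier may run the sampler to
#'   measure a missing pure path length; with FALSE it falls through to
#'   the asymptotic tier.
#' @param seed seed for any sampling performed.
#' @return a `count_record`: list with `key`, `tier`, `count`, `l_G`,
#'   `n_pairs`, `seed`.
#' @export
estimate_count <- function(d, db = NULL, cal = calibration_constants(),
                           cap = 10L, tier = c("auto", "exact", "base",
                                               "pure", "asymptotic"),
                           measure = TRUE, seed = NULL) {
  stopifnot(inherits(d, "degree_seq"))
  tier <- match.arg(tier)
  key <- ds_key(d)
  at <- ds_atoms(d)
  if (!is_realizable(at$degree))
    return(count_record(key, "exact", 0))
  if (is.null(db)) db <- counts_db()
  rec <- db_lookup(db, key)

  if (tier %in% c("auto", "exact")) {
    if (!is.null(rec) && rec$tier == "exact")
      return(count_record(key, "exact", rec$count))
    if (length(at$degree) <= cap)
      return(count_record(key, "exact", count_exact(d, cap = cap)))
    if (tier == "exact") stop("exact tier unavailable above the cap")
  }
  if (tier %in% c("auto", "base")) {
    if (!is.null(rec) && !is.na(rec$l_G) && rec$tier %in% c("base", "exact"))
      return(count_record(key, "base",
                          count_from_path_length(rec$l_G, cal),
                          l_G = rec$l_G, n_pairs = rec$n_pairs))
    if (tier == "base") stop("no stored path length for this sequence")
  }
  dU <- pure_counterpart(d)
  if (tier %in% c("auto", "pure")) {
    recU <- db_lookup(db, ds_key(dU))
    l_pure <- if (!is.null(recU) && !is.na(recU$l_G)) recU$l_G
              else if (measure || tier == "pure")
                average_path_length(dU, seed = seed)$l_G
              else NA_real_
    if (!is.na(l_pure)) {
      lg <- nonpure_path_length(d, l_pure)
      return(count_record(key, "pure", count_from_path_length(lg, cal),
                          l_G = lg, seed = seed))
    }
  }
  # asymptotic tier
  kdeg <- ds_atoms(dU)$degree
  lG_asym <- asymptotic_count(kdeg, log = TRUE)
  lG_asym <- lG_asym - lgamma(excess_monovalent(d) + 1)  # t! correction
  l_pure <- max(0, cal$a10 * lG_asym + cal$b10)
  lg <- nonpure_path_length(d, l_pure)
  count_record(key, "asymptotic", count_from_path_length(lg, cal), l_G = lg)
}

count_record <- function(key, tier, count, l_G = NA_real_,
                         n_pairs = NA_integer_, seed = NA_integer_) {
  structure(list(key = key, tier = tier, count = count, l_G = l_G,
                 n_pairs = n_pairs,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "count_record")
}

#' @export
print.count_record <- function(x, ...) {
  cat(sprintf("Count record [%s] tier=%s count=%.6g", x$key, x$tier, x$count))
  if (!is.na(x$l_G)) cat(sprintf(" l_G=%.4g", x$l_G))
  cat("\n")
  invisible(x)
}

#' Refit the calibration constants from exact data
#'
#' Least-squares fits of `log(count)` on `l_G` (count-from-path-length
#' relation) and, when asymptotic counts are supplied, of `l_G` on
#' `log(G)` (path-length-from-asymptotics relation).
#'
#' @param records data.frame with columns `l_G`, `count`, and optionally
#'   `G_asym`; at least 10 rows spanning two orders of magnitude in count.
#' @param strict enforce the row/span requirement (default TRUE).
#' @return a [calibration_constants()] with attributes `r2_7` (and `r2_10`
#'   when fitted).
#' @export
refit_calibration <- function(records, strict = TRUE) {
  stopifnot(is.data.frame(records), all(c("l_G", "count") %in% names(records)))
  records <- records[records$count > 0, , drop = FALSE]
  if (strict) {
    if (nrow(records) < 10L) stop("need at least 10 records")
    if (diff(range(log10(records$count))) < 2)
      stop("records must span at least two orders of magnitude in count")
  }
  if (stats::sd(records$l_G) == 0) stop("degenerate (constant) predictor")
  f7 <- stats::lm(log(count) ~ l_G, data = records)
  cal <- calibration_constants(a7 = unname(stats::coef(f7)[2L]),
                               b7 = unname(stats::coef(f7)[1L]))
  attr(cal, "r2_7") <- summary(f7)$r.squared
  if ("G_asym" %in% names(records) && any(is.finite(log(records$G_asym)))) {
    ok <- is.finite(log(records$G_asym))
    f10 <- stats::lm(l_G ~ log(G_asym), data = records[ok, , drop = FALSE])
    cal$a10 <- unname(stats::coef(f10)[2L])
    cal$b10 <- unname(stats::coef(f10)[1L])
    attr(cal, "r2_10") <- summary(f10)$r.squared
  }
  cal
}
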