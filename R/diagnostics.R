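#' Sorted-frequency uniformity curve with a multinomial envelope
#'
#' The primary sampler diagnostic: per-class sampling frequencies,
#' normalized so that perfectly uniform sampling has expectation 1, sorted
#' ascending — uniform draws produce a characteristic s-shaped curve that
#' flattens as the sample size grows.  The expected band is obtained by
#' simulating uniform multinomial draws at the same sample size and taking
#' pointwise order-statistic quantiles.
#'
#' @param sample_keys character vector of canonical keys of the sampled
#'   graphs ([proto_key()]).
#' @param universe_keys character vector of the canonical keys of the full
#'   enumerated universe; sample keys outside it are a sampler bug and
#'   raise an error.
#' @param envelope_reps Monte-Carlo repetitions for the envelope.
#' @param level joint coverage level of the envelope (default 0.99): the
#'   band is calibrated by curve-wise extreme ranks so that a whole
#'   uniform curve stays inside with this probability, not merely each
#'   point separately.
#' @param seed optional seed for the envelope simulation.
#' @return object of class `uniformity_report`: list with `n`, `n_classes`,
#'   `sorted_freq` (normalized, ascending), `envelope` (data.frame `lower`,
#'   `upper`), `chisq` (statistic, df, p_value), `inside_envelope`.
#' @export
sorted_frequency_curve <- function(sample_keys, universe_keys,
                                   envelope_reps = 1000L, level = 0.99,
                                   seed = NULL) {
  stopifnot(length(sample_keys) > 0L, length(universe_keys) > 0L)
  if (anyDuplicated(universe_keys)) stop("universe keys must be unique")
  bad <- setdiff(unique(sample_keys), universe_keys)
  if (length(bad) > 0L)
    stop("sampled keys outside the enumerated universe (sampler bug): ",
         length(bad), " distinct keys")
  k <- length(universe_keys)
  n <- length(sample_keys)
  counts <- table(factor(sample_keys, levels = universe_keys))
  freq <- sort(as.numeric(counts) / (n / k))
  chi <- stats::chisq.test(as.numeric(counts), p = rep(1 / k, k))
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(0, envelope_reps, k)
  for (r in seq_len(envelope_reps)) {
    sims[r, ] <- sort(as.numeric(stats::rmultinom(1L, n, rep(1 / k, k))) / (n / k))
  }
  # global rank envelope: score each simulated curve by its most extreme
  # pointwise rank, drop the (1 - level) most extreme curves, and take the
  # pointwise min/max of the rest — the band then has joint coverage
  # ~level for a uniform sampler
  lo_rank <- apply(sims, 2L, rank, ties.method = "max")
  hi_rank <- envelope_reps + 1L - apply(sims, 2L, rank, ties.method = "min")
  depth <- pmin(apply(lo_rank, 1L, min), apply(hi_rank, 1L, min))
  keep <- depth > stats::quantile(depth, 1 - level, type = 1L)
  if (sum(keep) < 2L) keep <- rep(TRUE, envelope_reps)
  # the band always contains the ideal flat curve: being closer to perfect
  # uniformity than typical multinomial noise is never evidence of bias
  env <- data.frame(
    lower = pmin(apply(sims[keep, , drop = FALSE], 2L, min), 1),
    upper = pmax(apply(sims[keep, , drop = FALSE], 2L, max), 1))
  structure(list(
    n = n, n_classes = k, sorted_freq = freq, envelope = env,
    chisq = list(statistic = unname(chi$statistic),
                 df = unname(chi$parameter),
                 p_value = unname(chi$p.value)),
    inside_envelope = all(freq >= env$lower & freq <= env$upper)),
    class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf(paste0("Uniformity report: %d samples over %d classes; ",
                     "chi-square p = %.3g; %s the %s envelope\n"),
              x$n, x$n_classes, x$chisq$p_value,
              if (x$inside_envelope) "inside" else "OUTSIDE",
              "simulated uniform"))
  invisible(x)
}

#' Per-stoichiometry normalized sampling frequencies
#'
#' Frequency of each stoichiometry divided by its expected share (its
#' class count over the total): uniform sampling over the joint space
#' gives values near 1 for every stoichiometry.
#'
#' @param sample_formulas character vector of formula keys, one per sample.
#' @param space_counts named numeric vector of per-formula class counts.
#' @return data.frame with columns `formula`, `n`, `normalized` (observed
#'   over expected share) and `z` (binomial standard score).
#' @export
stoichiometry_frequency <- function(sample_formulas, space_counts) {
  stopifnot(length(sample_formulas) > 0L)
  bad <- setdiff(unique(sample_formulas), names(space_counts))
  if (length(bad) > 0L)
    stop("sampled formulas missing from space_counts: ",
         paste(bad, collapse = ", "))
  n <- length(sample_formulas)
  p <- space_counts / sum(space_counts)
  obs <- table(factor(sample_formulas, levels = names(space_counts)))
  obs <- as.numeric(obs)
  norm <- (obs / n) / as.numeric(p)
  z <- (obs - n * p) / sqrt(n * p * (1 - p))
  data.frame(formula = names(space_counts), n = obs,
             normalized = norm, z = as.numeric(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-square uniformity test of sampled classes
#'
#' Convenience wrapper: observed class counts against the uniform law over
#' an enumerated universe.
#' @inheritParams sorted_frequency_curve
#' @return htest object from [stats::chisq.test()].
#' @export
uniformity_chisq <- function(sample_keys, universe_keys) {
  counts <- table(factor(sample_keys, levels = universe_keys))
  stats::chisq.test(as.numeric(counts),
                    p = rep(1 / length(universe_keys), length(universe_keys)))
}
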