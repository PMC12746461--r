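#' Transport cost of a vertex permutation between two adjacency matrices
#'
#' The ground cost used throughout the edit-distance machinery: half the L1
#' difference between the permuted bond-order matrix of the first graph and
#' the matrix of the second.  Each unit is one elementary bond edit (remove
#' or add one bond-order unit), so the minimum over permutations is the
#' graph edit distance within a degree sequence.
#'
#' @param A,B symmetric bond-multiplicity matrices of equal order.
#' @param perm integer permutation mapping vertices of `A` onto `B`; must
#'   only interchange vertices of the same atom-type slot.
#' @param type integer vector of slot ids (checked against `perm`); omit to
#'   skip the guard.
#' @return nonnegative number of unit bond edits.
#' @export
permuted_cost <- function(A, B, perm, type = NULL) {
  stopifnot(nrow(A) == ncol(A), all(dim(A) == dim(B)),
            length(perm) == nrow(A))
  if (!is.null(type) && !all(type[perm] == type))
    stop("permutation mixes vertices of different atom-type slots")
  sum(abs(A[perm, perm, drop = FALSE] - B)) / 2
}

# all permutations of 1..n (deterministic order), n small
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perms_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      row <- integer(n); row[pos] <- n
      row[-pos] <- sub[s, ]
      out[r, ] <- row
    }
  }
  out
}

# number of slot-respecting permutations
n_type_perms <- function(type) prod(factorial(table(type)))

# class index list
type_classes <- function(type) split(seq_along(type), type)

#' Exact minimal edit distance between two protomolecules
#'
#' Brute force over all slot-respecting vertex permutations; refuses when
#' their number reaches `threshold` (default 100) — use
#' [edit_distance_heuristic()] beyond that.
#'
#' @param g1,g2 `protomolecule`s of the same labeled degree sequence.
#' @param threshold refusal bound on the permutation count.
#' @return a `distance_estimate`: list with `value`, `exact = TRUE`,
#'   `method = "exhaustive"`.
#' @export
edit_distance_exact <- function(g1, g2, threshold = 100) {
  check_same_ds(g1, g2)
  np <- n_type_perms(g1$type)
  if (np >= threshold)
    stop(sprintf(paste0("%d slot-respecting permutations (>= %d); ",
                        "use edit_distance_heuristic()"), np, threshold))
  A <- adjacency_multiplicity(g1); B <- adjacency_multiplicity(g2)
  cls <- type_classes(g1$type)
  per_class <- lapply(cls, function(ix) {
    p <- perms_of(length(ix))
    matrix(ix[p], nrow(p), ncol(p))
  })
  best <- Inf
  grid <- do.call(expand.grid, lapply(per_class, function(m) seq_len(nrow(m))))
  n <- length(g1$type)
  for (r in seq_len(nrow(grid))) {
    perm <- integer(n)
    for (k in seq_along(cls)) perm[cls[[k]]] <- per_class[[k]][grid[r, k], ]
    cost <- permuted_cost(A, B, perm)
    if (cost < best) best <- cost
    if (best == 0) break
  }
  structure(list(value = best, exact = TRUE, method = "exhaustive"),
            class = "distance_estimate")
}

check_same_ds <- function(g1, g2) {
  if (!identical(ds_key(g1$d), ds_key(g2$d)))
    stop("protomolecules have different labeled degree sequences")
}

#' @export
print.distance_estimate <- function(x, ...) {
  cat("Edit distance", x$value, if (x$exact) "(exact)" else
      sprintf("(heuristic upper bound, %s)", x$method), "\n")
  invisible(x)
}

#' Heuristic minimal edit distance between two protomolecules
#'
#' Minimum of six search heuristics over slot-respecting permutations:
#' (i) random shuffling, (ii) pairwise-switch descent from random starts,
#' (iii) 2-opt over all slot-respecting transpositions (quadratic
#' assignment flavor), (iv) per-element-class exhaustive/2-opt optimization
#' freezing all other classes, single scan, (v) the same with repeated
#' scans to convergence, and (vi) a depth-first branch-and-bound assignment
#' search.  The result is an upper bound on the true minimum (exact when
#' the search happens to hit it).  The pair is canonically ordered before
#' searching, so the call is symmetric; with a seed it is deterministic.
#'
#' @param g1,g2 `protomolecule`s of the same labeled degree sequence.
#' @param budget restarts/iterations per heuristic (paper-scale default 50).
#' @param seed optional integer seed for reproducibility.
#' @return a `distance_estimate` with `exact = FALSE` and the winning
#'   heuristic's tag (cheapest wins ties: order as listed above).
#' @export
edit_distance_heuristic <- function(g1, g2, budget = 50L, seed = NULL) {
  check_same_ds(g1, g2)
  if (!is.null(seed)) set.seed(seed)
  # symmetrize: order pair by canonical key
  if (proto_key(g1) > proto_key(g2)) { tmp <- g1; g1 <- g2; g2 <- tmp }
  A <- adjacency_multiplicity(g1); B <- adjacency_multiplicity(g2)
  type <- g1$type
  cls <- type_classes(type)
  n <- length(type)
  cost_of <- function(perm) sum(abs(A[perm, perm] - B)) / 2
  rand_perm <- function() {
    p <- seq_len(n)
    for (ix in cls) if (length(ix) > 1L) p[ix] <- ix[sample.int(length(ix))]
    p
  }
  # candidate transpositions: within-class pairs
  swaps <- do.call(rbind, lapply(cls, function(ix) {
    if (length(ix) < 2L) return(NULL)
    t(utils::combn(ix, 2L))
  }))
  best <- cost_of(seq_len(n)); best_m <- "identity"
  note <- function(v, m) if (v < best) { best <<- v; best_m <<- m }

  # (i) random shuffling
  for (k in seq_len(budget)) note(cost_of(rand_perm()), "random")
  if (best == 0) return(heur_result(0, best_m))

  descent <- function(p, first_improvement) {
    v <- cost_of(p)
    repeat {
      ord <- sample.int(nrow(swaps))
      bestv <- v; bestp <- NULL
      for (r in ord) {
        q <- p; q[swaps[r, ]] <- q[rev(swaps[r, ])]
        cv <- cost_of(q)
        if (cv < bestv) {
          bestv <- cv; bestp <- q
          if (first_improvement) break
        }
      }
      if (is.null(bestp)) break
      p <- bestp; v <- bestv
      if (v == 0) break
    }
    v
  }

  # (ii) pairwise-switch first-improvement descent from random starts
  if (!is.null(swaps)) {
    for (k in seq_len(max(1L, budget %/% 5L)))
      note(descent(rand_perm(), TRUE), "switch-descent")
    if (best == 0) return(heur_result(0, best_m))

    # (iii) 2-opt (best-improvement) over all slot-respecting transpositions
    for (k in seq_len(max(1L, budget %/% 5L)))
      note(descent(rand_perm(), FALSE), "qap-2opt")
    if (best == 0) return(heur_result(0, best_m))
  }

  # (iv)/(v): optimize one element class at a time, others frozen
  class_scan <- function(p, nscan) {
    for (s in seq_len(nscan)) {
      v0 <- cost_of(p)
      for (ix in cls) {
        if (length(ix) < 2L) next
        if (factorial(length(ix)) <= 720) {
          pm <- perms_of(length(ix))
          vals <- apply(pm, 1L, function(pp) {
            q <- p; q[ix] <- p[ix][pp]; cost_of(q)
          })
          w <- which.min(vals)
          p[ix] <- p[ix][pm[w, ]]
        } else {
          sw <- t(utils::combn(ix, 2L))
          repeat {
            v <- cost_of(p); done <- TRUE
            for (r in seq_len(nrow(sw))) {
              q <- p; q[sw[r, ]] <- q[rev(sw[r, ])]
              if (cost_of(q) < v) { p <- q; v <- cost_of(p); done <- FALSE }
            }
            if (done) break
          }
        }
      }
      if (cost_of(p) >= v0 && s > 1L) break
    }
    cost_of(p)
  }
  for (k in seq_len(max(1L, budget %/% 10L))) {
    note(class_scan(rand_perm(), 1L), "class-freeze-1scan")
    note(class_scan(rand_perm(), 5L), "class-freeze-multiscan")
    if (best == 0) return(heur_result(0, best_m))
  }

  # (vi) depth-first branch-and-bound over slot-respecting assignments
  note(dfs_assignment(A, B, type, node_budget = 200L * budget), "dfs")
  heur_result(best, best_m)
}

heur_result <- function(v, m) {
  structure(list(value = v, exact = FALSE, method = m),
            class = "distance_estimate")
}

# branch and bound: assign g1 vertices (in order) to unused g2 vertices of
# the same type; bound = cost over the already-assigned principal submatrix
dfs_assignment <- function(A, B, type, node_budget = 10000L) {
  n <- length(type)
  best <- sum(abs(A - B)) / 2
  nodes <- 0L
  assign_to <- integer(n)  # g1 vertex i -> g2 vertex
  used <- logical(n)
  rec <- function(i, partial) {
    if (nodes > node_budget || partial >= best) return()
    if (i > n) { best <<- partial; return() }
    for (j in which(!used & type == type[i])) {
      nodes <<- nodes + 1L
      add <- 0
      if (i > 1L) {
        pv <- seq_len(i - 1L)
        add <- sum(abs(A[pv, i] - B[assign_to[pv], j]))
      }
      assign_to[i] <<- j; used[j] <<- TRUE
      rec(i + 1L, partial + add)
      used[j] <<- FALSE
    }
  }
  rec(1L, 0)
  best
}

#' Dispatching edit distance
#'
#' Uses the exhaustive search when the slot-respecting permutation count is
#' below `threshold`, the heuristic suite otherwise.
#' @inheritParams edit_distance_heuristic
#' @param threshold exactness bound on the permutation count (default 100).
#' @return a `distance_estimate`.
#' @export
edit_distance <- function(g1, g2, threshold = 100, budget = 50L, seed = NULL) {
  if (n_type_perms(g1$type) < threshold) edit_distance_exact(g1, g2, threshold)
  else edit_distance_heuristic(g1, g2, budget = budget, seed = seed)
}
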