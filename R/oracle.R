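# Brute-force reference implementations for small graphs.  These exist to
# test the search-based code, so they share nothing with it beyond the
# adjacency encoding: labels come from exhaustive enumeration of
# permutations, not from individualization and refinement.

#' @keywords internal
all_permutations <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

oracle_budget_check <- function(g, max_vertices) {
  if (n_vertices(g) > max_vertices) {
    stop("graph exceeds the oracle budget of ", max_vertices, " vertices",
         call. = FALSE)
  }
}

# all vertex orderings in which the color classes (in the lexicographic
# class order used by initial_partition) stay contiguous
color_orderings <- function(g) {
  classes <- initial_partition(g)
  per_class <- lapply(classes, function(cell) {
    idx <- match(cell, g$vertices)
    lapply(all_permutations(length(idx)), function(p) idx[p])
  })
  acc <- list(integer(0))
  for (perms in per_class) {
    out <- vector("list", length(acc) * length(perms))
    k <- 0L
    for (a in acc) for (p in perms) {
      k <- k + 1L
      out[[k]] <- c(a, p)
    }
    acc <- out
  }
  acc
}

#' Brute-force canonical label
#'
#' The minimum row-major serialization of the adjacency matrix over every
#' vertex ordering that keeps color classes contiguous and in class order.
#' Exact, and independent of the search-based labeler, but exponential:
#' inputs above the vertex budget are refused.
#'
#' @param g A [typed_graph()].
#' @param max_vertices Oracle budget (default 8).
#' @return A label string (same `colors|matrix` format as
#'   [hnauty_canonical()]).
#' @export
brute_canonical <- function(g, max_vertices = 8L) {
  stopifnot(inherits(g, "typed_graph"))
  oracle_budget_check(g, max_vertices)
  a <- plain_adjacency(g)
  width <- nchar(as.character(bitwShiftL(1L, g$m) - 1L))
  best <- NULL
  best_perm <- NULL
  for (p in color_orderings(g)) {
    s <- leaf_string(a, p, width)
    if (is.null(best) || s < best) {
      best <- s
      best_perm <- p
    }
  }
  m <- a[best_perm, best_perm, drop = FALSE]
  paste0(color_class_signature(g, initial_partition(g)), "|",
         paste(as.integer(t(m)), collapse = " "))
}

#' Brute-force automorphism enumeration
#'
#' Every permutation of the vertices preserving colors, attributes and each
#' typed edge set, found by checking all color-class-preserving
#' permutations.  The result always contains the identity and is closed
#' under composition and inversion.
#'
#' @inheritParams brute_canonical
#' @return A list of named character vectors (vertex to image).
#' @export
brute_automorphisms <- function(g, max_vertices = 8L) {
  stopifnot(inherits(g, "typed_graph"))
  oracle_budget_check(g, max_vertices)
  a <- plain_adjacency(g)
  classes <- initial_partition(g)
  # class-preserving bijections: permute within each color class only
  per_class <- lapply(classes, function(cell) {
    idx <- match(cell, g$vertices)
    lapply(all_permutations(length(idx)), function(p) {
      cbind(idx, idx[p])
    })
  })
  combos <- Reduce(function(acc, maps) {
    out <- vector("list", length(acc) * length(maps))
    k <- 0L
    for (x in acc) for (y in maps) {
      k <- k + 1L
      out[[k]] <- rbind(x, y)
    }
    out
  }, per_class, init = list(matrix(integer(0), 0L, 2L)))
  keep <- list()
  n <- n_vertices(g)
  for (mp in combos) {
    gamma <- integer(n)
    gamma[mp[, 1L]] <- mp[, 2L]
    if (identical(a[gamma, gamma, drop = FALSE], a)) {
      keep[[length(keep) + 1L]] <-
        stats::setNames(g$vertices[gamma], g$vertices)
    }
  }
  keep
}
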