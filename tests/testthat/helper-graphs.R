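# Shared generators and tiny independent oracles for the test suite.
# Everything here is deterministic given its seed arguments.

# single-edge-type undirected random graph, all vertices one color
rand_single <- function(n, p = 0.4, seed = 1L) {
  ids <- paste0("v", seq_len(n))
  set.seed(seed)
  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(0L, 0L, 2L)
  keep <- stats::runif(nrow(pairs)) < p
  edges <- if (any(keep)) {
    data.frame(src = ids[pairs[keep, 1L]], dst = ids[pairs[keep, 2L]],
               type = 0L)
  } else NULL
  typed_graph(ids, edges, "undirected",
              labels = stats::setNames(rep("v", n), ids))
}

# every undirected single-type graph on n labeled one-color vertices
all_single_graphs <- function(n) {
  ids <- paste0("v", seq_len(n))
  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(0L, 0L, 2L)
  np <- nrow(pairs)
  lapply(seq_len(2^np) - 1L, function(mask) {
    keep <- bitwAnd(mask, bitwShiftL(1L, seq_len(np) - 1L)) > 0L
    edges <- if (any(keep)) {
      data.frame(src = ids[pairs[keep, 1L]], dst = ids[pairs[keep, 2L]],
                 type = 0L)
    } else NULL
    typed_graph(ids, edges, "undirected",
                labels = stats::setNames(rep("v", n), ids))
  })
}

# uniform random relabeling of a graph (names -> images), seeded
rand_perm <- function(g, seed = 1L) {
  set.seed(seed)
  stats::setNames(sample(g$vertices), g$vertices)
}

shuffled_copy <- function(g, seed = 1L) {
  set.seed(seed)
  ord <- sample(g$vertices)
  permute_graph(g, rand_perm(g, seed + 1L), new_order = ord)
}

# bare list of cells, attributes stripped, for identical() comparisons
cells <- function(p) {
  x <- unclass(p)
  attributes(x) <- NULL
  x
}

# every ordering of a small vertex vector
all_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# all unordered partitions of a vertex vector (Bell-number many)
all_set_partitions <- function(v) {
  if (length(v) == 0L) return(list(list()))
  rest <- all_set_partitions(v[-1L])
  out <- list()
  for (p in rest) {
    out[[length(out) + 1L]] <- c(list(v[1L]), p)
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(v[1L], q[[i]])
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

# all ordered partitions (every ordering of every set partition)
all_ordered_partitions <- function(v) {
  perms <- function(k) {
    if (k <= 1L) return(list(seq_len(k)))
    out <- list()
    for (p in perms(k - 1L)) {
      for (i in seq_len(k)) {
        out[[length(out) + 1L]] <- append(p, k, after = i - 1L)
      }
    }
    out
  }
  out <- list()
  for (p in all_set_partitions(v)) {
    for (o in perms(length(p))) {
      out[[length(out) + 1L]] <- ordered_partition(p[o], v)
    }
  }
  out
}

# independent single-type equitability check, straight from the defining
# degree condition (no shared code with the package's key machinery)
naive_equitable <- function(g, cells) {
  adj <- lapply(g$vertices, function(v) {
    e <- g$edges
    c(e$dst[e$src == v], e$src[e$dst == v])
  })
  names(adj) <- g$vertices
  for (cell in cells) {
    for (target in cells) {
      d <- vapply(cell, function(x) sum(adj[[x]] %in% target), integer(1))
      if (length(unique(d)) > 1L) return(FALSE)
    }
  }
  TRUE
}

# coarsest equitable refinement as an unordered partition, by naive
# fixpoint splitting (single undirected type only)
naive_refine_unordered <- function(g, cells) {
  repeat {
    new <- list()
    for (cell in cells) {
      key <- vapply(cell, function(x) {
        e <- g$edges
        nb <- c(e$dst[e$src == x], e$src[e$dst == x])
        paste(vapply(cells, function(tc) sum(nb %in% tc), integer(1)),
              collapse = ",")
      }, character(1))
      for (k in unique(key)) new[[length(new) + 1L]] <- cell[key == k]
    }
    if (length(new) == length(cells)) return(new)
    cells <- new
  }
}

unordered_cells_equal <- function(a, b) {
  norm <- function(cells) {
    sort(vapply(cells, function(x) paste(sort(x), collapse = ","),
                character(1)))
  }
  identical(norm(a), norm(b))
}

# is P a refinement of Q, ignoring cell order
unordered_refines <- function(p, q) {
  all(vapply(p, function(cell) {
    any(vapply(q, function(big) all(cell %in% big), logical(1)))
  }, logical(1)))
}

expect_same_graph <- function(a, b) {
  expect_true(graphs_identical(a, b))
}
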