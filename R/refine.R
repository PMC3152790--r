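# Generalized equitable partition refinement.
#
# A partition is generalized equitable when, restricted to any single edge
# type (and, for directed types, to either arc direction), any two vertices
# in the same cell have the same number of edges into every cell.  Every
# partition has a unique coarsest generalized equitable refinement (as an
# unordered partition); the cell ORDER of the refinement is fixed by the
# fragment-ordering convention documented in `coarsest_equitable_refinement`.

# One 0/1 "channel" matrix per (edge type, direction): for undirected types a
# single symmetric matrix, for directed types the out-arc matrix followed by
# its transpose.  All degree bookkeeping is matrix arithmetic on these.
channel_matrices <- function(g, a = NULL) {
  if (is.null(a)) a <- encode_adjacency(g)
  a <- unclass(a)
  chans <- list()
  for (e in seq_len(g$m) - 1L) {
    bit <- matrix((bitwAnd(as.integer(a), bitwShiftL(1L, e)) > 0L) * 1L,
                  nrow = nrow(a), ncol = ncol(a))
    chans[[length(chans) + 1L]] <- bit
    if (g$directedness[e + 1L] == "directed") {
      chans[[length(chans) + 1L]] <- t(bit)
    }
  }
  chans
}

# n x (nchan * k) matrix of per-cell edge counts, channel-major blocks.
cell_degree_keys <- function(chans, cells, n) {
  k <- length(cells)
  C <- matrix(0, n, k)
  C[cbind(unlist(cells), rep.int(seq_len(k), lengths(cells)))] <- 1
  do.call(cbind, lapply(chans, function(M) M %*% C))
}

# Fragment-ordering comparator, as two radix-sortable strings per key row:
# primary = entries sorted descending (compared descending), secondary = the
# raw key vector (compared ascending).  This is the one convention that
# reproduces both the worked coarsest-refinement cell orders and the worked
# search-tree leaves; see the methods vignette.
frag_sort_strings <- function(keyrows) {
  w <- max(3L, nchar(as.character(max(keyrows, 1))))
  fmt <- function(m) {
    s <- matrix(formatC(m, width = w, flag = "0"),
                nrow = nrow(m), ncol = ncol(m))
    do.call(paste0, lapply(seq_len(ncol(s)), function(j) s[, j]))
  }
  sorted <- keyrows
  for (i in seq_len(nrow(keyrows))) {
    sorted[i, ] <- sort(keyrows[i, ], decreasing = TRUE)
  }
  list(primary = fmt(sorted), secondary = fmt(keyrows))
}

# Core refinement on integer-index cells.  Repeatedly splits every cell by
# its full degree key against the current partition until a fixpoint; the
# simultaneous full-pass schedule plus the key-based fragment order makes the
# result deterministic and equivariant under vertex relabeling.
refine_cells <- function(chans, cells, n) {
  repeat {
    K <- cell_degree_keys(chans, cells, n)
    out <- vector("list", 0L)
    changed <- FALSE
    for (cell in cells) {
      if (length(cell) == 1L) {
        out[[length(out) + 1L]] <- cell
        next
      }
      rows <- K[cell, , drop = FALSE]
      id <- do.call(paste, c(as.data.frame(rows), sep = ","))
      if (length(unique(id)) == 1L) {
        out[[length(out) + 1L]] <- cell
        next
      }
      changed <- TRUE
      first <- !duplicated(id)
      ukeys <- rows[first, , drop = FALSE]
      uid <- id[first]
      ss <- frag_sort_strings(ukeys)
      ord <- order(ss$primary, ss$secondary,
                   decreasing = c(TRUE, FALSE), method = "radix")
      for (o in ord) {
        out[[length(out) + 1L]] <- cell[id == uid[o]]
      }
    }
    cells <- out
    if (!changed) return(cells)
  }
}

cells_to_idx <- function(p, vertices) {
  pos <- stats::setNames(seq_along(vertices), vertices)
  lapply(p, function(cell) unname(pos[cell]))
}

idx_to_partition <- function(cells, vertices) {
  ordered_partition(lapply(cells, function(i) vertices[i]), vertices)
}

#' Is a partition generalized equitable?
#'
#' Checks the per-edge-type equitability condition: for every edge type (and
#' arc direction), any two vertices sharing a cell have equal edge counts
#' into every cell.  A discrete partition is always equitable; the trivial
#' partition is equitable exactly for graphs that are regular in every
#' channel.
#'
#' @param g A [typed_graph()].
#' @param p An [ordered_partition()] of `g`'s vertices.
#' @return `TRUE` or `FALSE`.
#' @export
is_generalized_equitable <- function(g, p) {
  stopifnot(inherits(g, "typed_graph"), inherits(p, "ordered_partition"))
  check_partition_of(g, p)
  chans <- channel_matrices(g)
  cells <- cells_to_idx(p, g$vertices)
  K <- cell_degree_keys(chans, cells, n_vertices(g))
  for (cell in cells) {
    if (length(cell) > 1L) {
      rows <- K[cell, , drop = FALSE]
      if (any(rows[-1L, , drop = FALSE] !=
              rows[rep(1L, length(cell) - 1L), , drop = FALSE])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

check_partition_of <- function(g, p) {
  if (!setequal(attr(p, "vertices"), g$vertices)) {
    stop("partition is not over the graph's vertex set", call. = FALSE)
  }
}

#' Coarsest generalized equitable refinement
#'
#' Computes the unique coarsest refinement of `p` that is generalized
#' equitable, by repeatedly splitting every cell on its vector of per-type,
#' per-direction edge counts into the current cells until nothing splits.
#' Fragments of a split cell replace it in place; among themselves they are
#' ordered by their count vectors sorted in decreasing order (larger counts
#' first, so cells of higher degree precede cells of lower degree), with
#' ties broken by the raw count vector in increasing lexicographic order.
#' The result refines `p` (in the ordered sense), is equitable, and is
#' idempotent under re-refinement.
#'
#' @param g A [typed_graph()].
#' @param p An [ordered_partition()]; defaults to the trivial partition.
#' @return An [ordered_partition()].
#' @examples
#' g1 <- fixture_g1()
#' coarsest_equitable_refinement(g1)
#' @export
coarsest_equitable_refinement <- function(g, p = NULL) {
  stopifnot(inherits(g, "typed_graph"))
  if (is.null(p)) p <- ordered_partition(list(g$vertices), g$vertices)
  check_partition_of(g, p)
  chans <- channel_matrices(g)
  cells <- refine_cells(chans, cells_to_idx(p, g$vertices), n_vertices(g))
  idx_to_partition(cells, g$vertices)
}
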