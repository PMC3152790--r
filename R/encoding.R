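#' Multi-edge-type adjacency encoding
#'
#' Encodes a typed graph as an integer matrix in a given vertex order: the
#' `(i, j)` entry is the sum of `2^e` over the edge types `e` present between
#' vertices `i` and `j`.  An undirected-type edge contributes to both the
#' `(i, j)` and `(j, i)` entries; a directed-type edge from `i` to `j`
#' contributes only to `(i, j)`.  With the molecular convention (hierarchy =
#' type 0 directed, bond = type 1 undirected) the possible entries are 0, 1,
#' 2 and 3, where 3 means a hierarchy edge and a bond coincide.  The diagonal
#' is always 0 since roots carry no self-edge.
#'
#' @param g A [typed_graph()].
#' @param order Character vector: a permutation of `g`'s vertex ids giving
#'   the row/column order.  Defaults to the stored vertex order.
#' @return An object of class `adjacency_matrix`: an integer matrix with
#'   dimnames `order` and attributes `directedness`.
#' @examples
#' g <- lck_species()
#' encode_adjacency(g)[1:3, 1:3]
#' @export
encode_adjacency <- function(g, order = NULL) {
  stopifnot(inherits(g, "typed_graph"))
  if (is.null(order)) order <- g$vertices
  order <- as.character(order)
  if (!setequal(order, g$vertices) || length(order) != length(g$vertices)) {
    stop("`order` must be a permutation of the graph's vertices",
         call. = FALSE)
  }
  n <- length(order)
  a <- matrix(0L, n, n, dimnames = list(order, order))
  e <- g$edges
  if (nrow(e)) {
    pos <- stats::setNames(seq_len(n), order)
    i <- pos[e$src]
    j <- pos[e$dst]
    w <- bitwShiftL(1L, e$type)
    und <- g$directedness[e$type + 1L] == "undirected"
    # same-type parallel edges are excluded by construction, so summing
    # weights per (row, col) position never double-counts a bit
    lin <- c((j - 1L) * n + i, (i[und] - 1L) * n + j[und])
    wts <- c(w, w[und])
    s <- rowsum(wts, lin)
    a[as.integer(rownames(s))] <- as.integer(s[, 1L])
  }
  structure(a, directedness = g$directedness, class = "adjacency_matrix")
}

#' Reconstruct a typed graph from its adjacency encoding
#'
#' Inverse of [encode_adjacency()] for graphs without same-type parallel
#' edges: bit `e` of entry `(i, j)` declares a type-`e` edge.  For undirected
#' types the bit must be symmetric across the diagonal; an asymmetric
#' undirected bit signals a corrupted matrix and is rejected.
#'
#' @param m An `adjacency_matrix`, or a plain integer matrix with dimnames.
#' @param directedness Per-type directedness (defaults to the attribute
#'   stored on `m`).
#' @param labels,possible,attributes Vertex metadata passed to
#'   [typed_graph()].
#' @return A [typed_graph()] whose re-encoding under the same order
#'   reproduces `m` exactly.
#' @export
decode_adjacency <- function(m, directedness = attr(m, "directedness"),
                             labels = NULL, possible = NULL,
                             attributes = NULL) {
  if (is.null(directedness)) {
    stop("`directedness` is required when `m` carries no attribute",
         call. = FALSE)
  }
  a <- unclass(m)
  attr(a, "directedness") <- NULL
  n <- nrow(a)
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("v", seq_len(n))
  ntypes <- length(directedness)
  if (any(a < 0L) || any(a >= bitwShiftL(1L, ntypes))) {
    stop("matrix entry out of range for ", ntypes, " edge types",
         call. = FALSE)
  }
  edges <- list()
  for (e in seq_len(ntypes) - 1L) {
    bit <- matrix(bitwAnd(as.integer(a), bitwShiftL(1L, e)) > 0L, n, n)
    if (directedness[e + 1L] == "undirected") {
      if (!isTRUE(all(bit == t(bit)))) {
        stop("asymmetric entries for undirected edge type ", e,
             call. = FALSE)
      }
      idx <- which(bit & upper.tri(bit), arr.ind = TRUE)
    } else {
      idx <- which(bit, arr.ind = TRUE)
    }
    if (nrow(idx)) {
      edges[[length(edges) + 1L]] <- data.frame(
        src = ids[idx[, 1L]], dst = ids[idx[, 2L]], type = e,
        stringsAsFactors = FALSE)
    }
  }
  if (any(diag(a) != 0L)) stop("nonzero diagonal entry", call. = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  typed_graph(ids, edges, directedness,
              labels = labels, possible = possible, attributes = attributes)
}

#' Flatten a typed graph to a single edge type
#'
#' Replaces every typed edge by an inserted vertex labeled after the edge's
#' type ("h" for hierarchy, "b" for bond, "t<e>" for further types),
#' connected to both endpoints, producing a bipartite graph with one edge
#' type.  Direction survives the transform: a directed-type edge from `x` to
#' `y` becomes the arcs `x -> v` and `v -> y`, while an undirected-type edge
#' becomes two arcs into the inserted vertex (or two plain undirected edges
#' when no input type is directed).  Original vertex labels are prefixed
#' `"v:"` and inserted labels `"e:"` so the two sides can never collide.
#' Two typed graphs are isomorphic exactly when their flattenings are.
#'
#' @param g A [typed_graph()].
#' @return A [typed_graph()] with a single edge type and
#'   `|V| + |E|` vertices.
#' @export
flatten <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  any_dir <- any(g$directedness == "directed")
  out_dir <- if (any_dir) "directed" else "undirected"
  type_label <- function(e) {
    if (e == 0L) "h" else if (e == 1L) "b" else paste0("t", e)
  }
  ne <- nrow(g$edges)
  ins_ids <- if (ne) paste0(".e", seq_len(ne)) else character(0)
  labels <- c(stats::setNames(paste0("v:", g$labels), g$vertices),
              stats::setNames(
                paste0("e:", vapply(g$edges$type, type_label, character(1))),
                ins_ids))
  edges <- NULL
  if (ne) {
    dir_in <- g$directedness[g$edges$type + 1L] == "directed"
    src1 <- g$edges$src
    dst1 <- ins_ids
    # directed e: x -> v -> y ; undirected e: x -> v <- y (both arcs inward)
    src2 <- ifelse(dir_in, ins_ids, g$edges$dst)
    dst2 <- ifelse(dir_in, g$edges$dst, ins_ids)
    edges <- data.frame(src = c(src1, src2), dst = c(dst1, dst2),
                        type = 0L, stringsAsFactors = FALSE)
  }
  possible <- g$possible
  attributes <- g$attributes
  typed_graph(c(g$vertices, ins_ids), edges, out_dir,
              labels = labels, possible = possible, attributes = attributes)
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  y <- unclass(x)
  attr(y, "directedness") <- NULL
  print(y, ...)
  invisible(x)
}

# bare integer matrix of the encoding: no class, no attributes, no dimnames
# (safe for identical() comparisons under row/column permutation)
plain_adjacency <- function(g, order = NULL) {
  a <- unclass(encode_adjacency(g, order))
  attributes(a) <- list(dim = dim(a))
  a
}

#' Serialize an adjacency matrix row-major
#'
#' The row-major integer sequence of the matrix in its stored order; this
#' string is the comparison unit for canonical labels.
#'
#' @param m An `adjacency_matrix` or integer matrix.
#' @return A single string of space-separated integers.
#' @export
serialize_adjacency <- function(m) {
  paste(as.integer(t(unclass(m))), collapse = " ")
}

#' Nested adjacency mapping
#'
#' Converts a typed graph to the nested mapping vertex -> neighbor -> vector
#' of edge types: for directed types only the source vertex lists the
#' neighbor, for undirected types both endpoints do.
#'
#' @param g A [typed_graph()].
#' @return A named list of named lists of integer vectors.
#' @export
as_adjacency_list <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  a <- encode_adjacency(g)
  out <- lapply(g$vertices, function(v) {
    row <- a[v, ]
    nb <- names(row)[row > 0L]
    stats::setNames(lapply(nb, function(u) {
      which(bitwAnd(row[[u]], bitwShiftL(1L, 0:(g$m - 1L))) > 0L) - 1L
    }), nb)
  })
  stats::setNames(out, g$vertices)
}
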