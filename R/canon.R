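# The HNauty search: individualization and refinement leaves, automorphism
# discovery and pruning, shape-sequence indicator pruning, canonical label
# selection.

# --- small comparators ------------------------------------------------------

# lexicographic on integer vectors, shorter-prefix-first
cmp_vec <- function(x, y) {
  k <- min(length(x), length(y))
  if (k > 0L) {
    d <- which(x[seq_len(k)] != y[seq_len(k)])
    if (length(d)) return(if (x[d[1L]] < y[d[1L]]) -1L else 1L)
  }
  sign(length(x) - length(y))
}

# indicator paths: sequences of shape vectors, compared elementwise
cmp_path <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    c <- cmp_vec(a[[i]], b[[i]])
    if (c != 0L) return(c)
  }
  sign(length(a) - length(b))
}

# compare a node's (partial) path against a leaf path: 0 means "still on the
# same track", i.e. the node path is a prefix-equal of the leaf path
cmp_path_prefix <- function(path, full) {
  k <- min(length(path), length(full))
  for (i in seq_len(k)) {
    c <- cmp_vec(path[[i]], full[[i]])
    if (c != 0L) return(c)
  }
  if (length(path) > length(full)) 1L else 0L
}

cells_shape <- function(cells) {
  sizes <- lengths(cells)
  tabulate(sizes, nbins = max(sizes))
}

# --- initial coloring -------------------------------------------------------

#' Initial partition from vertex colors
#'
#' Groups vertices by their color key: the label, the sorted list of possible
#' attribute values, and the assigned attribute (the internal state is folded
#' into the color, so a phosphorylated and an unphosphorylated tyrosine fall
#' in different cells).  Cells are ordered lexicographically by color key
#' (byte order, locale-independent), so the result does not depend on the
#' input vertex order.
#'
#' @param g A [typed_graph()].
#' @return An [ordered_partition()].
#' @export
initial_partition <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  keys <- color_keys(g)
  ukeys <- sort(unique(keys), method = "radix")
  cells <- lapply(ukeys, function(k) g$vertices[keys == k])
  ordered_partition(cells, g$vertices)
}

color_keys <- function(g) {
  vapply(g$vertices, function(v) {
    poss <- if (v %in% names(g$possible)) {
      paste(sort(g$possible[[v]], method = "radix"), collapse = ",")
    } else ""
    assn <- if (v %in% names(g$attributes)) g$attributes[[v]] else ""
    paste(g$labels[[v]], poss, assn, sep = "\x01")
  }, character(1))
}

# --- the search -------------------------------------------------------------

leaf_string <- function(a, perm, width) {
  paste(formatC(as.integer(t(a[perm, perm, drop = FALSE])),
                width = width, flag = "0"), collapse = "")
}

# Depth-first individualization-and-refinement search.  Returns an
# environment with the first leaf, the best ((indicator path, matrix
# string)-minimal) leaf, discovered automorphism generators, node/leaf
# counts, and optionally every surviving leaf.
hn_search <- function(g, p0 = NULL,
                      pruning = c("auto+ind", "auto", "none"),
                      collect_leaves = FALSE) {
  pruning <- match.arg(pruning)
  use_auto <- pruning %in% c("auto", "auto+ind")
  use_ind <- pruning == "auto+ind"
  if (is.null(p0)) p0 <- initial_partition(g)
  check_partition_of(g, p0)

  n <- n_vertices(g)
  a <- plain_adjacency(g)
  chans <- channel_matrices(g, a)
  width <- nchar(as.character(bitwShiftL(1L, g$m) - 1L))

  st <- new.env(parent = emptyenv())
  st$first <- NULL
  st$best <- NULL
  st$gens <- list()
  st$nodes <- 0L
  st$nleaves <- 0L
  st$leaves <- if (collect_leaves) list() else NULL

  handle_leaf <- function(cells, path) {
    st$nleaves <- st$nleaves + 1L
    perm <- unlist(cells)
    str <- leaf_string(a, perm, width)
    if (collect_leaves) st$leaves[[length(st$leaves) + 1L]] <- cells
    this <- list(perm = perm, str = str, path = path)
    if (is.null(st$first)) {
      st$first <- this
      st$best <- this
      return(invisible())
    }
    if (use_auto) {
      for (ref in list(st$first, st$best)) {
        if (cmp_path(path, ref$path) == 0L && str == ref$str &&
            any(perm != ref$perm)) {
          gamma <- integer(n)
          gamma[ref$perm] <- perm
          add_generator(gamma)
        }
      }
    }
    cp <- cmp_path(path, st$best$path)
    if (cp < 0L || (cp == 0L && str < st$best$str)) st$best <- this
    invisible()
  }

  add_generator <- function(gamma) {
    for (g0 in st$gens) if (all(g0 == gamma)) return(invisible())
    st$gens[[length(st$gens) + 1L]] <- gamma
    invisible()
  }

  # orbit of x under the subgroup generated by generators fixing nu pointwise
  reachable <- function(x, targets, nu) {
    gens <- Filter(function(gm) all(gm[nu] == nu), st$gens)
    if (!length(gens)) return(FALSE)
    seen <- x
    frontier <- x
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(gens, function(gm) {
        c(gm[frontier], match(frontier, gm))
      })))
      nxt <- setdiff(nxt[!is.na(nxt)], seen)
      if (any(nxt %in% targets)) return(TRUE)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    any(seen %in% targets)
  }

  dfs <- function(cells, path, nu) {
    st$nodes <- st$nodes + 1L
    if (use_ind && !is.null(st$best)) {
      if (cmp_path_prefix(path, st$best$path) > 0L &&
          cmp_path_prefix(path, st$first$path) != 0L) {
        return(invisible())
      }
    }
    sizes <- lengths(cells)
    if (all(sizes == 1L)) return(handle_leaf(cells, path))
    t_idx <- which(sizes > 1L)[1L]
    target <- cells[[t_idx]]
    explored <- integer(0)
    for (x in target) {
      if (use_auto && length(explored) && length(st$gens) &&
          reachable(x, explored, nu)) {
        explored <- c(explored, x)
        next
      }
      child <- c(cells[seq_len(t_idx - 1L)],
                 list(x, setdiff(target, x)),
                 if (t_idx < length(cells)) cells[(t_idx + 1L):length(cells)])
      child <- refine_cells(chans, child, n)
      dfs(child, c(path, list(cells_shape(child))), c(nu, x))
      explored <- c(explored, x)
    }
    invisible()
  }

  root <- refine_cells(chans, cells_to_idx(p0, g$vertices), n)
  dfs(root, list(cells_shape(root)), integer(0))
  st$p0 <- p0
  st$adj <- a
  st$width <- width
  st
}

# --- user-facing operations -------------------------------------------------

#' Canonical form of a typed graph (HNauty)
#'
#' Runs the individualization-and-refinement search from the color-induced
#' initial partition (or a supplied one) and returns the canonical form: the
#' leaf whose (indicator path, serialized adjacency matrix) pair is minimal
#' among all search leaves.  The label string couples the initial color-class
#' structure with the row-major integer serialization of the permuted
#' adjacency matrix, so isomorphic graphs -- and only isomorphic graphs,
#' among graphs sharing an edge-type table -- receive equal labels.  The
#' label is invariant under any relabeling or reordering of the input
#' vertices and contains no randomness.
#'
#' @param g A [typed_graph()].
#' @param p0 Optional initial [ordered_partition()]; defaults to
#'   [initial_partition()].
#' @param pruning `"auto+ind"` (default: automorphism and indicator pruning),
#'   `"auto"`, or `"none"`.  All three return the same canonical form; the
#'   flag exists for diagnostics.
#' @return An object of class `canonical_form` with elements `permutation`
#'   (the canonical vertex ordering), `label` (the canonical label string),
#'   `matrix` (the canonically permuted adjacency matrix), `n_nodes`,
#'   `n_leaves` (search-tree statistics) and `generators` (discovered
#'   automorphisms, as named character vectors).
#' @examples
#' cf <- hnauty_canonical(fixture_g2())
#' cf$permutation
#' @export
hnauty_canonical <- function(g, p0 = NULL,
                             pruning = c("auto+ind", "auto", "none")) {
  stopifnot(inherits(g, "typed_graph"))
  st <- hn_search(g, p0, pruning)
  perm <- g$vertices[st$best$perm]
  m <- st$adj[st$best$perm, st$best$perm, drop = FALSE]
  dimnames(m) <- list(perm, perm)
  label <- paste0(color_class_signature(g, st$p0), "|",
                  paste(as.integer(t(m)), collapse = " "))
  structure(
    list(permutation = perm, label = label, matrix = m,
         n_nodes = st$nodes, n_leaves = st$nleaves,
         generators = lapply(st$gens, function(gm) {
           stats::setNames(g$vertices[gm], g$vertices)
         })),
    class = "canonical_form"
  )
}

color_class_signature <- function(g, p0) {
  keys <- color_keys(g)
  paste(vapply(p0, function(cell) {
    k <- unique(keys[match(cell, g$vertices)])
    k <- if (length(k) == 1L) k else ""
    paste0(gsub("\x01", "~", k), "x", length(cell))
  }, character(1)), collapse = ";")
}

#' @export
print.canonical_form <- function(x, ...) {
  cat("<canonical_form>\n")
  cat("  permutation:", paste(x$permutation, collapse = " "), "\n")
  cat("  label:", substr(x$label, 1L, 60L),
      if (nchar(x$label) > 60L) "..." else "", "\n")
  cat(sprintf("  search: %d nodes, %d leaves, %d generator(s)\n",
              x$n_nodes, x$n_leaves, length(x$generators)))
  invisible(x)
}

#' Enumerate the discrete partitions produced by the search
#'
#' With `pruning = "none"` every leaf reachable by individualizing each
#' vertex of the first non-singleton cell at each level is returned, in
#' depth-first order.  With automorphism pruning, subtrees that are images of
#' an explored subtree under a discovered automorphism are skipped; with
#' indicator pruning, nodes whose shape-sequence indicator cannot reach the
#' minimum are skipped as well.  All modes retain a leaf realizing the
#' canonical form.
#'
#' @inheritParams hnauty_canonical
#' @return A list of discrete [ordered_partition()]s, with attributes
#'   `n_nodes` and `n_leaves`.
#' @export
enumerate_leaves <- function(g, p0 = NULL,
                             pruning = c("none", "auto", "auto+ind")) {
  stopifnot(inherits(g, "typed_graph"))
  pruning <- match.arg(pruning)
  st <- hn_search(g, p0, pruning, collect_leaves = TRUE)
  out <- lapply(st$leaves, idx_to_partition, vertices = g$vertices)
  attr(out, "n_nodes") <- st$nodes
  attr(out, "n_leaves") <- st$nleaves
  out
}

#' Derive an automorphism from two search leaves
#'
#' Two discrete partitions (leaves) whose permuted adjacency matrices are
#' equal differ by an automorphism, recovered by composing one permutation
#' with the inverse of the other.  The returned map is verified against the
#' graph (edge preservation per type, color preservation) before being
#' reported; if the matrices differ, `NULL` is returned.
#'
#' @param g A [typed_graph()].
#' @param leaf1,leaf2 Discrete [ordered_partition()]s of `g`'s vertices.
#' @return A named character vector mapping each vertex to its image, or
#'   `NULL`.
#' @export
discover_automorphism <- function(g, leaf1, leaf2) {
  stopifnot(inherits(g, "typed_graph"))
  if (!is_discrete(leaf1) || !is_discrete(leaf2)) {
    stop("leaves must be discrete partitions", call. = FALSE)
  }
  a <- plain_adjacency(g)
  p1 <- match(unlist(leaf1), g$vertices)
  p2 <- match(unlist(leaf2), g$vertices)
  if (!identical(a[p1, p1, drop = FALSE], a[p2, p2, drop = FALSE])) {
    return(NULL)
  }
  gamma <- stats::setNames(g$vertices[p2], g$vertices[p1])
  gamma <- gamma[g$vertices]
  names(gamma) <- g$vertices
  stopifnot(is_automorphism(g, gamma))
  gamma
}

#' Check whether a permutation is an automorphism
#'
#' Edge preservation per edge type (and arc direction), plus preservation of
#' labels, possible-attribute lists and assigned attributes.
#'
#' @param g A [typed_graph()].
#' @param perm Named character vector mapping vertex to image.
#' @return `TRUE` or `FALSE`.
#' @export
is_automorphism <- function(g, perm) {
  stopifnot(inherits(g, "typed_graph"))
  perm <- perm[g$vertices]
  if (anyNA(perm) || !setequal(perm, g$vertices)) return(FALSE)
  keys <- color_keys(g)
  if (!all(keys[match(perm, g$vertices)] == keys)) return(FALSE)
  a <- plain_adjacency(g)
  p <- match(perm, g$vertices)
  identical(a[p, p, drop = FALSE], a)
}

#' Isomorphism test via canonical labels
#'
#' Two typed graphs with the same edge-type table are isomorphic exactly
#' when their canonical labels coincide (respecting vertex colors,
#' attributes and every edge type).
#'
#' @param g1,g2 [typed_graph()] objects with identical `directedness`
#'   tables.
#' @return `TRUE` or `FALSE`.
#' @export
are_isomorphic <- function(g1, g2) {
  stopifnot(inherits(g1, "typed_graph"), inherits(g2, "typed_graph"))
  if (!identical(g1$directedness, g2$directedness)) {
    stop("graphs have incompatible edge-type tables", call. = FALSE)
  }
  if (n_vertices(g1) != n_vertices(g2)) return(FALSE)
  hnauty_canonical(g1)$label == hnauty_canonical(g2)$label
}

#' Order of the automorphism group
#'
#' Counts the color- and edge-type-preserving automorphisms of `g` by
#' closing the generator set discovered during the pruned search under
#' composition.  Exact for small graphs; the enumeration refuses to grow
#' past `max_order` elements.
#'
#' @param g A [typed_graph()].
#' @param max_order Safety cap on the group enumeration (default `1e6`).
#' @return A positive integer.
#' @export
automorphism_count <- function(g, max_order = 1e6) {
  stopifnot(inherits(g, "typed_graph"))
  st <- hn_search(g, pruning = "auto")
  gens <- st$gens
  if (!length(gens)) return(1L)
  n <- n_vertices(g)
  id <- seq_len(n)
  key <- function(p) paste(p, collapse = ",")
  elems <- new.env(parent = emptyenv())
  assign(key(id), TRUE, envir = elems)
  frontier <- list(id)
  count <- 1L
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (gm in gens) {
        q <- gm[p]
        k <- key(q)
        if (!exists(k, envir = elems, inherits = FALSE)) {
          assign(k, TRUE, envir = elems)
          count <- count + 1L
          if (count > max_order) {
            stop("automorphism group larger than `max_order`", call. = FALSE)
          }
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
  }
  count
}
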