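#' Build a typed graph
#'
#' A typed graph is a vertex-labeled, vertex-attributed graph whose edges each
#' carry an integer edge type; every type is globally declared directed or
#' undirected.  In the molecular setting two types are used: type 0, directed,
#' for the containment hierarchy (protein contains domain contains residue)
#' and type 1, undirected, for bonds, but any number of types is supported.
#' At most one edge of a given type may join a vertex pair, undirected edges
#' are stored with endpoints in vertex order, and self-edges are rejected
#' (a component that declares itself as its own parent is treated as a root,
#' i.e. the edge is simply absent).
#'
#' @param vertices Either a character vector of vertex ids, or a data.frame
#'   with columns `id`, optional `label` (defaults to the id), optional
#'   `possible` (comma-separated string of allowed attribute values) and
#'   optional `attr` (assigned attribute value, `NA` for unassigned).
#' @param edges A data.frame with columns `src`, `dst`, `type` (integer edge
#'   type, counted from 0), or `NULL` for an edgeless graph.
#' @param directedness Character vector, one of `"directed"`/`"undirected"`
#'   per edge type, in type order starting at type 0.  Its length fixes the
#'   number of edge types `m`.
#' @param labels Optional named character vector of vertex labels (ignored
#'   when `vertices` is a data.frame).
#' @param possible Optional named list of character vectors: the allowed
#'   attribute values per vertex.  Vertices absent from the list admit no
#'   attribute.
#' @param attributes Optional named character vector of assigned attribute
#'   values; each must belong to that vertex's `possible` list.
#' @return An object of class `typed_graph`.
#' @examples
#' g <- typed_graph(
#'   vertices = c("a", "b", "c"),
#'   edges = data.frame(src = "a", dst = "b", type = 1L),
#'   directedness = c("directed", "undirected")
#' )
#' g
#' @export
typed_graph <- function(vertices, edges = NULL,
                        directedness = c("directed", "undirected"),
                        labels = NULL, possible = NULL, attributes = NULL) {
  if (is.data.frame(vertices)) {
    vdf <- vertices
    if (!"id" %in% names(vdf)) stop("vertex data.frame needs an `id` column",
                                    call. = FALSE)
    ids <- as.character(vdf$id)
    labels <- if ("label" %in% names(vdf)) {
      stats::setNames(as.character(vdf$label), ids)
    } else NULL
    if ("possible" %in% names(vdf)) {
      possible <- lapply(as.character(vdf$possible), function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",")[[1]]
      })
      names(possible) <- ids
      possible <- possible[lengths(possible) > 0L]
    }
    if ("attr" %in% names(vdf)) {
      a <- stats::setNames(as.character(vdf$attr), ids)
      attributes <- a[!is.na(a)]
    }
    vertices <- ids
  }
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate vertex ids", call. = FALSE)
  if (is.null(labels)) labels <- stats::setNames(vertices, vertices)
  labels <- labels[vertices]
  names(labels) <- vertices
  if (anyNA(labels)) stop("every vertex needs a label", call. = FALSE)

  directedness <- as.character(directedness)
  if (!length(directedness) ||
      !all(directedness %in% c("directed", "undirected"))) {
    stop("`directedness` entries must be \"directed\" or \"undirected\"",
         call. = FALSE)
  }
  m <- length(directedness)

  if (is.null(possible)) possible <- list()
  possible <- lapply(possible, as.character)
  if (!all(names(possible) %in% vertices)) {
    stop("attribute list names an unknown vertex", call. = FALSE)
  }
  if (is.null(attributes)) attributes <- character(0)
  if (length(attributes)) {
    bad <- setdiff(names(attributes), names(possible))
    if (length(bad)) {
      stop("assigned attribute on vertex without a possible-attribute list: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (v in names(attributes)) {
      if (!attributes[[v]] %in% possible[[v]]) {
        stop(sprintf("attribute '%s' of vertex '%s' is not in its possible list",
                     attributes[[v]], v), call. = FALSE)
      }
    }
  }

  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(src = character(0), dst = character(0),
                        type = integer(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(src = as.character(edges$src),
                        dst = as.character(edges$dst),
                        type = as.integer(edges$type),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(c(edges$src, edges$dst), vertices)
    if (length(unknown)) {
      stop("edge endpoint is not a declared vertex: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    if (any(edges$type < 0L | edges$type >= m)) {
      stop("edge type out of range 0..", m - 1L, call. = FALSE)
    }
    if (any(edges$src == edges$dst)) {
      stop("self-edges are not allowed (a self-parent denotes a root and is ",
           "represented by the absence of an edge)", call. = FALSE)
    }
    # normalize undirected edges: endpoints in vertex-list order
    pos <- stats::setNames(seq_along(vertices), vertices)
    und <- directedness[edges$type + 1L] == "undirected"
    flip <- und & pos[edges$src] > pos[edges$dst]
    tmp <- edges$src[flip]
    edges$src[flip] <- edges$dst[flip]
    edges$dst[flip] <- tmp
    if (anyDuplicated(edges[c("src", "dst", "type")])) {
      stop("duplicate edge of the same type between a vertex pair",
           call. = FALSE)
    }
    rownames(edges) <- NULL
  }

  structure(
    list(vertices = vertices, labels = labels, possible = possible,
         attributes = attributes, edges = edges,
         directedness = directedness, m = m),
    class = "typed_graph"
  )
}

#' @rdname typed_graph
#' @param vertex_specs,edge_specs,type_directedness Aliases of `vertices`,
#'   `edges` and `directedness`.
#' @export
build_graph <- function(vertex_specs, edge_specs = NULL,
                        type_directedness = c("directed", "undirected")) {
  typed_graph(vertex_specs, edge_specs, type_directedness)
}

#' @export
print.typed_graph <- function(x, ...) {
  cat(sprintf("<typed_graph> %d vertices, %d edges, %d edge type%s (%s)\n",
              length(x$vertices), nrow(x$edges), x$m,
              if (x$m == 1L) "" else "s",
              paste(x$directedness, collapse = ", ")))
  if (inherits(x, "hier_graph")) {
    cat(sprintf("  hierarchical molecule graph, flavor = %s\n",
                attr(x, "flavor")))
  }
  invisible(x)
}

n_vertices <- function(g) length(g$vertices)

#' Structural equality of typed graphs
#'
#' Two typed graphs are structurally equal when they have the same vertex
#' ids, labels, possible/assigned attributes, edge-type table and typed edge
#' set (regardless of edge row order).  This is equality of the stored
#' object, not isomorphism; see [are_isomorphic()] for the latter.
#'
#' @param g1,g2 [typed_graph()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
graphs_identical <- function(g1, g2) {
  canon_edges <- function(g) {
    e <- g$edges
    e[order(e$type, e$src, e$dst), , drop = FALSE]
  }
  same_attr <- function(a, b) {
    length(a) == length(b) && setequal(names(a), names(b)) &&
      all(unlist(a[names(a)]) == unlist(b[names(a)]))
  }
  identical(g1$vertices, g2$vertices) &&
    identical(g1$labels[g1$vertices], g2$labels[g1$vertices]) &&
    identical(g1$directedness, g2$directedness) &&
    setequal(names(g1$possible), names(g2$possible)) &&
    all(vapply(names(g1$possible), function(v) {
      identical(sort(g1$possible[[v]]), sort(g2$possible[[v]]))
    }, logical(1))) &&
    same_attr(g1$attributes, g2$attributes) &&
    isTRUE(all.equal(canon_edges(g1), canon_edges(g2),
                     check.attributes = FALSE)) &&
    nrow(g1$edges) == nrow(g2$edges)
}

#' Hierarchical molecule graphs
#'
#' A hierarchical molecule graph is a typed graph whose type-0 edges are the
#' directed containment hierarchy and whose type-1 edges are undirected
#' bonds.  The `flavor` distinguishes a molecular *entity* graph (attributed
#' vertices list their possible internal states, none assigned or some
#' assigned) from a chemical *species* graph, in which every vertex with a
#' non-empty possible-attribute list carries exactly one assigned value.
#'
#' @param g A [typed_graph()] with at least two edge types, type 0 directed
#'   and type 1 undirected.
#' @param flavor `"entity"` or `"species"`.
#' @return `g` with class `hier_graph` prepended and a `flavor` attribute.
#' @export
hier_graph <- function(g, flavor = c("entity", "species")) {
  stopifnot(inherits(g, "typed_graph"))
  flavor <- match.arg(flavor)
  if (g$m < 2L || g$directedness[1L] != "directed" ||
      g$directedness[2L] != "undirected") {
    stop("hierarchical molecule graphs need type 0 directed (hierarchy) and ",
         "type 1 undirected (bond)", call. = FALSE)
  }
  if (classify_hierarchy(g) == "invalid") {
    stop("hierarchy edges contain a directed cycle", call. = FALSE)
  }
  if (flavor == "species") {
    need <- names(g$possible)
    missing <- setdiff(need, names(g$attributes))
    if (length(missing)) {
      stop("species graph leaves attributes unassigned: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(g, class = c("hier_graph", class(g)), flavor = flavor)
}

#' Classify the containment hierarchy of a graph
#'
#' Inspects the type-0 (hierarchy) edges: a *strict hierarchy* is a forest
#' (acyclic, every vertex has at most one parent), a *pseudo-hierarchy* is
#' any other directed acyclic graph (some vertex has two or more parents, as
#' for a tyrosine shared by two overlapping linear motifs), and a graph whose
#' hierarchy edges contain a directed cycle is *invalid*.  Classification is
#' total and invariant under vertex renaming.
#'
#' @param g A [typed_graph()] whose type 0 is directed.
#' @return One of `"strict_hierarchy"`, `"pseudo_hierarchy"`, `"invalid"`.
#' @export
classify_hierarchy <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  h <- g$edges[g$edges$type == 0L, , drop = FALSE]
  if (nrow(h) == 0L) return("strict_hierarchy")
  ig <- igraph::graph_from_data_frame(
    h[c("src", "dst")], directed = TRUE,
    vertices = data.frame(name = g$vertices)
  )
  if (!igraph::is_dag(ig)) return("invalid")
  # parent count = hierarchy in-degree under the parent->child arrow direction
  indeg <- table(h$dst)
  if (any(indeg >= 2L)) "pseudo_hierarchy" else "strict_hierarchy"
}

#' Assign internal states to derive a chemical species graph
#'
#' Takes a molecular entity graph and a complete assignment of attribute
#' values (one per attributed vertex, each drawn from that vertex's possible
#' list) and returns the corresponding chemical species graph.  Labels never
#' change; only attributes do.
#'
#' @param entity A [hier_graph()] with `flavor = "entity"`.
#' @param assignment Named character vector: vertex id to attribute value.
#'   Must cover exactly the vertices with a non-empty possible list.
#' @return A [hier_graph()] with `flavor = "species"`.
#' @export
assign_attributes <- function(entity, assignment) {
  stopifnot(inherits(entity, "hier_graph"))
  if (attr(entity, "flavor") != "entity") {
    stop("`entity` must have flavor \"entity\"", call. = FALSE)
  }
  assignment <- stats::setNames(as.character(assignment), names(assignment))
  need <- names(entity$possible)
  if (!setequal(names(assignment), need)) {
    stop("assignment must cover exactly the attributed vertices (",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  g <- unclass_hier(entity)
  g <- typed_graph(g$vertices, g$edges, g$directedness,
                   labels = g$labels, possible = g$possible,
                   attributes = assignment)
  hier_graph(g, "species")
}

unclass_hier <- function(g) {
  class(g) <- "typed_graph"
  attr(g, "flavor") <- NULL
  g
}

#' Apply a vertex permutation to a typed graph
#'
#' Produces the isomorphic copy of `g` in which vertex `v` plays the role
#' that `perm[v]` played: labels, attributes and edges are mapped through the
#' permutation.  Optionally the stored vertex order of the result is an
#' arbitrary given order, which exercises input-order invariance of
#' downstream algorithms.
#'
#' @param g A [typed_graph()].
#' @param perm Named character vector mapping each vertex id to its image
#'   (a bijection of the vertex set onto itself).
#' @param new_order Optional character vector: storage order of the result's
#'   vertices (any permutation of the ids).  Defaults to `g`'s order.
#' @return A [typed_graph()].
#' @export
permute_graph <- function(g, perm, new_order = NULL) {
  stopifnot(inherits(g, "typed_graph"))
  perm <- stats::setNames(as.character(perm), names(perm))
  if (!setequal(names(perm), g$vertices) || !setequal(perm, g$vertices)) {
    stop("`perm` must be a bijection of the vertex set", call. = FALSE)
  }
  if (is.null(new_order)) new_order <- g$vertices
  labels <- stats::setNames(g$labels[names(perm)], perm[names(perm)])
  possible <- g$possible
  if (length(possible)) names(possible) <- perm[names(possible)]
  attributes <- g$attributes
  if (length(attributes)) names(attributes) <- perm[names(attributes)]
  edges <- g$edges
  if (nrow(edges)) {
    edges$src <- unname(perm[edges$src])
    edges$dst <- unname(perm[edges$dst])
  }
  typed_graph(new_order, edges, g$directedness,
              labels = labels, possible = possible, attributes = attributes)
}
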