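#' Ordered partitions of a vertex set
#'
#' An ordered partition is a sequence of pairwise disjoint, non-empty vertex
#' cells whose union is the full vertex set.  Cell order matters: the
#' individualization-and-refinement machinery treats two partitions with the
#' same cells in different orders as different objects.  A partition is
#' *discrete* when every cell is a singleton (equivalently, it is an ordering
#' of the vertices) and *trivial* when it has a single cell.
#'
#' @param cells A list of character vectors, one per cell, in cell order.
#' @param vertices Character vector of all vertex ids the partition covers.
#'   Defaults to the union of the cells (in first-appearance order).
#' @return An object of class `ordered_partition`: a list of character
#'   vectors with attribute `vertices`.
#' @examples
#' p <- ordered_partition(list(c("a", "b"), "c"))
#' partition_shape(p)
#' @export
ordered_partition <- function(cells, vertices = NULL) {
  if (!is.list(cells) || length(cells) == 0L) {
    stop("`cells` must be a non-empty list of character vectors", call. = FALSE)
  }
  cells <- lapply(cells, as.character)
  sizes <- lengths(cells)
  if (any(sizes == 0L)) stop("empty cell in partition", call. = FALSE)
  flat <- unlist(cells, use.names = FALSE)
  if (anyDuplicated(flat)) {
    stop("partition cells are not disjoint", call. = FALSE)
  }
  if (is.null(vertices)) {
    vertices <- flat
  } else {
    vertices <- as.character(vertices)
    if (!setequal(flat, vertices) || length(flat) != length(vertices)) {
      stop("cells do not cover the vertex set exactly", call. = FALSE)
    }
  }
  structure(cells, vertices = vertices, class = "ordered_partition")
}

#' @rdname ordered_partition
#' @param x Object to test or print.
#' @export
is_discrete <- function(x) {
  stopifnot(inherits(x, "ordered_partition"))
  all(lengths(x) == 1L)
}

#' @rdname ordered_partition
#' @export
is_trivial <- function(x) {
  stopifnot(inherits(x, "ordered_partition"))
  length(x) == 1L
}

#' @rdname ordered_partition
#' @param ... Ignored.
#' @export
print.ordered_partition <- function(x, ...) {
  cat(format_partition(x), "\n", sep = "")
  invisible(x)
}

format_partition <- function(p) {
  paste0("(", paste(vapply(p, function(cell) {
    paste0("{", paste(cell, collapse = ","), "}")
  }, character(1)), collapse = ", "), ")")
}

#' Shape of an ordered partition
#'
#' The shape records, for each cell size `k` starting at 1, how many cells of
#' size `k` the partition contains; the vector is truncated at the largest
#' occurring cell size.  A partition with two singleton cells, one cell of
#' size two and one of size four therefore has shape `c(2, 1, 0, 1)`.  Shapes
#' are invariant under any permutation of the vertices, which is what makes
#' them usable as a search-tree indicator function.
#'
#' @param p An [ordered_partition()].
#' @return Integer vector; entry `k` counts cells of size `k`.
#' @export
partition_shape <- function(p) {
  stopifnot(inherits(p, "ordered_partition"))
  sizes <- lengths(p)
  tabulate(sizes, nbins = max(sizes))
}

#' Test the ordered refinement relation between two partitions
#'
#' `P` refines `Q` when every cell of `P` lies inside some cell of `Q` and the
#' cell orders are compatible: the first cell of `P` lies in the first cell of
#' `Q`, and consecutive cells of `P` land in the same cell of `Q` or the next
#' one.  Equivalently, `Q`'s cells are obtained by concatenating consecutive
#' runs of `P`'s cells.
#'
#' @param p,q [ordered_partition()] objects over the same vertex set.
#' @return `TRUE` or `FALSE`.
#' @export
is_refinement <- function(p, q) {
  stopifnot(inherits(p, "ordered_partition"), inherits(q, "ordered_partition"))
  if (!setequal(attr(p, "vertices"), attr(q, "vertices"))) {
    stop("partitions are over different vertex sets", call. = FALSE)
  }
  # index of the q-cell containing each p-cell (NA if split across q-cells)
  host <- vapply(seq_along(p), function(i) {
    hits <- which(vapply(q, function(cell) all(p[[i]] %in% cell), logical(1)))
    if (length(hits) == 1L) hits else NA_integer_
  }, integer(1))
  if (anyNA(host)) return(FALSE)
  if (host[1L] != 1L) return(FALSE)
  all(diff(host) %in% c(0L, 1L))
}

#' Individualize a vertex within an ordered partition
#'
#' Splits the cell containing `x` into `{x}` followed by the remainder of the
#' cell, leaving all other cells untouched.  This is the symmetry-breaking
#' step of the search: the singleton placed first matches the worked
#' search-tree leaves of the two-cell convention used throughout the package.
#'
#' @param p An [ordered_partition()].
#' @param x A vertex id lying in a cell of size at least 2.
#' @return A new `ordered_partition` refining `p`.
#' @export
individualize <- function(p, x) {
  stopifnot(inherits(p, "ordered_partition"))
  x <- as.character(x)
  idx <- which(vapply(p, function(cell) x %in% cell, logical(1)))
  if (length(idx) != 1L) stop("vertex not found in partition", call. = FALSE)
  if (length(p[[idx]]) < 2L) {
    stop("cannot individualize a vertex already in a singleton cell",
         call. = FALSE)
  }
  cells <- c(p[seq_len(idx - 1L)], list(x, setdiff(p[[idx]], x)),
             if (idx < length(p)) p[(idx + 1L):length(p)])
  ordered_partition(cells, attr(p, "vertices"))
}
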