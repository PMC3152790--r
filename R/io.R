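# Line-oriented graph files, partition files, and adjacency dumps.
#
# Graph file format (UTF-8, '#' starts a comment):
#   T <type:int> <directed|undirected>     one per edge type, type 0 first
#   V <id> <label> [~attr1,attr2,...] [=assigned_attr]
#   E <src_id> <dst_id> <type:int>

#' Read and write typed graphs as line-oriented text files
#'
#' `write_graph()` emits the `T`/`V`/`E` line format; `read_graph()` parses
#' it back.  The round trip is lossless for vertex order, labels,
#' possible-attribute lists, assigned attributes, the edge-type table and
#' the typed edge set.  Malformed lines are reported with their line
#' number.
#'
#' @param g A [typed_graph()].
#' @param path File path.
#' @return `read_graph()` returns a [typed_graph()]; `write_graph()`
#'   returns `path` invisibly.
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "typed_graph"))
  lines <- sprintf("T %d %s", seq_len(g$m) - 1L, g$directedness)
  for (v in g$vertices) {
    ln <- sprintf("V %s %s", v, g$labels[[v]])
    if (v %in% names(g$possible)) {
      ln <- paste0(ln, " ~", paste(g$possible[[v]], collapse = ","))
    }
    if (v %in% names(g$attributes)) {
      ln <- paste0(ln, " =", g$attributes[[v]])
    }
    lines <- c(lines, ln)
  }
  if (nrow(g$edges)) {
    lines <- c(lines, sprintf("E %s %s %d",
                              g$edges$src, g$edges$dst, g$edges$type))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  raw <- readLines(path, warn = FALSE)
  bad <- function(i, msg) {
    stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  }
  directedness <- character(0)
  vdf <- list()
  edf <- list()
  possible <- list()
  attributes <- character(0)
  for (i in seq_along(raw)) {
    line <- sub("#.*$", "", raw[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[1L] == "T") {
      if (length(tok) != 3L || is.na(suppressWarnings(as.integer(tok[2L]))) ||
          !tok[3L] %in% c("directed", "undirected")) {
        bad(i, "expected `T <type> <directed|undirected>`")
      }
      type <- as.integer(tok[2L])
      if (type != length(directedness)) {
        bad(i, "edge types must be declared in order starting at 0")
      }
      directedness <- c(directedness, tok[3L])
    } else if (tok[1L] == "V") {
      if (length(tok) < 3L) bad(i, "expected `V <id> <label> [...]`")
      id <- tok[2L]
      vdf[[length(vdf) + 1L]] <- c(id, tok[3L])
      for (extra in tok[-(1:3)]) {
        if (startsWith(extra, "~")) {
          possible[[id]] <- strsplit(substring(extra, 2L), ",")[[1]]
        } else if (startsWith(extra, "=")) {
          attributes[id] <- substring(extra, 2L)
        } else {
          bad(i, paste0("unexpected token `", extra, "`"))
        }
      }
    } else if (tok[1L] == "E") {
      if (length(tok) != 4L ||
          is.na(suppressWarnings(as.integer(tok[4L])))) {
        bad(i, "expected `E <src> <dst> <type>`")
      }
      if (as.integer(tok[4L]) >= length(directedness)) {
        bad(i, paste0("unknown edge type ", tok[4L]))
      }
      edf[[length(edf) + 1L]] <- list(tok[2L], tok[3L],
                                      as.integer(tok[4L]))
    } else {
      bad(i, paste0("unknown record `", tok[1L], "`"))
    }
  }
  if (!length(directedness)) {
    stop(path, ": no `T` edge-type declarations found", call. = FALSE)
  }
  if (!length(vdf)) stop(path, ": no vertices", call. = FALSE)
  ids <- vapply(vdf, `[`, character(1), 1L)
  labels <- stats::setNames(vapply(vdf, `[`, character(1), 2L), ids)
  edges <- NULL
  if (length(edf)) {
    edges <- data.frame(
      src = vapply(edf, function(e) e[[1L]], character(1)),
      dst = vapply(edf, function(e) e[[2L]], character(1)),
      type = vapply(edf, function(e) e[[3L]], integer(1)),
      stringsAsFactors = FALSE)
  }
  typed_graph(ids, edges, directedness, labels = labels,
              possible = possible, attributes = attributes)
}

#' Read and write ordered partitions as text files
#'
#' One cell per line, comma-separated vertex ids, cells top to bottom.
#'
#' @param p An [ordered_partition()].
#' @param path File path.
#' @param vertices Optional full vertex set for validation on read.
#' @return `read_partition()` returns an [ordered_partition()].
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "ordered_partition"))
  writeLines(vapply(p, paste, character(1), collapse = ","), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, vertices = NULL) {
  raw <- trimws(readLines(path, warn = FALSE))
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  cells <- lapply(raw, function(ln) trimws(strsplit(ln, ",")[[1]]))
  ordered_partition(cells, vertices)
}

#' Write and read the adjacency matrix as tab-separated text
#'
#' A plain-text mirror of the encoded matrix: a header row of vertex ids, a
#' leading id column, integer entries.
#'
#' @param g A [typed_graph()] or an `adjacency_matrix`.
#' @param path File path.
#' @param order Optional vertex order (when `g` is a graph).
#' @return `read_adjacency_matrix()` returns an integer matrix with
#'   dimnames; pair it with [decode_adjacency()] and a directedness table to
#'   recover a graph.
#' @export
write_adjacency_matrix <- function(g, path, order = NULL) {
  a <- if (inherits(g, "typed_graph")) encode_adjacency(g, order) else g
  a <- unclass(a)
  attr(a, "directedness") <- NULL
  lines <- c(paste(c("", colnames(a)), collapse = "\t"),
             vapply(seq_len(nrow(a)), function(i) {
               paste(c(rownames(a)[i], a[i, ]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_adjacency_matrix
#' @export
read_adjacency_matrix <- function(path) {
  raw <- readLines(path, warn = FALSE)
  header <- strsplit(raw[1L], "\t")[[1]][-1L]
  rows <- strsplit(raw[-1L], "\t")
  ids <- vapply(rows, `[`, character(1), 1L)
  a <- t(vapply(rows, function(r) as.integer(r[-1L]),
                integer(length(header))))
  dimnames(a) <- list(ids, header)
  storage.mode(a) <- "integer"
  a
}

#' Adjacency dump as JSON
#'
#' Serializes the nested vertex -> neighbor -> edge-type mapping of
#' [as_adjacency_list()] to JSON.
#'
#' @param g A [typed_graph()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_adjacency_json <- function(g, path) {
  jsonlite::write_json(as_adjacency_list(g), path, auto_unbox = FALSE)
  invisible(path)
}
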