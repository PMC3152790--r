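# Seeded Erdos-Renyi two-edge-type graphs and the permutation self-test.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Sample a random two-edge-type graph
#'
#' Independent Erdos-Renyi draws over the unordered vertex pairs, visited in
#' lexicographic `i < j` order: a pair carries an undirected bond (type 1)
#' edge with probability `p_undirected`, a directed hierarchy (type 0) edge
#' with probability `p_directed` (orientation uniform at random), and no
#' edge otherwise.  All vertices share one color.  Fully deterministic for a
#' fixed seed.
#'
#' @param n Number of vertices.
#' @param p_undirected,p_directed Edge probabilities; their sum must not
#'   exceed 1.
#' @param seed Integer seed.
#' @return A [typed_graph()] with types `(directed, undirected)`.
#' @examples
#' g <- sample_graph(20, 0.1, 0.05, seed = 1)
#' nrow(g$edges)
#' @export
sample_graph <- function(n, p_undirected = 0.1, p_directed = 0.05,
                         seed = 1L) {
  if (p_undirected < 0 || p_directed < 0 || p_undirected + p_directed > 1) {
    stop("need p_undirected, p_directed >= 0 with sum <= 1", call. = FALSE)
  }
  ids <- sprintf("n%03d", seq_len(n))
  npair <- n * (n - 1L) / 2L
  edges <- NULL
  if (npair > 0L) {
    draws <- with_seed(seed, {
      list(u = stats::runif(npair), o = stats::runif(npair))
    })
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
    und <- draws$u < p_undirected
    dir <- !und & draws$u < p_undirected + p_directed
    fwd <- draws$o < 0.5
    src <- c(pair_i[und],
             ifelse(fwd[dir], pair_i[dir], pair_j[dir]))
    dst <- c(pair_j[und],
             ifelse(fwd[dir], pair_j[dir], pair_i[dir]))
    type <- c(rep(1L, sum(und)), rep(0L, sum(dir)))
    if (length(type)) {
      edges <- data.frame(src = ids[src], dst = ids[dst], type = type,
                          stringsAsFactors = FALSE)
    }
  }
  typed_graph(ids, edges, c("directed", "undirected"),
              labels = stats::setNames(rep("n", n), ids))
}

#' One permutation trial of the canonical labeler
#'
#' Applies a seeded uniformly random permutation to the vertices of `g`
#' (also shuffling the stored vertex order) and reports whether the
#' canonical labels of the original and the permuted copy agree -- which
#' they must, for a correct labeler.
#'
#' @param g A [typed_graph()].
#' @param seed Integer seed for the permutation.
#' @return `TRUE` if the labels agree.
#' @export
permutation_trial <- function(g, seed = 1L) {
  stopifnot(inherits(g, "typed_graph"))
  v <- g$vertices
  sigma <- with_seed(seed, {
    list(img = sample(v), ord = sample(v))
  })
  h <- permute_graph(g, stats::setNames(sigma$img, v), new_order = sigma$ord)
  hnauty_canonical(g)$label == hnauty_canonical(h)$label
}

#' Randomized permutation self-test
#'
#' Samples `num_graphs` independent random graphs from [sample_graph()] and
#' runs [permutation_trial()] on each; a correct canonical labeler succeeds
#' every time.  Per-graph seeds are derived from `master_seed`, so any
#' failure is reproducible from the seed recorded in the `failures`
#' attribute.
#'
#' @param num_graphs Number of graphs to test.
#' @param n Vertices per graph.
#' @param p_undirected,p_directed Edge probabilities (see [sample_graph()]).
#' @param master_seed Integer master seed.
#' @return Integer count of successes, with attribute `failures`: the
#'   per-graph seeds of any failing trials.
#' @export
run_self_test <- function(num_graphs, n = 200L, p_undirected = 0.1,
                          p_directed = 0.05, master_seed = 1L) {
  if (num_graphs <= 0L) {
    return(structure(0L, failures = integer(0)))
  }
  seeds <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1L, 2L * num_graphs))
  ok <- logical(num_graphs)
  for (i in seq_len(num_graphs)) {
    g <- sample_graph(n, p_undirected, p_directed, seed = seeds[2L * i - 1L])
    ok[i] <- permutation_trial(g, seed = seeds[2L * i])
  }
  structure(sum(ok), failures = seeds[2L * which(!ok) - 1L])
}
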