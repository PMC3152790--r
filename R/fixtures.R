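# Worked fixtures: the Lck kinase, the TCR complex, and the small graphs
# used to exercise refinement, search and the oracles.  All builders are
# deterministic.

#' Lck molecular entity graph
#'
#' The lymphocyte-specific kinase Lck as a hierarchical molecular entity
#' graph: the Lck root contains the SH3, SH2 and PTK domains and the
#' regulatory tyrosine Y505; Y192 sits inside the SH2 domain and Y394 inside
#' the kinase (PTK) domain.  The three tyrosines carry the possible internal
#' states U (unphosphorylated) and P (phosphorylated), none assigned.
#'
#' @return A [hier_graph()] with `flavor = "entity"`.
#' @export
lck_entity <- function() {
  g <- typed_graph(
    vertices = c("Lck", "SH3", "SH2", "Y505", "PTK", "Y192", "Y394"),
    edges = data.frame(
      src = c("Lck", "Lck", "Lck", "Lck", "SH2", "PTK"),
      dst = c("SH3", "SH2", "Y505", "PTK", "Y192", "Y394"),
      type = 0L),
    directedness = c("directed", "undirected"),
    possible = list(Y192 = c("U", "P"), Y394 = c("U", "P"),
                    Y505 = c("U", "P"))
  )
  hier_graph(g, "entity")
}

#' Lck chemical species graph
#'
#' The chemical species graph of free Lck with Y192 and Y394
#' unphosphorylated, Y505 phosphorylated, and the SH2 domain bound
#' intramolecularly to phosphorylated Y505 (one undirected bond edge).
#' Encoding this graph in the vertex order
#' `Lck, SH3, SH2, Y505, PTK, Y192, Y394` gives the reference 7x7 adjacency
#' matrix: 1 in each parent-to-child entry, 2 in both `(SH2, Y505)` entries.
#'
#' @return A [hier_graph()] with `flavor = "species"`.
#' @export
lck_species <- function() {
  g <- typed_graph(
    vertices = c("Lck", "SH3", "SH2", "Y505", "PTK", "Y192", "Y394"),
    edges = data.frame(
      src = c("Lck", "Lck", "Lck", "Lck", "SH2", "PTK", "SH2"),
      dst = c("SH3", "SH2", "Y505", "PTK", "Y192", "Y394", "Y505"),
      type = c(0L, 0L, 0L, 0L, 0L, 0L, 1L)),
    directedness = c("directed", "undirected"),
    possible = list(Y192 = c("U", "P"), Y394 = c("U", "P"),
                    Y505 = c("U", "P")),
    attributes = c(Y192 = "U", Y394 = "U", Y505 = "P")
  )
  hier_graph(g, "species")
}

#' T-cell receptor complex graph
#'
#' The TCR complex as a (pseudo-)hierarchical molecular entity graph.  The
#' root contains the four dimeric subunits (alpha-beta, gamma-epsilon,
#' delta-epsilon, zeta-zeta), each containing its two polypeptide chains.
#' The CD3-epsilon chain carries a proline-rich sequence (PRS) and an ITAM
#' whose tyrosine Y188 belongs to both motifs, making the hierarchy a DAG
#' rather than a tree.  With `expanded = FALSE` only one chain carries its
#' motifs, mirroring the usual drawing; with `expanded = TRUE` every chain
#' is expanded (each zeta chain carries three ITAMs, every ITAM two
#' tyrosines) and the disulfide link inside each dimer is emitted as a bond
#' edge between the chain vertices.  All tyrosines share the label `Y` and
#' the possible states U/P; ids use transliterated Greek letters.
#'
#' @param expanded Expand every chain (and emit dimer bonds)?
#' @return A [hier_graph()] with `flavor = "entity"`.
#' @export
tcr_complex <- function(expanded = FALSE) {
  vs <- list()  # id, label
  es <- list()  # src, dst, type
  add_v <- function(id, label = id) vs[[length(vs) + 1L]] <<- c(id, label)
  add_e <- function(src, dst, type = 0L) {
    es[[length(es) + 1L]] <<- list(src, dst, as.integer(type))
  }
  tyrosines <- character(0)
  add_y <- function(id) {
    tyrosines <<- c(tyrosines, id)
    add_v(id, "Y")
  }
  add_itam <- function(chain, tag, n_y = 2L) {
    id <- paste0("ITAM_", tag)
    add_v(id, "ITAM")
    add_e(chain, id)
    ys <- paste0("Y_", tag, "_", seq_len(n_y))
    for (y in ys) {
      add_y(y)
      add_e(id, y)
    }
    id
  }
  # CD3-epsilon: PRS and ITAM overlap at Y188
  add_epsilon_motifs <- function(chain, tag) {
    prs <- paste0("PRS_", tag)
    itam <- paste0("ITAM_", tag)
    y188 <- paste0("Y188_", tag)
    y199 <- paste0("Y199_", tag)
    add_v(prs, "PRS")
    add_v(itam, "ITAM")
    add_e(chain, prs)
    add_e(chain, itam)
    add_y(y188)
    add_y(y199)
    add_e(prs, y188)
    add_e(itam, y188)
    add_e(itam, y199)
  }

  add_v("TCR")
  dimers <- list(
    alphabeta = c("alpha", "beta"),
    gammaepsilon = c("gamma", "epsilon1"),
    deltaepsilon = c("delta", "epsilon2"),
    zetazeta = c("zeta1", "zeta2")
  )
  chain_label <- c(alpha = "alpha", beta = "beta", gamma = "gamma",
                   epsilon1 = "epsilon", epsilon2 = "epsilon",
                   delta = "delta", zeta1 = "zeta", zeta2 = "zeta")
  for (d in names(dimers)) {
    add_v(d)
    add_e("TCR", d)
    for (chain in dimers[[d]]) {
      add_v(chain, chain_label[[chain]])
      add_e(d, chain)
    }
    if (expanded) add_e(dimers[[d]][1L], dimers[[d]][2L], 1L)
  }
  if (expanded) {
    add_itam("gamma", "g")
    add_itam("delta", "d")
    add_epsilon_motifs("epsilon1", "e1")
    add_epsilon_motifs("epsilon2", "e2")
    for (z in c("z1", "z2")) {
      chain <- if (z == "z1") "zeta1" else "zeta2"
      for (k in 1:3) add_itam(chain, paste0(z, "_", k))
    }
  } else {
    add_epsilon_motifs("epsilon1", "e1")
  }

  ids <- vapply(vs, `[`, character(1), 1L)
  labels <- stats::setNames(vapply(vs, `[`, character(1), 2L), ids)
  edges <- data.frame(
    src = vapply(es, function(e) e[[1L]], character(1)),
    dst = vapply(es, function(e) e[[2L]], character(1)),
    type = vapply(es, function(e) e[[3L]], integer(1)),
    stringsAsFactors = FALSE)
  g <- typed_graph(ids, edges, c("directed", "undirected"),
                   labels = labels,
                   possible = stats::setNames(
                     rep(list(c("U", "P")), length(tyrosines)), tyrosines))
  hier_graph(g, "entity")
}

#' Worked five-vertex example graphs
#'
#' `fixture_g1()` is the complete bipartite graph on `{v2, v4}` against
#' `{v1, v3, v5}` (edges join vertices of different index parity);
#' `fixture_g2()` is the 5-cycle `v1..v5` plus the chord `v1-v3`.  Both have
#' one undirected edge type, one vertex color, and matching degree sequences
#' (two vertices of degree 3, three of degree 2), yet they are not
#' isomorphic: their coarsest equitable partitions already have different
#' shapes.
#'
#' @return A [typed_graph()] with a single undirected edge type.
#' @export
fixture_g1 <- function() {
  ids <- paste0("v", 1:5)
  pairs <- t(utils::combn(1:5, 2))
  odd <- (pairs[, 1L] - pairs[, 2L]) %% 2L == 1L
  typed_graph(ids,
              data.frame(src = ids[pairs[odd, 1L]],
                         dst = ids[pairs[odd, 2L]], type = 0L),
              "undirected",
              labels = stats::setNames(rep("v", 5L), ids))
}

#' @rdname fixture_g1
#' @export
fixture_g2 <- function() {
  ids <- paste0("v", 1:5)
  typed_graph(ids,
              data.frame(src = c("v1", "v2", "v3", "v4", "v5", "v1"),
                         dst = c("v2", "v3", "v4", "v5", "v1", "v3"),
                         type = 0L),
              "undirected",
              labels = stats::setNames(rep("v", 5L), ids))
}

#' Three isomorphic copies of a four-vertex graph
#'
#' A base graph `G` (the 4-cycle `v1-v2-v3-v4-v1`; the structure is a
#' synthetic reconstruction satisfying the defining constraints of the
#' worked example: swapping `v2` and `v4` is an automorphism of `G` while
#' swapping `v3` and `v4` is not) together with its images under the
#' permutation `pi1 = (v3 v4)` and `pi2 = (v2 v4)`.  All three graphs are
#' isomorphic and must share one canonical label; only `pi2` is an
#' automorphism of `G`.
#'
#' @return A list of three [typed_graph()]s with attributes `pi1` and `pi2`
#'   (the named permutation vectors).
#' @export
fig5_triple <- function() {
  ids <- paste0("v", 1:4)
  g <- typed_graph(ids,
                   data.frame(src = c("v1", "v2", "v3", "v4"),
                              dst = c("v2", "v3", "v4", "v1"), type = 0L),
                   "undirected",
                   labels = stats::setNames(rep("v", 4L), ids))
  pi1 <- stats::setNames(c("v1", "v2", "v4", "v3"), ids)
  pi2 <- stats::setNames(c("v1", "v4", "v3", "v2"), ids)
  structure(list(g = g,
                 via_pi1 = permute_graph(g, pi1),
                 via_pi2 = permute_graph(g, pi2)),
            pi1 = pi1, pi2 = pi2)
}

#' Fixture catalog
#'
#' Named deterministic builders for every shipped fixture, used by the
#' command-line `fixtures` subcommand and the tests.
#'
#' @return `fixture_names()`: a character vector.  `build_fixture(name)`:
#'   the corresponding graph (for `"fig5_triple"`, the list of three).
#' @export
fixture_names <- function() {
  c("lck_entity", "lck_species", "tcr_complex", "tcr_complex_expanded",
    "g1", "g2", "fig5_triple")
}

#' @rdname fixture_names
#' @param name One of `fixture_names()`.
#' @export
build_fixture <- function(name) {
  switch(match.arg(name, fixture_names()),
         lck_entity = lck_entity(),
         lck_species = lck_species(),
         tcr_complex = tcr_complex(FALSE),
         tcr_complex_expanded = tcr_complex(TRUE),
         g1 = fixture_g1(),
         g2 = fixture_g2(),
         fig5_triple = fig5_triple())
}
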