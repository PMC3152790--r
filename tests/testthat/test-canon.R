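test_that("the initial partition groups and orders vertices by color", {
  g <- rand_single(4, 0.5, 1)
  expect_true(is_trivial(initial_partition(g)))
  expect_true(is_discrete(initial_partition(lck_species())))
  # assigned attribute is folded into the color; cells in byte-lex order
  two <- typed_graph(c("a", "b"), NULL, "undirected",
                     labels = c(a = "Y", b = "Y"),
                     possible = list(a = c("U", "P"), b = c("U", "P")),
                     attributes = c(a = "U", b = "P"))
  p <- initial_partition(two)
  expect_identical(cells(p), list("b", "a"))  # "P" sorts before "U"
})

test_that("the unpruned search yields the worked discrete partitions", {
  lv <- enumerate_leaves(fixture_g2(), pruning = "none")
  expect_length(lv, 2L)
  expect_identical(cells(lv[[1]]),
                   list("v1", "v3", "v2", "v4", "v5"))
  expect_identical(cells(lv[[2]]),
                   list("v3", "v1", "v2", "v5", "v4"))

  # an edgeless same-color graph has a full automorphism group, so every
  # discrete partition appears
  e3 <- rand_single(3, 0, 1)
  expect_length(enumerate_leaves(e3, pruning = "none"), 6L)

  # complete bipartite K_{2,3}: all orderings with the two degree-3
  # vertices first
  lv1 <- enumerate_leaves(fixture_g1(), pruning = "none")
  expect_length(lv1, 12L)
  for (p in lv1) {
    expect_setequal(unlist(p[1:2]), c("v2", "v4"))
  }
})

test_that("equal-matrix leaves yield verified automorphisms", {
  lv <- enumerate_leaves(fixture_g2(), pruning = "none")
  gamma <- discover_automorphism(fixture_g2(), lv[[1]], lv[[2]])
  expect_identical(gamma,
                   c(v1 = "v3", v2 = "v2", v3 = "v1", v4 = "v5", v5 = "v4"))
  id <- discover_automorphism(fixture_g2(), lv[[1]], lv[[1]])
  expect_identical(unname(id), names(id))

  # a rigid graph: two different leaves of anything rigid can never match;
  # certify rigidity by brute force first
  rigid <- NULL
  for (seed in 1:50) {
    g <- rand_single(6, 0.5, seed)
    if (length(brute_automorphisms(g)) == 1L) {
      rigid <- g
      break
    }
  }
  expect_false(is.null(rigid))
  d1 <- ordered_partition(as.list(rigid$vertices), rigid$vertices)
  d2 <- ordered_partition(as.list(rev(rigid$vertices)), rigid$vertices)
  expect_null(discover_automorphism(rigid, d1, d2))
})

test_that("canonical labels are invariant under relabeling and reordering", {
  cases <- c(list(lck_species(), tcr_complex(FALSE), tcr_complex(TRUE),
                  fixture_g1(), fixture_g2()),
             lapply(1:10, function(s) sample_graph(8, 0.3, 0.2, seed = s)))
  for (g in cases) {
    ref <- hnauty_canonical(g)$label
    for (s in 1:3) {
      expect_identical(hnauty_canonical(shuffled_copy(g, s))$label, ref)
    }
  }
})

test_that("label equality agrees with brute-force isomorphism", {
  set.seed(17)
  suite <- lapply(1:30, function(s) sample_graph(6, 0.35, 0.25, seed = s))
  labs <- vapply(suite, function(g) hnauty_canonical(g)$label, character(1))
  bru <- vapply(suite, brute_canonical, character(1))
  for (i in 1:29) {
    for (j in (i + 1):30) {
      expect_identical(labs[i] == labs[j], bru[i] == bru[j])
    }
  }
})

test_that("isomorphism testing agrees with igraph VF2 on plain graphs", {
  to_igraph <- function(g) {
    igraph::graph_from_data_frame(g$edges[c("src", "dst")],
                                  directed = FALSE,
                                  vertices = data.frame(name = g$vertices))
  }
  for (seed in 1:20) {
    g <- rand_single(7, 0.4, seed)
    h <- if (seed %% 2 == 0) {
      shuffled_copy(g, seed + 30)
    } else {
      rand_single(7, 0.4, seed + 300)
    }
    expect_identical(
      are_isomorphic(g, h),
      igraph::isomorphic(to_igraph(g), to_igraph(h), method = "vf2"))
  }
})

test_that("pruned and unpruned searches agree and pruning never explores
          more nodes", {
  cases <- c(list(fixture_g1(), fixture_g2(), lck_species(),
                  tcr_complex(TRUE), rand_single(3, 0, 1),
                  all_single_graphs(4)[[64]]),
             lapply(1:8, function(s) sample_graph(7, 0.35, 0.25, seed = s)))
  for (g in cases) {
    full <- enumerate_leaves(g, pruning = "none")
    auto <- enumerate_leaves(g, pruning = "auto")
    both <- enumerate_leaves(g, pruning = "auto+ind")
    expect_lte(attr(auto, "n_nodes"), attr(full, "n_nodes"))
    expect_lte(attr(both, "n_nodes"), attr(auto, "n_nodes"))
    labs <- vapply(c("none", "auto", "auto+ind"), function(m) {
      hnauty_canonical(g, pruning = m)$label
    }, character(1))
    expect_length(unique(labs), 1L)
  }
})

test_that("discovered generators are genuine automorphisms", {
  for (g in list(fixture_g1(), fixture_g2(), tcr_complex(TRUE))) {
    cf <- hnauty_canonical(g)
    for (gamma in cf$generators) {
      expect_true(is_automorphism(g, gamma))
    }
  }
})

test_that("automorphism group orders match brute-force enumeration", {
  expect_identical(automorphism_count(fixture_g2()), 2L)
  expect_identical(automorphism_count(fixture_g1()), 12L)
  k4 <- all_single_graphs(4)[[64]]
  expect_identical(automorphism_count(k4), 24L)
  for (seed in 1:10) {
    g <- sample_graph(6, 0.3, 0.25, seed = seed)
    expect_identical(automorphism_count(g),
                     length(brute_automorphisms(g)))
  }
  for (seed in 1:6) {
    g <- rand_single(6, 0.5, seed)
    expect_identical(automorphism_count(g),
                     length(brute_automorphisms(g)))
  }
})

test_that("isomorphism verdicts match the worked examples", {
  tr <- fig5_triple()
  expect_true(are_isomorphic(tr$g, tr$via_pi1))
  expect_true(are_isomorphic(tr$g, tr$via_pi2))
  expect_true(are_isomorphic(tr$via_pi1, tr$via_pi2))
  expect_false(are_isomorphic(fixture_g1(), fixture_g2()))
  expect_true(are_isomorphic(lck_species(), lck_species()))
  expect_error(are_isomorphic(fixture_g1(), lck_species()),
               "incompatible")
})

test_that("graphs differing only in colors or attributes get distinct
          labels", {
  a <- typed_graph(c("x", "y"),
                   data.frame(src = "x", dst = "y", type = 0L),
                   "undirected", labels = c(x = "A", y = "A"))
  b <- typed_graph(c("x", "y"),
                   data.frame(src = "x", dst = "y", type = 0L),
                   "undirected", labels = c(x = "B", y = "B"))
  expect_false(are_isomorphic(a, b))
  u <- typed_graph("s", NULL, "undirected", labels = c(s = "Y"),
                   possible = list(s = c("U", "P")),
                   attributes = c(s = "U"))
  p <- typed_graph("s", NULL, "undirected", labels = c(s = "Y"),
                   possible = list(s = c("U", "P")),
                   attributes = c(s = "P"))
  expect_false(are_isomorphic(u, p))
})
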