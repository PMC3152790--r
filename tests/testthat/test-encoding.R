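lck_table <- matrix(
  c(0, 1, 1, 1, 1, 0, 0,
    0, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 2, 0, 1, 0,
    0, 0, 2, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 0, 1,
    0, 0, 0, 0, 0, 0, 0,
    0, 0, 0, 0, 0, 0, 0),
  nrow = 7, byrow = TRUE,
  dimnames = rep(list(c("Lck", "SH3", "SH2", "Y505", "PTK",
                        "Y192", "Y394")), 2))
storage.mode(lck_table) <- "integer"

test_that("the Lck species graph encodes to the reference matrix", {
  a <- encode_adjacency(lck_species(),
                        c("Lck", "SH3", "SH2", "Y505", "PTK",
                          "Y192", "Y394"))
  expect_identical(unclass(a)[,], lck_table[,])
  expect_identical(a[["SH2", "Y505"]], 2L)
  expect_identical(a[["Y505", "SH2"]], 2L)
  expect_identical(a[["Lck", "SH3"]], 1L)
  expect_identical(a[["SH3", "Lck"]], 0L)
})

test_that("encoding follows the power-of-two per-type convention", {
  g <- typed_graph(c("a", "b"),
                   data.frame(src = "a", dst = "b", type = 1L),
                   c("directed", "undirected"))
  a <- unclass(encode_adjacency(g))
  expect_identical(a[,], matrix(c(0L, 2L, 2L, 0L), 2,
                                dimnames = list(c("a", "b"),
                                                c("a", "b")))[,])
  edgeless <- typed_graph(letters[1:3], NULL, c("directed", "undirected"))
  expect_true(all(unclass(encode_adjacency(edgeless)) == 0L))
  expect_error(encode_adjacency(g, c("a", "a")), "permutation")
})

test_that("permuting the order conjugates the encoding", {
  g <- sample_graph(8, 0.3, 0.2, seed = 5)
  ord <- g$vertices
  set.seed(9)
  pord <- sample(ord)
  a <- unclass(encode_adjacency(g, ord))
  b <- unclass(encode_adjacency(g, pord))
  expect_identical(a[pord, pord], b[,])
})

test_that("decode inverts encode, and rejects corrupted matrices", {
  a <- encode_adjacency(lck_species())
  g2 <- decode_adjacency(a, labels = lck_species()$labels,
                         possible = lck_species()$possible,
                         attributes = lck_species()$attributes)
  expect_same_graph(g2, lck_species())
  expect_identical(sum(g2$edges$type == 0L), 6L)
  expect_identical(sum(g2$edges$type == 1L), 1L)

  zero <- matrix(0L, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  expect_identical(nrow(decode_adjacency(
    zero, c("directed", "undirected"))$edges), 0L)

  for (seed in 1:100) {
    g <- sample_graph(8, 0.25, 0.2, seed = seed)
    expect_same_graph(
      decode_adjacency(encode_adjacency(g), labels = g$labels), g)
  }

  bad <- matrix(c(0L, 2L, 0L, 0L), 2, dimnames = rep(list(c("a", "b")), 2))
  expect_error(decode_adjacency(bad, c("directed", "undirected")),
               "asymmetric")
  over <- matrix(c(0L, 9L, 0L, 0L), 2, dimnames = rep(list(c("a", "b")), 2))
  expect_error(decode_adjacency(over, c("directed", "undirected")),
               "out of range")
})

test_that("flattening inserts one typed marker vertex per edge", {
  f <- flatten(lck_species())
  expect_identical(length(f$vertices), 14L)
  expect_identical(nrow(f$edges), 14L)
  expect_identical(f$m, 1L)
  expect_identical(sum(f$labels == "e:h"), 6L)
  expect_identical(sum(f$labels == "e:b"), 1L)

  e0 <- typed_graph(letters[1:3], NULL, c("directed", "undirected"))
  f0 <- flatten(e0)
  expect_identical(f0$vertices, e0$vertices)
  expect_identical(nrow(f0$edges), 0L)
})

test_that("flattening preserves and reflects isomorphism", {
  # isomorphic pairs: a graph and a relabeled copy
  for (seed in 1:25) {
    g <- sample_graph(6, 0.3, 0.25, seed = seed)
    h <- shuffled_copy(g, seed = seed + 100)
    expect_true(are_isomorphic(flatten(g), flatten(h)))
  }
  # non-isomorphic pairs, certified by the brute-force label
  found <- 0L
  for (seed in 1:40) {
    g <- sample_graph(5, 0.35, 0.25, seed = seed)
    h <- sample_graph(5, 0.35, 0.25, seed = seed + 500)
    if (brute_canonical(g) != brute_canonical(h)) {
      found <- found + 1L
      expect_false(are_isomorphic(flatten(g), flatten(h)))
    }
  }
  expect_gt(found, 10L)
})

test_that("the adjacency list mirrors the per-type neighbor structure", {
  al <- as_adjacency_list(lck_species())
  expect_identical(sort(names(al[["Lck"]])),
                   sort(c("SH3", "SH2", "Y505", "PTK")))
  expect_identical(sort(unname(unlist(al[["SH2"]][["Y505"]]))), c(1L))
  expect_identical(unname(unlist(al[["Y505"]][["SH2"]])), 1L)
  expect_identical(unname(unlist(al[["Lck"]][["SH3"]])), 0L)
  expect_null(al[["SH3"]][["Lck"]])
})
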