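test_that("graph construction validates vertices, edges and attributes", {
  g <- typed_graph(c("a", "b", "c"), NULL, "undirected")
  expect_s3_class(g, "typed_graph")
  expect_identical(nrow(g$edges), 0L)

  expect_error(typed_graph(c("a", "a")), "duplicate vertex")
  expect_error(
    typed_graph(c("a", "b"),
                data.frame(src = "a", dst = "z", type = 0L)),
    "not a declared vertex")
  expect_error(
    typed_graph(c("a", "b"),
                data.frame(src = c("a", "a"), dst = c("b", "b"),
                           type = c(0L, 0L))),
    "duplicate edge")
  # undirected edges are normalized, so reversed duplicates collide too
  expect_error(
    typed_graph(c("a", "b"),
                data.frame(src = c("a", "b"), dst = c("b", "a"),
                           type = c(1L, 1L))),
    "duplicate edge")
  expect_error(
    typed_graph(c("a", "b"),
                data.frame(src = "a", dst = "b", type = 5L)),
    "out of range")
  expect_error(
    typed_graph(c("a", "b"),
                data.frame(src = "a", dst = "a", type = 0L)),
    "self-edges")
  expect_error(
    typed_graph("a", possible = list(a = c("U", "P")),
                attributes = c(a = "Q")),
    "not in its possible list")
})

test_that("the Lck species fixture has the documented structure", {
  g <- lck_species()
  expect_identical(length(g$vertices), 7L)
  expect_identical(nrow(g$edges), 7L)
  expect_identical(sum(g$edges$type == 0L), 6L)
  expect_identical(sum(g$edges$type == 1L), 1L)
  expect_identical(attr(g, "flavor"), "species")
  expect_identical(unname(g$attributes[c("Y192", "Y394", "Y505")]),
                   c("U", "U", "P"))
})

test_that("hierarchy classification distinguishes trees, DAGs and cycles", {
  expect_identical(classify_hierarchy(lck_species()), "strict_hierarchy")
  expect_identical(classify_hierarchy(tcr_complex(FALSE)),
                   "pseudo_hierarchy")
  expect_identical(classify_hierarchy(tcr_complex(TRUE)),
                   "pseudo_hierarchy")
  cyc <- typed_graph(c("a", "b"),
                     data.frame(src = c("a", "b"), dst = c("b", "a"),
                                type = 0L),
                     c("directed", "undirected"))
  expect_identical(classify_hierarchy(cyc), "invalid")
  # invariance under renaming
  for (g in list(lck_species(), tcr_complex(FALSE))) {
    h <- permute_graph(g, rand_perm(g, seed = 11))
    expect_identical(classify_hierarchy(h), classify_hierarchy(g))
  }
})

test_that("attribute assignment turns an entity graph into a species graph", {
  ent <- lck_entity()
  expect_identical(attr(ent, "flavor"), "entity")
  # entity + intramolecular bond + full assignment reproduces the species
  # fixture exactly
  with_bond <- hier_graph(
    typed_graph(ent$vertices,
                rbind(ent$edges,
                      data.frame(src = "SH2", dst = "Y505", type = 1L)),
                ent$directedness, labels = ent$labels,
                possible = ent$possible),
    "entity")
  sp <- assign_attributes(with_bond, c(Y192 = "U", Y394 = "U", Y505 = "P"))
  expect_identical(attr(sp, "flavor"), "species")
  expect_same_graph(sp, lck_species())
  expect_identical(sp$labels, with_bond$labels)

  # no attributed vertices: the empty assignment is the species graph
  plain <- hier_graph(
    typed_graph(c("a", "b"),
                data.frame(src = "a", dst = "b", type = 0L),
                c("directed", "undirected")),
    "entity")
  sp2 <- assign_attributes(plain, character(0))
  expect_same_graph(sp2, plain)

  expect_error(assign_attributes(with_bond, c(Y192 = "U", Y394 = "U",
                                              Y505 = "Q")),
               "not in its possible list")
  expect_error(assign_attributes(with_bond, c(Y192 = "U")),
               "cover exactly")
  expect_error(assign_attributes(sp, c(Y192 = "U", Y394 = "U",
                                       Y505 = "P")),
               "flavor")
})

test_that("species graphs require every attributed vertex to be assigned", {
  g <- typed_graph(c("m", "y"),
                   data.frame(src = "m", dst = "y", type = 0L),
                   c("directed", "undirected"),
                   possible = list(y = c("U", "P")))
  expect_error(hier_graph(g, "species"), "unassigned")
  expect_s3_class(hier_graph(g, "entity"), "hier_graph")
})
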