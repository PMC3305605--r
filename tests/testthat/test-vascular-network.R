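test_that("Strahler ordering follows the confluence rules", {
  # two order-1 children meeting raise the parent to order 2
  g <- tree_graph(parents = c(1, 2, 2), children = c(2, 3, 4),
                  orders = c(2L, 1L, 1L))
  so <- assign_strahler_orders(g, root = 1)
  expect_equal(unname(so$edge_orders[c("2", "3")]), c(1L, 1L))
  expect_equal(unname(so$edge_orders["1"]), 2L)
  # an order-3 branch meeting an order-1 branch keeps order 3
  #        1 -e1- 2; below 2: a full order-3 subtree and a single leaf
  g2 <- tree_graph(
    parents  = c(1, 2, 2, 3, 3, 4, 4, 5, 5),
    children = c(2, 3, 9, 4, 5, 6, 7, 8, 10),
    orders   = c(3L, 3L, 1L, 2L, 2L, 1L, 1L, 1L, 1L))
  so2 <- assign_strahler_orders(g2, root = 1)
  expect_equal(unname(so2$edge_orders["2"]), 3L)  # order-3 subtree root
  expect_equal(unname(so2$edge_orders["1"]), 3L)  # 3 meets 1 -> stays 3
  # a single edge is an order-1 vessel
  g3 <- chain_graph(1)
  so3 <- assign_strahler_orders(g3, root = 1)
  expect_equal(unname(so3$edge_orders), 1L)
})

test_that("Strahler ordering rejects cyclic and disconnected input", {
  nodes <- data.frame(id = 1:3, x = 0, y = 0, z = 0, kind = "regular",
                      z_offset = 0)
  edges <- data.frame(id = 1:3, node_a = c(1, 2, 3), node_b = c(2, 3, 1),
                      diameter = 1e-5, length = 1e-4, strahler_order = 1L,
                      vessel_class = "artery", compliance = 0)
  cyc <- vascular_graph(nodes, edges, validate = FALSE)
  expect_error(assign_strahler_orders(cyc, 1), "cycle")
})

test_that("generated trees carry morphometric dimensions and leaf counts", {
  tr <- build_strahler_tree(4, horsfield_arterial(), 21, "arterial")
  expect_equal(sum(tr$edges$strahler_order == 1L), 21L)
  o4 <- tr$edges[tr$edges$strahler_order == 4L, ]
  expect_equal(unique(o4$diameter), 0.054e-3)
  expect_equal(unique(o4$length), 0.44e-3)
  # relabeling from scratch reproduces the generation labels (idempotence)
  root <- tr$nodes$id[tr$nodes$kind == "boundary_arterial"]
  so <- assign_strahler_orders(tr, root)
  expect_equal(unname(so$edge_orders[as.character(tr$edges$id)]),
               tr$edges$strahler_order)
  # orders are non-increasing from root to leaves along every path
  for (k in seq_len(nrow(tr$edges))) {
    child_edges <- tr$edges[tr$edges$node_a == tr$edges$node_b[k], ]
    if (nrow(child_edges))
      expect_true(all(child_edges$strahler_order <=
                        tr$edges$strahler_order[k]))
  }
  # power-of-two leaf count gives a perfectly balanced dichotomy
  tr8 <- build_strahler_tree(4, horsfield_arterial(), 8, "arterial")
  expect_equal(sum(tr8$edges$strahler_order == 1L), 8L)
  expect_equal(nrow(tr8$edges), 8L + 4L + 2L + 1L)
  # infeasible request is rejected with an explanation
  expect_error(build_strahler_tree(4, horsfield_arterial(), 5, "arterial"),
               "infeasible")
})

test_that("the coupled example network has the documented structure", {
  g <- build_coupled_example()
  ups <- g$nodes[startsWith(g$nodes$kind, "upscaled"), ]
  expect_equal(nrow(ups), 21L)
  expect_equal(sum(ups$kind == "upscaled_tumor"), 3L)
  expect_silent(validate_graph(g))
  deg <- table(c(g$edges$node_a, g$edges$node_b))
  expect_true(all(deg[as.character(ups$id)] == 2L))
  # the smallest valid scenario: one arteriole, one venule, one alveolus
  g1 <- build_coupled_example(n_alveoli = 1, tumor_ids = integer(0))
  expect_equal(sum(startsWith(g1$nodes$kind, "upscaled")), 1L)
  expect_equal(sum(g1$edges$vessel_class == "arteriole"), 1L)
  expect_equal(sum(g1$edges$vessel_class == "venule"), 1L)
  # tumor assignment is labeling only
  g0 <- build_coupled_example(tumor_ids = integer(0))
  expect_identical(g0$edges, g$edges)
  expect_true(all(g0$nodes$kind[startsWith(g0$nodes$kind, "upscaled")] ==
                    "upscaled_healthy"))
  expect_error(build_coupled_example(n_alveoli = 0), "n_alveoli")
})

test_that("graph JSON round-trip is value-exact and validates fields", {
  g <- build_coupled_example(n_alveoli = 5, tumor_ids = 2)
  tf <- withr::local_tempfile(fileext = ".json")
  write_graph(g, tf, "json")
  g2 <- read_graph(tf, "json")
  expect_equal(g2$nodes, g$nodes, tolerance = 0)
  expect_equal(g2$edges, g$edges, tolerance = 0)
  # a file missing a mandatory edge attribute is rejected by name
  doc <- jsonlite::read_json(tf, simplifyVector = TRUE)
  doc$edges$diameter <- NULL
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, tf2, auto_unbox = TRUE, digits = I(17))
  expect_error(read_graph(tf2, "json"), "diameter")
  # unit declaration is checked
  doc2 <- jsonlite::read_json(tf, simplifyVector = TRUE)
  doc2$units$length <- "mm"
  tf3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc2, tf3, auto_unbox = TRUE, digits = I(17))
  expect_error(read_graph(tf3, "json"), "unit")
})

test_that("GraphML export preserves typed attributes and round-trips", {
  g <- build_coupled_example(n_alveoli = 3, tumor_ids = 1)
  tf <- withr::local_tempfile(fileext = ".graphml")
  write_graph(g, tf, "graphml")
  doc <- xml2::read_xml(tf)
  xml2::xml_ns_strip(doc)
  key <- xml2::xml_find_first(doc, ".//key[@attr.name='kind']")
  expect_equal(xml2::xml_attr(key, "attr.type"), "string")
  g2 <- read_graph(tf, "graphml")
  o <- order(g2$nodes$id)
  expect_equal(g2$nodes[o, ], g$nodes, ignore_attr = TRUE)
  oe <- order(g2$edges$id)
  expect_equal(g2$edges[oe, ], g$edges, ignore_attr = TRUE)
})

test_that("graph validation catches invariant violations", {
  g <- build_coupled_example(n_alveoli = 2)
  bad <- g
  bad$edges$diameter[1] <- -1
  expect_error(validate_graph(bad), "positive")
  bad2 <- g
  bad2$edges <- rbind(bad2$edges, bad2$edges[1, ])
  bad2$edges$id[nrow(bad2$edges)] <- max(g$edges$id) + 1L
  expect_error(validate_graph(bad2), "duplicate edge")
})
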