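test_that("activity profiles count zero entries as case exceptions", {
  m <- indicator_matrix(matrix(c(1L, 1L, 1L, 0L,
                                 1L, 1L, 1L, 1L), 2, 4, byrow = TRUE,
                               dimnames = list(c("g1", "g2"), NULL)))
  a1 <- compute_activity(m, 1)
  expect_true(a1$is_active[a1$gene == "g1"])   # 1 exception <= 1
  a0 <- compute_activity(m, 0)
  expect_false(a0$is_active[a0$gene == "g1"])  # 1 exception > 0
  expect_true(a0$is_active[a0$gene == "g2"])   # all-ones row
  # unmeasured genes are maximally inactive
  a <- compute_activity(m, 2, genes = c("g1", "g2", "g9"))
  expect_equal(a$exception_count[a$gene == "g9"], 4L)
  expect_false(a$is_active[a$gene == "g9"])
})

test_that("solution validity enforces connectivity and exception budgets", {
  g <- mk_graph(c("A-B", "B-C"), isolated = "D")
  m <- indicator_matrix(matrix(c(1L, 0L, 1L, 1L), 4, 1,
                               dimnames = list(c("A", "B", "C", "D"), NULL)))
  act <- compute_activity(m, 0, genes = igraph::V(g)$name)
  k0 <- extraction_config("INES", k = 0)
  k1 <- extraction_config("INES", k = 1)
  expect_false(is_valid_solution(c("A", "B", "C"), g, act, k0)) # B inactive
  expect_true(is_valid_solution(c("A", "B", "C"), g, act, k1))
  expect_false(is_valid_solution(c("A", "C"), g, act, k1))      # disconnected
  expect_true(is_valid_solution(c("A", "B"), g, act, k1))
  expect_false(is_valid_solution(c("A", "D"), g, act, k1))      # D isolated
  # GLONE: budget on total case exceptions
  gl <- extraction_config("GLONE", l = 1)
  expect_true(is_valid_solution(c("A", "B", "C"), g, act, gl))  # B costs 1
  gl0 <- extraction_config("GLONE", l = 0)
  expect_false(is_valid_solution(c("A", "B", "C"), g, act, gl0))
})

test_that("greedy extraction covers trivial and degenerate cases", {
  g <- mk_graph(c("A-B", "B-C", "C-A"))
  ones <- indicator_matrix(matrix(1L, 3, 2,
                                  dimnames = list(c("A", "B", "C"), NULL)))
  act <- compute_activity(ones, 0, genes = igraph::V(g)$name)
  sols <- greedy_extract(g, act, extraction_config("INES", k = 0))
  expect_length(sols, 1)
  expect_equal(sols[[1]]$nodes, c("A", "B", "C"))

  zeros <- indicator_matrix(matrix(0L, 3, 2,
                                   dimnames = list(c("A", "B", "C"), NULL)))
  act0 <- compute_activity(zeros, 0, genes = igraph::V(g)$name)
  expect_length(greedy_extract(g, act0, extraction_config("INES", k = 0)), 0)
  expect_length(greedy_extract(igraph::make_empty_graph(0) |>
                                 igraph::set_vertex_attr("name", value = character(0)),
                               act0, extraction_config("INES", k = 0)), 0)
})

test_that("greedy recovers a strongly planted module, checked against exact", {
  inst <- generate_synthetic_instance(
    synthetic_spec(n_nodes = 12, attachment = 1, module_size = 6,
                   n_cases = 8, p_active_in_module = 1,
                   p_active_background = 0, seed = 42))
  cfg_g <- extraction_config("INES", "greedy", k = 1, l = 0)
  cfg_e <- extraction_config("INES", "exact", k = 1, l = 0)
  act <- compute_activity(inst$matrix, 0, genes = igraph::V(inst$network)$name)
  top <- largest_solution(greedy_extract(inst$network, act, cfg_g))
  expect_true(all(inst$gold %in% top$nodes))
  best <- exact_extract(inst$network, act, cfg_e)
  expect_gte(best$size, top$size)
  expect_true(all(inst$gold %in% best$nodes))
})

test_that("exact extraction solves the inactive-hub star exactly", {
  g <- mk_graph(c("h-a", "h-b", "h-c", "h-d"))
  m <- indicator_matrix(matrix(c(0L, 1L, 1L, 1L, 1L), 5, 1,
                               dimnames = list(c("h", "a", "b", "c", "d"), NULL)))
  act <- compute_activity(m, 0, genes = igraph::V(g)$name)
  p0 <- exact_extract(g, act, extraction_config("INES", "exact", k = 0))
  expect_equal(p0$nodes, "a") # leaves disconnect without the hub; smallest id
  p1 <- exact_extract(g, act, extraction_config("INES", "exact", k = 1))
  expect_setequal(p1$nodes, c("h", "a", "b", "c", "d"))
  # triangle of active nodes is fully feasible at K = 0
  tri <- mk_graph(c("x-y", "y-z", "z-x"))
  mt <- indicator_matrix(matrix(1L, 3, 1, dimnames = list(c("x", "y", "z"), NULL)))
  at <- compute_activity(mt, 0, genes = igraph::V(tri)$name)
  expect_setequal(exact_extract(tri, at,
                                extraction_config("INES", "exact"))$nodes,
                  c("x", "y", "z"))
  expect_error(exact_extract(rand_connected_graph(16), at,
                             extraction_config("INES", "exact")),
               "limited to 15")
})

test_that("GLONE with an unbounded budget returns the full component", {
  withr::local_seed(5)
  g <- rand_connected_graph(9)
  m <- rand_matrix(g, 3)
  l_free <- ncol(m) * igraph::vcount(g) # budget can never bind
  cfg <- extraction_config("GLONE", "greedy", l = l_free)
  act <- compute_activity(m, ncol(m), genes = igraph::V(g)$name)
  top <- largest_solution(greedy_extract(g, act, cfg))
  expect_setequal(top$nodes, igraph::V(g)$name)
})

test_that("both extractors only ever return valid, deduplicated solutions", {
  withr::local_seed(99)
  for (rep in 1:25) {
    g <- rand_connected_graph(sample(4:9, 1))
    m <- rand_matrix(g)
    strategy <- sample(c("INES", "GLONE"), 1)
    cfg <- extraction_config(strategy, "greedy",
                             k = sample(0:2, 1), l = sample(0:3, 1))
    act <- compute_activity(m, suppressWarnings(resolve_l(cfg$l, ncol(m))),
                            genes = igraph::V(g)$name)
    sols <- greedy_extract(g, act, cfg)
    keys <- vapply(sols, function(p) paste(p$nodes, collapse = "|"), "")
    expect_equal(anyDuplicated(keys), 0L)
    for (p in sols)
      expect_true(suppressWarnings(is_valid_solution(p, g, act, cfg)))
    if (length(sols) > 1) {
      sizes <- vapply(sols, `[[`, 0L, "size")
      expect_true(all(diff(sizes) <= 0)) # ranked by size, descending
    }
  }
})
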