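test_that("network readers parse TSV and SIF, dedupe and drop self-loops", {
  g <- read_network(c("A\tB", "B\tC"), dialect = "tsv")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  g <- read_network(c("A pp B", "B pp A"), dialect = "sif")
  expect_equal(igraph::ecount(g), 1)

  expect_warning(g <- read_network(c("A\tA", "A\tB"), dialect = "tsv"),
                 "self-loop")
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1)

  expect_error(read_network(c("A\tB\tC"), dialect = "tsv"), "line 1")
  expect_error(read_network(character(0), dialect = "tsv"), "empty")
  # SIF declares isolated nodes on their own line
  g <- read_network(c("A pp B", "Z"), dialect = "sif")
  expect_true("Z" %in% igraph::V(g)$name)
})

test_that("network round-trips through each dialect up to ordering", {
  g <- mk_graph(c("A-B", "B-C", "C-D", "A-C"))
  for (dialect in c("tsv", "sif", "graphml")) {
    f <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_network(g, f, dialect)
    g2 <- read_network(f, dialect)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    canon <- function(x) {
      el <- igraph::as_edgelist(x)
      sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    }
    expect_equal(canon(g2), canon(g))
  }
})

test_that("indicator matrix parsing handles headers, errors on bad input", {
  m <- read_indicator_matrix(c("g1\t1\t0", "g2\t0\t0"))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[1, ]), c(1L, 0L))
  expect_equal(colnames(m), c("c1", "c2"))

  m <- read_indicator_matrix(c("id\ts1\ts2", "g1\t1\t0"))
  expect_equal(colnames(m), c("s1", "s2"))

  expect_error(read_indicator_matrix(c("g1\t1\t2")), "non-binary")
  expect_error(read_indicator_matrix(c("id\ta\tb", "g1\t1\t0", "g2\t1")),
               "ragged")
  expect_error(indicator_matrix(matrix(c(1, 0), 2, 1,
                                       dimnames = list(c("g1", "g1"), "c1"))),
               "duplicate")
  # write/read round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_indicator_matrix(m, f)
  m2 <- read_indicator_matrix(f)
  expect_equal(unclass(m2)[, ], unclass(m)[, ])
})

test_that("p-value thresholding is strict at the cutoff", {
  p <- matrix(c(0.049, 0.05, 0.2, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- pvalues_to_indicator(p, 0.05)
  expect_equal(unname(m[, ]), matrix(c(1L, 0L, 0L, 0L), 2, 2))
  expect_equal(sum(pvalues_to_indicator(matrix(1, 2, 2,
    dimnames = list(c("a", "b"), NULL)), 0.05)), 0)
  expect_error(pvalues_to_indicator(matrix(1.2, 1, 1,
    dimnames = list("a", NULL))), "\\[0, 1\\]")
})

test_that("formula grammar gives AND precedence over OR", {
  f <- parse_formula("D1 OR D2")
  expect_equal(f$op, "OR")
  f <- parse_formula("(D1 AND D2) OR D3")
  expect_equal(f$op, "OR")
  expect_equal(f$args[[1]]$op, "AND")
  f <- parse_formula("D1 OR D2 AND D3") # AND binds tighter
  expect_equal(f$op, "OR")
  expect_equal(f$args[[2]]$op, "AND")
  expect_equal(parse_formula("D1")$op, "id")
  expect_error(parse_formula("D1 AND"), "unexpected end")
  expect_error(parse_formula("(D1 OR D2"), "parenthes")
  expect_error(parse_formula(""), "empty")
})

test_that("dataset combination follows the formula over the gene union", {
  m1 <- indicator_matrix(matrix(c(1L, 1L, 0L, 1L), 2, 2,
                                dimnames = list(c("g1", "g2"), NULL)), "D1")
  m2 <- indicator_matrix(matrix(c(0L, 1L, 1L, 1L), 2, 2,
                                dimnames = list(c("g1", "g3"), NULL)), "D2")
  and <- combine_datasets(dataset_collection(list(m1, m2), "D1 AND D2"))
  or <- combine_datasets(dataset_collection(list(m1, m2), "D1 OR D2"))
  # g1: D1 = (1,0), D2 = (0,1)
  expect_equal(unname(and["g1", ]), c(0L, 0L))
  expect_equal(unname(or["g1", ]), c(1L, 1L))
  # g2 missing from D2 -> zero row there, so AND kills it
  expect_equal(unname(and["g2", ]), c(0L, 0L))
  expect_equal(unname(or["g2", ]), c(1L, 1L))
  expect_setequal(rownames(and), c("g1", "g2", "g3"))
  # single-dataset formula returns that dataset padded to the universe
  single <- combine_datasets(dataset_collection(list(m1, m2), "D1"))
  expect_equal(unname(single["g1", ]), unname(m1["g1", ]))
  expect_equal(unname(single["g3", ]), c(0L, 0L))
  expect_error(dataset_collection(list(m1), "D9"), "unknown dataset")
  m3 <- indicator_matrix(matrix(1L, 1, 3, dimnames = list("g1", NULL)), "D3")
  expect_error(combine_datasets(dataset_collection(list(m1, m3))),
               "unequal case counts")
})

test_that("L resolution: ceiling for percentages, cap for absolutes", {
  expect_equal(resolve_l(l_spec("25%"), 32), 8L)
  # independent ceiling oracle: smallest count covering p% of the cases
  pct_oracle <- function(p, n) {
    k <- 0L
    while (k / n * 100 < p && k < n) k <- k + 1L
    k
  }
  expect_equal(resolve_l(l_spec("20%"), 38), pct_oracle(20, 38))
  expect_equal(resolve_l(l_spec("20%"), 38), 8L)
  for (n in c(1, 7, 32, 38, 100))
    for (p in c(0, 13, 20, 50, 100))
      expect_equal(resolve_l(l_spec(paste0(p, "%")), n), pct_oracle(p, n))
  expect_equal(resolve_l(l_spec("100%"), 17), 17L)
  expect_equal(resolve_l(l_spec("0%"), 17), 0L)
  expect_warning(out <- resolve_l(l_spec(5), 3), "capped")
  expect_equal(out, 3L)
  expect_error(l_spec(-1), "non-negative")
  expect_error(l_spec("120%"), "exceed 100")
})

test_that("positive/negative gene lists filter and annotate the network", {
  g <- mk_graph(c("A-B", "B-C"))
  out <- apply_node_lists(g, negative = "B")
  expect_setequal(igraph::V(out)$name, c("A", "C"))
  expect_equal(igraph::ecount(out), 0)

  # positive-list gene with an all-zero row is active for any L
  out <- apply_node_lists(g, positive = "A")
  m <- indicator_matrix(matrix(0L, 3, 4,
                               dimnames = list(c("A", "B", "C"), NULL)))
  act <- compute_activity(m, 0, positive = igraph::graph_attr(out, "positive"),
                          genes = igraph::V(out)$name)
  expect_true(act$is_active[act$gene == "A"])
  expect_false(act$is_active[act$gene == "B"])

  expect_equal(igraph::vcount(apply_node_lists(g)), 3)
  expect_error(apply_node_lists(g, positive = "A", negative = "A"), "both")
  expect_warning(apply_node_lists(g, positive = "ZZZ"), "absent")
})

test_that("gene lists support comments and blank lines", {
  ids <- read_gene_list(c("# header", "HTT ", "", "CASP3 # trailing", "HTT"))
  expect_equal(ids, c("HTT", "CASP3"))
})
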