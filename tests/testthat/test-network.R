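path_graph <- function(nodes) {
  igraph::graph_from_edgelist(cbind(nodes[-length(nodes)], nodes[-1]),
                              directed = FALSE)
}

test_that("raw proximity matches hand-computed values on small graphs", {
  g <- path_graph(c("a", "b", "c", "d"))

  # identical singleton sets sit at distance zero
  p <- raw_proximity("a", "a", g)
  expect_equal(p$raw_distance, 0)
  expect_true(p$defined)

  # endpoints of the 4-node path: both directional minima are 3
  p <- raw_proximity("a", "d", g)
  expect_equal(p$raw_distance, 3)
  expect_equal(p$n_terms_used, 2)

  # mixed sets: C={a,b}, D={c,d}; minima a->2, b->1, c->1, d->2 -> mean 1.5
  p <- raw_proximity(c("a", "b"), c("c", "d"), g)
  expect_equal(p$raw_distance, 1.5)
  expect_equal(p$n_terms_used, 4)

  # gene absent from the graph: undefined, flagged, not fatal
  p <- raw_proximity("a", "z", g)
  expect_false(p$defined)
  expect_true(is.na(p$raw_distance))

  expect_s3_class(tryCatch(raw_proximity(character(0), "a", g),
                           condition = identity),
                  "drugrepo_empty_set_error")
})

test_that("unreachable genes are excluded from the average, not penalized", {
  # two components: a-b and x-y; C={a,x}, D={b}: x contributes no term
  g <- igraph::graph_from_edgelist(cbind(c("a", "x"), c("b", "y")),
                                   directed = FALSE)
  p <- raw_proximity(c("a", "x"), "b", g)
  expect_equal(p$raw_distance, 1)
  expect_equal(p$n_terms_used, 2)  # a->b and b->a, x excluded
})

test_that("proximity is symmetric and matches the BFS oracle on random graphs", {
  set.seed(3011)
  for (trial in 1:100) {
    n <- sample(5:30, 1)
    rg <- random_test_graph(n, stats::runif(1, 0.05, 0.3))
    cg <- sample(rg$nodes, sample(1:4, 1))
    dg <- sample(rg$nodes, sample(1:4, 1))
    p <- raw_proximity(cg, dg, rg$graph)
    q <- raw_proximity(dg, cg, rg$graph)
    expect_equal(p$raw_distance, q$raw_distance)
    oracle <- proximity_oracle(cg, dg, rg$nodes, rg$edges)
    if (is.na(oracle)) {
      expect_false(p$defined)
    } else {
      expect_equal(p$raw_distance, oracle)
    }
  }
})

test_that("adding a shortcut edge between the gene sets never increases proximity", {
  set.seed(512)
  for (trial in 1:25) {
    rg <- random_test_graph(15, 0.15)
    cg <- sample(rg$nodes, 3)
    dg <- sample(setdiff(rg$nodes, cg), 3)
    before <- raw_proximity(cg, dg, rg$graph)
    g2 <- igraph::add_edges(rg$graph,
                            c(which(igraph::V(rg$graph)$name == cg[1]),
                              which(igraph::V(rg$graph)$name == dg[1])))
    after <- raw_proximity(cg, dg, g2)
    if (before$defined) {
      expect_lte(after$raw_distance, before$raw_distance)
    }
  }
})

test_that("min-max normalization inverts orientation onto [0,1]", {
  batch <- data.frame(compound_id = c("c1", "c2", "c3"),
                      disease_id = "d1",
                      raw_distance = c(0, 2, 4),
                      n_terms_used = 2L, defined = TRUE,
                      stringsAsFactors = FALSE)
  out <- normalize_cds(batch)
  expect_equal(out$cds, c(1, 0.5, 0))

  # single defined entry gets 1; undefined entries get 0
  one <- normalize_cds(batch[1, ])
  expect_equal(one$cds, 1)

  batch$defined[2] <- FALSE
  batch$raw_distance[2] <- NA
  out <- normalize_cds(batch)
  expect_equal(out$cds, c(1, 0, 0))

  expect_error(normalize_cds(batch[0, ]), "empty")
})

test_that("normalized batches attain 0 and 1 whenever raw values differ", {
  set.seed(88)
  for (trial in 1:20) {
    k <- sample(3:12, 1)
    batch <- data.frame(compound_id = sprintf("c%d", 1:k),
                        disease_id = sample(c("d1", "d2"), k, replace = TRUE),
                        raw_distance = sample(0:5, k, replace = TRUE),
                        n_terms_used = 2L, defined = TRUE,
                        stringsAsFactors = FALSE)
    out <- normalize_cds(batch)
    expect_true(all(out$cds >= 0 & out$cds <= 1))
    if (length(unique(batch$raw_distance)) >= 2) {
      expect_equal(min(out$cds), 0)
      expect_equal(max(out$cds), 1)
    }
  }
})

test_that("per-disease normalization rescales within each disease", {
  batch <- data.frame(compound_id = c("c1", "c2", "c1", "c2"),
                      disease_id = c("d1", "d1", "d2", "d2"),
                      raw_distance = c(1, 3, 10, 20),
                      n_terms_used = 2L, defined = TRUE,
                      stringsAsFactors = FALSE)
  out <- normalize_cds(batch, per_disease = TRUE)
  expect_equal(out$cds, c(1, 0, 1, 0))
})
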