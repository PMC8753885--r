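test_that("substrate-product chaining links genes across reactions", {
  rt <- reaction_table(c("R1", "R2"), c("a", "m"), c("m", "b"),
                       c("g1", "g2"))
  net <- build_network(rt, currency = character(0))
  expect_setequal(igraph::V(net)$name, c("g1", "g2"))
  expect_true(igraph::are_adjacent(net, "g1", "g2"))
  # same chain through a currency metabolite: no edge
  rt2 <- reaction_table(c("R1", "R2"), c("a", "h2o"), c("h2o", "b"),
                        c("g1", "g2"))
  expect_equal(igraph::ecount(build_network(rt2)), 0)
  # compartment suffixes are stripped before currency matching
  rt3 <- reaction_table(c("R1", "R2"), c("a", "h2o[c]"), c("h2o[c]", "b"),
                        c("g1", "g2"))
  expect_equal(igraph::ecount(build_network(rt3)), 0)
  expect_equal(igraph::ecount(build_network(rt3, currency = character(0))), 1)
})

test_that("a reaction chain gives the hand-enumerated edges, isolates stay", {
  rt <- reaction_table(
    c("R1", "R2", "R3", "R4"),
    substrates = c("a", "m1", "m2", "q1"),
    products = c("m1", "m2", "b", "q2"),
    genes = c("g1", "g2", "g3", "g4"))
  net <- build_network(rt, currency = character(0))
  expect_equal(igraph::ecount(net), 2)
  expect_true(igraph::are_adjacent(net, "g1", "g2"))
  expect_true(igraph::are_adjacent(net, "g2", "g3"))
  expect_equal(igraph::degree(net)[["g4"]], 0)
})

test_that("reversible reactions contribute both orientations", {
  rt <- reaction_table(c("R1", "R2"), c("m", "x"), c("a", "m"),
                       c("g1", "g2"), reversible = c(FALSE, FALSE))
  # R2 produces m, R1 consumes m: edge g2-g1 exists even in this order
  expect_equal(igraph::ecount(build_network(rt, currency = character(0))), 1)
  rt2 <- reaction_table(c("R1", "R2"), c("a", "x"), c("m", "y"),
                        c("g1", "g2"), reversible = c(FALSE, TRUE))
  # irreversibly: R2 never touches m; reversibly: R2 consumes y,x AND m? no -
  # m is not in R2 at all, so still no edge
  expect_equal(igraph::ecount(build_network(rt2, currency = character(0))), 0)
  rt3 <- reaction_table(c("R1", "R2"), c("a", "m"), c("m", "b"),
                        c("g1", "g2"), reversible = c(FALSE, TRUE))
  expect_equal(igraph::ecount(build_network(rt3, currency = character(0))), 1)
})

test_that("multi-gene reactions connect all cross-reaction pairs only", {
  rt <- reaction_table(c("R1", "R2"), c("a", "m"), c("m", "b"),
                       c("g1;g2", "g3;g4"))
  net <- build_network(rt, currency = character(0))
  expect_equal(igraph::ecount(net), 4)       # 2 x 2 bipartite, no intra edges
  expect_false(igraph::are_adjacent(net, "g1", "g2"))
  net2 <- build_network(rt, currency = character(0), intra_reaction = TRUE)
  expect_equal(igraph::ecount(net2), 6)
  expect_true(igraph::are_adjacent(net2, "g1", "g2"))
})

test_that("adding currency metabolites never adds edges", {
  set.seed(4)
  mets <- sprintf("m%d", 1:6)
  rt <- reaction_table(
    sprintf("R%d", 1:10),
    substrates = replicate(10, paste(sample(mets, 2), collapse = ";")),
    products = replicate(10, paste(sample(mets, 2), collapse = ";")),
    genes = sprintf("g%d", 1:10))
  prev <- Inf
  for (k in 0:6) {
    e <- igraph::ecount(build_network(rt, currency = mets[seq_len(k)]))
    expect_lte(e, prev)
    prev <- e
  }
})

test_that("network construction is order-invariant and matches brute force", {
  set.seed(9)
  for (rep in 1:5) {
    n_rx <- 12
    mets <- sprintf("m%d", 1:8)
    rt <- reaction_table(
      sprintf("R%d", seq_len(n_rx)),
      substrates = replicate(n_rx, paste(sample(mets, 2), collapse = ";")),
      products = replicate(n_rx, paste(sample(mets, 2), collapse = ";")),
      genes = replicate(n_rx, paste(sample(sprintf("g%d", 1:9), 2),
                                    collapse = ";")),
      reversible = runif(n_rx) < 0.3)
    cur <- sample(mets, 2)
    net <- build_network(rt, currency = cur)

    # brute force: double loop over all ordered reaction pairs
    subs <- lapply(strsplit(rt$substrates, ";"), setdiff, y = cur)
    prods <- lapply(strsplit(rt$products, ";"), setdiff, y = cur)
    gl <- strsplit(rt$genes, ";")
    want <- character(0)
    for (i in seq_len(n_rx)) {
      for (j in seq_len(n_rx)) {
        if (i == j) next
        out_i <- if (rt$reversible[i]) union(prods[[i]], subs[[i]]) else prods[[i]]
        in_j <- if (rt$reversible[j]) union(subs[[j]], prods[[j]]) else subs[[j]]
        if (length(intersect(out_i, in_j)) > 0L) {
          for (a in gl[[i]]) for (b in gl[[j]]) {
            if (a != b) want <- c(want, paste(sort(c(a, b)), collapse = "-"))
          }
        }
      }
    }
    got <- apply(igraph::as_edgelist(net), 1L, function(e) {
      paste(sort(e), collapse = "-")
    })
    expect_setequal(got, unique(want))

    shuf <- rt[sample(nrow(rt)), ]
    class(shuf) <- class(rt)
    net2 <- build_network(shuf, currency = cur)
    got2 <- apply(igraph::as_edgelist(net2), 1L, function(e) {
      paste(sort(e), collapse = "-")
    })
    expect_setequal(got2, got)
    expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  }
})

test_that("annotate_degs counts set intersections with network nodes", {
  net <- g_from(rbind(c("g1", "g2"), c("g2", "g3")), isolates = "g4")
  out <- annotate_degs(net, list(A_B = c("g1", "g4", "zz"),
                                 A_C = character(0), B_C = "q9"))
  expect_equal(out$counts, c(A_B = 2L, A_C = 0L, B_C = 0L))
  expect_setequal(out$genes$A_B, c("g1", "g4"))
})

test_that("edge lists round-trip through TSV including isolates", {
  net <- g_from(rbind(c("b", "a"), c("c", "b")), isolates = "zz")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), 2)
})
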