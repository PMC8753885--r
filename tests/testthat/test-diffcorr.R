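test_that("mean absolute Pearson correlation on toy data", {
  ds <- toy_ds(list(A = rbind(c(1, 2, 3), c(2, 4, 6))), c("x", "y"))
  expect_equal(mean_abs_pearson(ds, c("x", "y"), "A"), 1)
  ds2 <- toy_ds(list(A = rbind(c(1, 2, 3), c(3, 2, 1))), c("x", "y"))
  expect_equal(mean_abs_pearson(ds2, c("x", "y"), "A"), 1)  # |r| symmetric
  # three genes: brute-force pairwise mean
  m <- rbind(a = c(1, 4, 2, 8), b = c(2, 2, 5, 7), c = c(9, 1, 4, 4))
  ds3 <- toy_ds(list(A = m), rownames(m))
  want <- mean(abs(c(cor(m["a", ], m["b", ]), cor(m["a", ], m["c", ]),
                     cor(m["b", ], m["c", ]))))
  expect_equal(mean_abs_pearson(ds3, rownames(m), "A"), want)
})

test_that("zero-variance genes contribute 0 with a warning", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 1, 2))
  ds <- toy_ds(list(A = m), rownames(m))
  expect_warning(h <- mean_abs_pearson(ds, rownames(m), "A"),
                 "zero-variance")
  expect_equal(h, abs(cor(m["a", ], m["c", ])) / 3)
})

test_that("W is zero on state-identical data and symmetric in the contrast", {
  base <- matrix(rnorm(15), 3, dimnames = list(c("a", "b", "c"), NULL))
  ds <- toy_ds(list(A = base, B = base), rownames(base))
  expect_equal(w_score(ds, rownames(base), c("A", "B"))$W, 0)
  set.seed(2)
  ds2 <- toy_ds(list(A = matrix(rnorm(15), 3), B = matrix(rnorm(15), 3)),
                c("a", "b", "c"))
  ab <- w_score(ds2, c("a", "b", "c"), c("A", "B"))
  ba <- w_score(ds2, c("a", "b", "c"), c("B", "A"))
  expect_equal(ab$W, ba$W)
  expect_true(ab$W >= 0 && ab$W <= 1)
})

test_that("size-conserved sampling is uniform and exhaustive at full size", {
  nodes <- sprintf("n%02d", 1:20)
  net <- g_from(rbind(cbind(nodes[-20], nodes[-1])))
  expect_setequal(sample_size_conserved(net, 20), nodes)
  expect_error(sample_size_conserved(net, 21), "exceeds")
  set.seed(5)
  counts <- table(unlist(replicate(10000, sample_size_conserved(net, 4),
                                   simplify = FALSE)))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("degree-conserved sampling preserves the degree multiset", {
  # 3-regular graph: any 4 distinct nodes qualify
  reg <- g_from(rbind(c("a","b"), c("b","c"), c("c","d"), c("d","a"),
                      c("a","c"), c("b","d")))  # K4: 3-regular
  set.seed(1)
  s <- sample_degree_conserved(reg, c("a", "b"))
  expect_length(s, 2)
  expect_equal(anyDuplicated(s), 0)
  # star: the centre is forced
  star <- g_from(cbind("hub", paste0("leaf", 1:4)))
  expect_equal(sample_degree_conserved(star, "hub"), "hub",
               ignore_attr = TRUE)
  # random graphs: exact pools suffice when the module is small
  set.seed(31)
  for (rep in 1:20) {
    nodes <- sprintf("n%02d", 1:25)
    net <- g_from(random_edges(nodes, 0.25), isolates = nodes)
    deg <- igraph::degree(net)
    mod <- sample(nodes, 4)
    s <- suppressMessages(sample_degree_conserved(net, mod))
    if (!attr(s, "relaxed")) {
      expect_equal(sort(unname(deg[s])), sort(unname(deg[mod])))
    }
    expect_equal(anyDuplicated(s), 0)
  }
})

test_that("permutation p-values hit the exact extremes", {
  set.seed(41)
  nodes <- sprintf("n%02d", 1:30)
  net <- g_from(random_edges(nodes, 0.2), isolates = nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)
  stat <- function(genes) sum(idx[genes])
  # observed = unique maximum over all 5-sets: every random draw is smaller
  top <- names(sort(idx, decreasing = TRUE))[1:5]
  pr <- suppressMessages(permutation_pvalues(net, top, stat, n_rand = 50))
  expect_equal(pr$p_size, 0)
  expect_equal(pr$t_size, 50)
  # observed = unique minimum: no random draw is strictly below, p = 1
  bottom <- names(sort(idx))[1:5]
  pr2 <- suppressMessages(permutation_pvalues(net, bottom, stat, n_rand = 50))
  expect_equal(pr2$p_size, 1)
  expect_equal(pr2$t_size, 0)
})

test_that("size-conserved p matches the enumeration probability", {
  # statistic counts overlap with a fixed pair; only the pair itself ties the
  # observed value, so E[p] = 1 - P(draw != pair) = 1/choose(6,2) + o(1)
  nodes <- letters[1:6]
  net <- g_from(cbind(nodes[-6], nodes[-1]))
  stat <- function(genes) length(intersect(genes, c("b", "e")))
  set.seed(7)
  pr <- suppressMessages(
    permutation_pvalues(net, c("b", "e"), stat, n_rand = 2000))
  expect_lt(abs(pr$p_size - 1 / choose(6, 2)), 0.02)
})

test_that("failed statistic evaluations are redrawn, not dropped", {
  nodes <- letters[1:10]
  net <- g_from(cbind(nodes[-10], nodes[-1]))
  calls <- 0L
  stat <- function(genes) {
    calls <<- calls + 1L
    if (calls %% 5L == 0L) stop("boom")
    length(genes)
  }
  set.seed(3)
  pr <- suppressMessages(permutation_pvalues(net, c("a", "b"), stat,
                                             n_rand = 20))
  expect_equal(pr$n_rand, 20)
  expect_equal(pr$p_size, 1)  # all draws tie the observed size statistic
})

test_that("candidate selection requires both p-values below alpha", {
  mk <- function(pd, ps) structure(list(p_degree = pd, p_size = ps),
                                   class = "perm_result")
  expect_identical(
    unname(select_candidates(list(mk(0.04, 0.06), mk(0, 0), mk(0.06, 0.01)))),
    c(FALSE, TRUE, FALSE))
})
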