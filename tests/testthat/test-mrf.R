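test_that("expression difference handles the no-signal cases", {
  base <- matrix(rnorm(12), 2, 6, dimnames = list(c("a", "b"), NULL))
  ds <- toy_ds(list(A = base, B = base), c("a", "b"))
  E <- expression_difference(ds, c("a", "b"), c("A", "B"))
  expect_equal(unname(E), c(0, 0))   # identical groups: p = 1, E clipped to 0
})

test_that("expression difference matches a hand-computed Welch transform", {
  x1 <- c(1, 2, 3); x2 <- c(5, 7, 6)
  ds <- toy_ds(list(A = rbind(a = x1), B = rbind(a = x2)), "a")
  E <- expression_difference(ds, "a", c("A", "B"))
  se2 <- var(x1) / 3 + var(x2) / 3
  tt <- (mean(x2) - mean(x1)) / sqrt(se2)
  df <- se2^2 / ((var(x1) / 3)^2 / 2 + (var(x2) / 3)^2 / 2)
  p <- 2 * pt(-abs(tt), df)
  expect_equal(unname(E), min(max(qnorm(1 - p), 0), 8.2))
  Et <- expression_difference(ds, "a", c("A", "B"), method = "abs_t")
  expect_equal(unname(Et), abs(tt))
})

test_that("expression difference is capped and zero-variance safe", {
  ds <- toy_ds(list(A = rbind(a = c(1, 1, 1)), B = rbind(a = c(9, 9, 9))),
               "a")
  expect_equal(unname(expression_difference(ds, "a", c("A", "B"))), 8.2)
  ds0 <- toy_ds(list(A = rbind(a = c(2, 2, 2)), B = rbind(a = c(2, 2, 2))),
                "a")
  expect_equal(unname(expression_difference(ds0, "a", c("A", "B"))), 0)
})

test_that("mutual information on canonical inputs", {
  x <- c(1.2, 3.4, 0.5, 7.7, 2.2, 9.1)
  expect_equal(mutual_information(x, x, n_bins = 2), 1)   # diagonal joint
  expect_equal(mutual_information(rep(1, 6), x), 0)
  # plug-in MI has an upward O(bins^2 / n) bias, so the shuffle baseline is
  # checked with bins coarse relative to n
  set.seed(5)
  y <- rnorm(100)
  self <- mutual_information(y, y, n_bins = 4)
  shuffled <- mean(replicate(100, mutual_information(y, sample(y),
                                                     n_bins = 4)))
  expect_lt(shuffled, self / 10)
})

test_that("mrfms on hand-built modules", {
  net <- g_from(t(combn(paste0("g", 1:4), 2)))   # K4
  E <- stats::setNames(rep(1, 4), paste0("g", 1:4))
  mi_fn <- function(v, z) 0.5
  sc <- mrfms(net, paste0("g", 1:4), E, deg_genes = paste0("g", 1:4),
              mi_fn = mi_fn)
  expect_equal(sc$mrfms, 2)              # all DEGs: 4 / sqrt(4), term2 = 0
  expect_equal(sc$term2, 0)
  sc0 <- mrfms(net, paste0("g", 1:4), E * 0, deg_genes = character(0),
               mi_fn = mi_fn)
  expect_equal(sc0$mrfms, 0)
})

test_that("mrfms matches an explicit spreadsheet-style evaluation", {
  # 5-gene toy: path g1-g2-g3-g4-g5 plus chord g2-g4; DEGs g1, g5
  net <- g_from(rbind(c("g1","g2"), c("g2","g3"), c("g3","g4"),
                      c("g4","g5"), c("g2","g4")))
  E <- c(g1 = 3.1, g2 = 0.4, g3 = 1.7, g4 = 0.9, g5 = 2.6)
  mi_tab <- c("g2|g3" = 0.2, "g3|g4" = 0.7, "g2|g4" = 0.05)
  mi_fn <- function(v, z) mi_tab[[paste(sort(c(v, z)), collapse = "|")]]
  d <- igraph::degree(net)
  sc <- mrfms(net, paste0("g", 1:5), E, deg_genes = c("g1", "g5"),
              mi_fn = mi_fn)
  term1 <- (3.1 + 2.6) / sqrt(5)
  pair <- function(a, b, mi) {
    (E[[a]] / sqrt(d[[a]]) - E[[b]] / sqrt(d[[b]]))^2 * mi
  }
  term2 <- (pair("g2", "g3", 0.2) + pair("g3", "g4", 0.7) +
              pair("g2", "g4", 0.05)) / 5   # b = 5 induced edges
  expect_equal(sc$term1, term1)
  expect_equal(sc$term2, term2)
  expect_equal(sc$mrfms, term1 - term2)
  expect_equal(sc$b, 5)
  # and the Gibbs-energy identity holds through the independent path
  en <- mrf_energy(net, paste0("g", 1:5), E, deg_genes = c("g1", "g5"),
                   mi_fn = mi_fn)
  expect_equal(sc$mrfms, -en, tolerance = 1e-12)
})

test_that("mrfms monotonicity in DEG evidence and non-DEG discord", {
  net <- g_from(rbind(c("g1","g2"), c("g2","g3"), c("g1","g3"),
                      c("g3","g4")))
  mi_fn <- function(v, z) 0.3
  E <- c(g1 = 2, g2 = 1, g3 = 1, g4 = 0.5)
  base <- mrfms(net, paste0("g", 1:4), E, deg_genes = "g1", mi_fn = mi_fn)
  up <- E; up["g1"] <- 3
  expect_gt(mrfms(net, paste0("g", 1:4), up, deg_genes = "g1",
                  mi_fn = mi_fn)$mrfms, base$mrfms)
  # widening the discrepancy between adjacent non-DEGs g3, g4 cannot help
  worse <- E; worse["g4"] <- 0.1
  expect_lte(mrfms(net, paste0("g", 1:4), worse, deg_genes = "g1",
                   mi_fn = mi_fn)$mrfms, base$mrfms)
  expect_gte(base$term2, 0)
  expect_lte(base$mrfms, base$term1)
})

test_that("term1 scales as sqrt(g) when a module is doubled", {
  # module A: K4 all DEGs with E = e; module B: two disjoint K4s, same e
  e <- 1.4
  netA <- g_from(t(combn(paste0("a", 1:4), 2)))
  netB <- g_from(rbind(t(combn(paste0("a", 1:4), 2)),
                       t(combn(paste0("b", 1:4), 2))))
  mi_fn <- function(v, z) 0
  EA <- stats::setNames(rep(e, 4), paste0("a", 1:4))
  EB <- stats::setNames(rep(e, 8), c(paste0("a", 1:4), paste0("b", 1:4)))
  scA <- mrfms(netA, names(EA), EA, deg_genes = names(EA), mi_fn = mi_fn)
  scB <- mrfms(netB, names(EB), EB, deg_genes = names(EB), mi_fn = mi_fn)
  expect_equal(scB$term1 / scA$term1, sqrt(2))
})

test_that("risk selection filters candidates and never invents modules", {
  sim <- generate_synthetic(synth_config(seed = 12))
  net <- build_network(sim$reactions)
  ds <- sim$expression
  mod <- sim$truth$planted_module_genes
  set.seed(1)
  sel <- suppressMessages(select_risk_modules(
    net, list(list(genes = mod)), ds, c("A", "B"),
    sim$truth$planted_deg_sets$A_B, n_rand = 200))
  expect_length(sel$results, 1)
  expect_length(sel$risk, 1)
  expect_true(sel$risk[[1]])
  expect_equal(sel$results[[1]]$statistic_name, "MRFms")
})

test_that("a module with no DEGs and discordant non-DEGs scores <= 0", {
  net <- g_from(t(combn(paste0("g", 1:4), 2)))
  E <- c(g1 = 5, g2 = 0.1, g3 = 4, g4 = 0.2)
  sc <- mrfms(net, paste0("g", 1:4), E, deg_genes = character(0),
              mi_fn = function(v, z) 0.4)
  expect_equal(sc$term1, 0)
  expect_gt(sc$term2, 0)
  expect_lt(sc$mrfms, 0)
})
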