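#' Per-gene expression difference between two states
#'
#' The quantity `E_i` feeding the MRF module score. Default transform: a
#' Welch two-sample t-test p-value `p_i` is mapped through the standard
#' normal quantile, `E_i = qnorm(1 - p_i)`, with `p` clipped to
#' `[1e-16, 1 - 1e-16]` and `E` clipped to `[0, 8.2]` — genes with no
#' evidence of a difference get 0, strongly shifted genes approach the cap.
#' The alternative transform is the absolute Welch t statistic.
#'
#' @param ds an [expr_set()]
#' @param genes gene ids (vectorised)
#' @param contrast two state labels, each with at least two samples
#' @param method `"qnorm"` (default) or `"abs_t"`
#' @return named numeric vector of `E` values, all `>= 0`
#' @export
expression_difference <- function(ds, genes, contrast,
                                  method = c("qnorm", "abs_t")) {
  method <- match.arg(method)
  stopifnot(length(contrast) == 2L)
  assert_genes_present(genes, rownames(ds$matrix))
  X1 <- state_matrix(ds, genes, contrast[1])
  X2 <- state_matrix(ds, genes, contrast[2])
  n1 <- ncol(X1); n2 <- ncol(X2)
  if (n1 < 2L || n2 < 2L) stop("both states need at least 2 samples")
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1L, var); v2 <- apply(X2, 1L, var)
  se2 <- v1 / n1 + v2 / n2
  tt <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), ifelse(m1 == m2, 0, Inf))
  if (method == "abs_t") {
    E <- abs(tt)
    E[!is.finite(E)] <- 8.2
    return(stats::setNames(pmin(E, 8.2), genes))
  }
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(tt)] <- 0
  p <- pmin(pmax(p, 1e-16), 1 - 1e-16)
  E <- pmin(pmax(qnorm(1 - p), 0), 8.2)
  stats::setNames(E, genes)
}

#' Plug-in mutual information with equal-frequency binning
#'
#' Both vectors are discretised into `n_bins` equal-frequency bins (ranks,
#' ties broken by position) and the mutual information of the joint bin
#' distribution is returned in bits. Constant vectors carry no information
#' and yield 0.
#'
#' @param x,y numeric vectors of equal length `>= 4`
#' @param n_bins bins per variable; default `ceiling(log2(n)) + 1`
#' @return non-negative scalar (bits)
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  if (var(x) == 0 || var(y) == 0) return(0)
  if (is.null(n_bins)) n_bins <- ceiling(log2(n)) + 1
  bx <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  by <- ceiling(rank(y, ties.method = "first") * n_bins / n)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

# shared machinery: term1/term2 of the MRF score for a gene set
mrf_terms <- function(net, genes, E, deg_genes, mi_fn,
                      g2_pairs = c("edges", "all")) {
  g2_pairs <- match.arg(g2_pairs)
  missing_E <- setdiff(genes, names(E))
  if (length(missing_E) > 0L) {
    stop("no expression difference for gene(s): ",
         paste(utils::head(missing_E, 5L), collapse = ", "))
  }
  assert_genes_present(genes, igraph::V(net)$name, "network")
  d <- igraph::degree(net)[genes]
  g1 <- intersect(genes, deg_genes)
  g2 <- setdiff(genes, deg_genes)
  sub <- igraph::induced_subgraph(net, genes)
  b <- igraph::ecount(sub)
  g <- length(genes)
  term1 <- sum(E[g1]) / sqrt(g)
  term2 <- 0
  if (length(g2) >= 2L && b > 0L) {
    if (g2_pairs == "edges") {
      el <- igraph::as_edgelist(sub)
      el <- el[el[, 1] %in% g2 & el[, 2] %in% g2, , drop = FALSE]
    } else {
      el <- t(combn(sort(g2), 2L))
    }
    if (nrow(el) > 0L) {
      sm <- 0
      for (i in seq_len(nrow(el))) {
        v <- el[i, 1]; z <- el[i, 2]
        if (d[[v]] == 0L || d[[z]] == 0L) {
          stop("gene with network degree 0 in the smoothness term: ",
               if (d[[v]] == 0L) v else z)
        }
        sm <- sm + (E[[v]] / sqrt(d[[v]]) - E[[z]] / sqrt(d[[z]]))^2 *
          mi_fn(v, z)
      }
      term2 <- sm / b
    }
  }
  list(term1 = term1, term2 = term2, g = g, b = b, G1 = sort(g1),
       G2 = sort(g2))
}

# memoising pairwise-MI closure over the contrast's pooled samples
make_mi_fn <- function(ds, contrast, n_bins = NULL) {
  samples <- c(state_samples(ds, contrast[1]), state_samples(ds, contrast[2]))
  cache <- new.env(parent = emptyenv())
  function(v, z) {
    key <- paste(sort(c(v, z)), collapse = "\r")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- mutual_information(ds$matrix[v, samples], ds$matrix[z, samples],
                              n_bins = n_bins)
    cache[[key]] <- val
    val
  }
}

#' MRF-based module score
#'
#' `MRFms(M) = (1/sqrt(g)) * sum_{u in G1} E_u
#'   - (1/b) * sum_{(v,z)} (E_v/sqrt(d_v) - E_z/sqrt(d_z))^2 * MI(v,z)`
#'
#' where `G1`/`G2` are the DEGs/non-DEGs of the module, `g` the module size,
#' `b` the number of edges induced by the module, `d` the degree in the full
#' network, and the second sum runs (by default) over induced module edges
#' with both endpoints in `G2`. The score rewards differential-expression
#' mass among the module's DEGs and penalises degree-normalised expression-
#' difference discrepancy between adjacent non-DEGs, weighted by their
#' mutual information. It equals minus the Gibbs energy of the module's MRF
#' (see [mrf_energy()]); the Gibbs temperature and normalising constants
#' never enter because only score comparisons matter.
#'
#' @param net an `igraph` network (degrees are taken from the full network)
#' @param genes module gene ids
#' @param E named vector of expression differences from
#'   [expression_difference()] covering at least the module genes
#' @param deg_genes DEG gene ids of the contrast (defines `G1`)
#' @param ds,contrast expression data and contrast used for the pairwise
#'   mutual information (pooled samples of both states); alternatively pass
#'   a memoised `mi_fn`
#' @param mi_bins bins for the MI estimate (`NULL` = default rule)
#' @param mi_fn optional `function(v, z)` overriding the MI computation
#' @param g2_pairs `"edges"` (default): smoothness over induced G2-G2 edges;
#'   `"all"`: over all unordered G2 pairs
#' @return list with `mrfms`, `term1`, `term2`, `g`, `b`, `G1`, `G2`
#' @export
mrfms <- function(net, genes, E, deg_genes, ds = NULL, contrast = NULL,
                  mi_bins = NULL, mi_fn = NULL, g2_pairs = "edges") {
  stopifnot(length(genes) >= 1L)
  if (is.null(mi_fn)) {
    if (is.null(ds) || is.null(contrast)) {
      stop("either `mi_fn` or both `ds` and `contrast` must be supplied")
    }
    mi_fn <- make_mi_fn(ds, contrast, mi_bins)
  }
  tm <- mrf_terms(net, genes, E, deg_genes, mi_fn, g2_pairs)
  c(list(mrfms = tm$term1 - tm$term2), tm)
}

#' Gibbs energy F(E) of a module
#'
#' The energy function of the Gibbs distribution
#' `P(E) = (1/K) exp(-F(E)/T)` underlying the MRF model:
#' `F(E) = -(1/sqrt(g)) sum_{G1} E_i + (1/b) sum (E_i/sqrt(d_i) -
#' E_j/sqrt(d_j))^2 MI(i,j)`. By construction `mrfms = -F(E)`; both are
#' computed through separate arithmetic paths so the identity is testable.
#'
#' @inheritParams mrfms
#' @return scalar energy
#' @export
mrf_energy <- function(net, genes, E, deg_genes, ds = NULL, contrast = NULL,
                       mi_bins = NULL, mi_fn = NULL, g2_pairs = "edges") {
  if (is.null(mi_fn)) mi_fn <- make_mi_fn(ds, contrast, mi_bins)
  tm <- mrf_terms(net, genes, E, deg_genes, mi_fn, g2_pairs)
  -tm$term1 + tm$term2
}

#' Identify risk modules among candidate modules
#'
#' Reuses the two-null permutation machinery with the MRF score as the
#' statistic. For every random gene set the DEG membership (`G1`) is
#' re-evaluated against the contrast's DEG list, `E` and degrees come from
#' the full network, and mutual information is memoised across draws.
#'
#' @param net an `igraph` network
#' @param candidates list of candidate modules (each with `genes`)
#' @param ds an [expr_set()]
#' @param contrast two state labels
#' @param deg_genes DEG gene ids of the contrast
#' @param n_rand permutation draws per null
#' @param alpha significance level on both p-values
#' @param e_method,mi_bins,g2_pairs forwarded to the score
#' @return list with `results` (a `perm_result` plus the observed score per
#'   candidate) and `risk` (logical selection vector)
#' @export
select_risk_modules <- function(net, candidates, ds, contrast, deg_genes,
                                n_rand = 1000, alpha = 0.05,
                                e_method = "qnorm", mi_bins = NULL,
                                g2_pairs = "edges") {
  E <- expression_difference(ds, igraph::V(net)$name, contrast,
                             method = e_method)
  mi_fn <- make_mi_fn(ds, contrast, mi_bins)
  stat_fn <- function(genes) {
    mrfms(net, genes, E, deg_genes, mi_fn = mi_fn,
          g2_pairs = g2_pairs)$mrfms
  }
  results <- lapply(candidates, function(m) {
    permutation_pvalues(net, m$genes, stat_fn, n_rand = n_rand,
                        statistic_name = "MRFms")
  })
  list(results = results, risk = select_candidates(results, alpha))
}
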