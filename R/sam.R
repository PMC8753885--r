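#' SAM-style differential expression between two sample states
#'
#' Moderated d-statistic with a permutation estimate of the false discovery
#' rate. For each gene, `d = (mean2 - mean1) / (s + s0)` where `s` is the
#' pooled standard error of the mean difference and `s0` a small positive
#' fudge factor taken as a fixed quantile of the gene-wise standard errors
#' (regularising genes with tiny variance). Because the data are log2 scale,
#' the log2 fold change is simply `mean2 - mean1`.
#'
#' The per-gene q-value at cutoff `|d_i|` is the expected number of permuted
#' `|d|` values at or above `|d_i|` (averaged over permutations) divided by
#' the observed count, capped at 1 and monotonised so that q is non-increasing
#' in `|d|`. When the label-permutation space `choose(n1+n2, n1)` is at most
#' `exhaustive_limit`, all assignments are enumerated; otherwise `n_perm`
#' random label permutations are drawn (seed the RNG for reproducibility).
#'
#' @param ds an [expr_set()]
#' @param contrast character vector of two state labels `c(reference, test)`;
#'   positive `d` and `log2fc` mean higher expression in the test state
#' @param n_perm number of random permutations when not exhaustive
#' @param s0_quantile quantile of the gene-wise standard errors used as `s0`
#' @param fc_threshold absolute log2 fold-change cut for calling a DEG
#' @param q_threshold q-value cut for calling a DEG
#' @param exhaustive_limit enumerate all label assignments when their number
#'   does not exceed this
#' @return data.frame with columns `gene_id`, `contrast`, `d`, `log2fc`, `q`,
#'   `is_deg`
#' @export
sam_degs <- function(ds, contrast, n_perm = 1000, s0_quantile = 0.05,
                     fc_threshold = 1, q_threshold = 0.05,
                     exhaustive_limit = 10000) {
  stopifnot(inherits(ds, "expr_set"), length(contrast) == 2L)
  s1 <- state_samples(ds, contrast[1])
  s2 <- state_samples(ds, contrast[2])
  if (length(s1) < 2L || length(s2) < 2L) {
    stop("both states need at least 2 samples")
  }
  X <- ds$matrix[, c(s1, s2), drop = FALSE]
  n1 <- length(s1); n2 <- length(s2); n <- n1 + n2

  d_of <- function(i1, i2, s0) {
    m1 <- rowMeans(X[, i1, drop = FALSE])
    m2 <- rowMeans(X[, i2, drop = FALSE])
    ss <- rowSums((X[, i1, drop = FALSE] - m1)^2) +
      rowSums((X[, i2, drop = FALSE] - m2)^2)
    s <- sqrt((1 / length(i1) + 1 / length(i2)) *
                ss / (length(i1) + length(i2) - 2))
    denom <- s + s0
    denom[denom == 0] <- .Machine$double.eps
    list(d = (m2 - m1) / denom, s = s, fc = m2 - m1)
  }

  # s0 from the observed split only, reused for every permutation
  raw <- d_of(seq_len(n1), n1 + seq_len(n2), 0)
  s0 <- unname(quantile(raw$s, s0_quantile))
  obs <- d_of(seq_len(n1), n1 + seq_len(n2), s0)

  n_assign <- choose(n, n1)
  if (n_assign <= exhaustive_limit) {
    splits <- combn(n, n1, simplify = FALSE)
  } else {
    splits <- replicate(n_perm, sample.int(n, n1), simplify = FALSE)
  }
  perm_abs <- unlist(lapply(splits, function(i1) {
    abs(d_of(i1, setdiff(seq_len(n), i1), s0)$d)
  }), use.names = FALSE)
  n_used <- length(splits)

  abs_obs <- abs(obs$d)
  sv <- sort(perm_abs)
  # count of permuted |d| >= threshold, exact under ties
  n_ge <- length(sv) - findInterval(abs_obs, sv, left.open = TRUE)
  obs_ge <- vapply(abs_obs, function(t) sum(abs_obs >= t), integer(1L))
  q <- pmin(1, (n_ge / n_used) / obs_ge)
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  out <- data.frame(
    gene_id = rownames(X),
    contrast = paste(contrast, collapse = "_"),
    d = unname(obs$d),
    log2fc = unname(obs$fc),
    q = unname(q),
    stringsAsFactors = FALSE
  )
  out$is_deg <- abs(out$log2fc) > fc_threshold & out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Extract per-contrast DEG gene sets from a DEG table
#' @param deg_table data.frame as returned by [sam_degs()] (possibly several
#'   contrasts row-bound together)
#' @return named list of character vectors, one per contrast
#' @export
deg_sets <- function(deg_table) {
  split(deg_table$gene_id[deg_table$is_deg],
        deg_table$contrast[deg_table$is_deg])
}
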