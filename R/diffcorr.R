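#' Mean absolute pairwise Pearson correlation of a gene set in one state
#'
#' The quantity `H`: the average over all `choose(g, 2)` unordered gene pairs
#' of the absolute Pearson correlation computed across that state's samples.
#' Pairs involving a zero-variance gene contribute 0 (with one warning).
#'
#' @param ds an [expr_set()]
#' @param genes at least two gene ids
#' @param state state label with at least three samples
#' @return scalar in `[0, 1]`
#' @export
mean_abs_pearson <- function(ds, genes, state) {
  stopifnot(length(genes) >= 2L)
  assert_genes_present(genes, rownames(ds$matrix))
  X <- state_matrix(ds, genes, state)
  if (ncol(X) < 3L) stop("state ", state, " has fewer than 3 samples")
  cm <- suppressWarnings(cor(t(X)))
  up <- cm[upper.tri(cm)]
  if (anyNA(up)) {
    warning("zero-variance gene(s) in state ", state,
            "; their pairs contribute correlation 0")
    up[is.na(up)] <- 0
  }
  mean(abs(up))
}

#' Differential-correlation score W of a module
#'
#' `W(M) = |H - H'|` where `H` and `H'` are the mean absolute pairwise
#' Pearson correlations of the module genes in the two states of the
#' contrast. `W` lies in `[0, 1]`, is symmetric in the state order and is 0
#' when both states carry identical data.
#'
#' @param ds an [expr_set()]
#' @param genes module gene ids
#' @param contrast two state labels
#' @return list with `H`, `H_prime`, `W`, `contrast`, `n`, `m`, `n_pairs`
#' @export
w_score <- function(ds, genes, contrast) {
  stopifnot(length(contrast) == 2L)
  H <- mean_abs_pearson(ds, genes, contrast[1])
  Hp <- mean_abs_pearson(ds, genes, contrast[2])
  g <- length(genes)
  list(H = H, H_prime = Hp, W = abs(H - Hp),
       contrast = paste(contrast, collapse = "_"),
       n = length(state_samples(ds, contrast[1])),
       m = length(state_samples(ds, contrast[2])),
       n_pairs = g * (g - 1) / 2)
}

#' Size-conserved random gene set
#'
#' Uniform sample of `size` distinct network nodes (the size-conserved
#' permutation null). Uses R's global RNG; seed beforehand for
#' reproducibility.
#'
#' @param net an `igraph` network
#' @param size number of nodes to draw
#' @return character vector of gene ids
#' @export
sample_size_conserved <- function(net, size) {
  nodes <- igraph::V(net)$name
  if (size > length(nodes)) stop("size exceeds the number of network nodes")
  sample(nodes, size)
}

# degree pools reused across many degree-conserved draws
degree_index <- function(net) {
  deg <- igraph::degree(net)
  list(deg = deg, pools = split(names(deg), deg),
       pool_degrees = sort(unique(unname(deg))))
}

sample_degree_conserved_idx <- function(idx, module_degrees) {
  taken <- character(0)
  relaxed <- FALSE
  for (d in sort(module_degrees, decreasing = TRUE)) {
    pool <- setdiff(idx$pools[[as.character(d)]] %||% character(0), taken)
    if (length(pool) == 0L) {
      # widen to the nearest degree on a log scale until a node is free
      ord <- idx$pool_degrees[order(abs(log2(idx$pool_degrees + 1) -
                                          log2(d + 1)))]
      for (d2 in ord) {
        pool <- setdiff(idx$pools[[as.character(d2)]], taken)
        if (length(pool) > 0L) break
      }
      if (length(pool) == 0L) {
        stop("network too small to draw a degree-conserved set")
      }
      relaxed <- TRUE
    }
    taken <- c(taken, if (length(pool) == 1L) pool else sample(pool, 1L))
  }
  attr(taken, "relaxed") <- relaxed
  taken
}

#' Degree-conserved random gene set
#'
#' For each module node a distinct network node of equal degree is drawn
#' without replacement, so the sampled set matches the module's degree
#' multiset. When an exact-degree pool is exhausted the match is relaxed to
#' the nearest degree on a log2 scale (common for unique high-degree hubs);
#' the relaxation is reported via a message and the `"relaxed"` attribute.
#'
#' @param net an `igraph` network
#' @param module_genes gene ids of the observed module (must be nodes)
#' @return character vector of gene ids with attribute `relaxed`
#' @export
sample_degree_conserved <- function(net, module_genes) {
  assert_genes_present(module_genes, igraph::V(net)$name, "network")
  idx <- degree_index(net)
  out <- sample_degree_conserved_idx(idx, unname(idx$deg[module_genes]))
  if (attr(out, "relaxed")) {
    message("degree matching relaxed to nearest log2 degree bin for some nodes")
  }
  out
}

#' Two-null permutation p-values for a module statistic
#'
#' Draws `n_rand` degree-conserved and `n_rand` size-conserved random gene
#' sets from the network, evaluates `statistic_fn` on each and returns
#' `p = 1 - t / n_rand` per null, where `t` counts random sets whose
#' statistic is strictly below the observed one (ties count against
#' significance). A failing statistic evaluation on a random set triggers a
#' redraw (never a silent drop).
#'
#' @param net an `igraph` network
#' @param module_genes observed module gene ids
#' @param statistic_fn function(genes) -> scalar statistic
#' @param n_rand number of random sets per null (default 1000)
#' @param statistic_name label stored in the result
#' @return list of class `perm_result` with `observed`, `p_degree`, `p_size`,
#'   `t_degree`, `t_size`, `n_rand`
#' @export
permutation_pvalues <- function(net, module_genes, statistic_fn,
                                n_rand = 1000, statistic_name = "W") {
  stopifnot(n_rand >= 1)
  observed <- statistic_fn(module_genes)
  idx <- degree_index(net)
  mod_deg <- unname(idx$deg[module_genes])
  n_relax <- 0L

  eval_on <- function(draw_fn) {
    vapply(seq_len(n_rand), function(i) {
      for (try in 1:100) {
        genes <- draw_fn()
        val <- tryCatch(statistic_fn(genes), error = function(e) NULL)
        if (!is.null(val)) return(val)
        message("statistic failed on a random set; redrawing")
      }
      stop("statistic failed on 100 consecutive random draws")
    }, numeric(1L))
  }

  deg_stats <- eval_on(function() {
    s <- sample_degree_conserved_idx(idx, mod_deg)
    if (attr(s, "relaxed")) n_relax <<- n_relax + 1L
    s
  })
  size_stats <- eval_on(function() {
    sample(igraph::V(net)$name, length(module_genes))
  })
  if (n_relax > 0L) {
    message(n_relax, "/", n_rand, " degree-conserved draws needed relaxation")
  }
  t_deg <- sum(deg_stats < observed)
  t_size <- sum(size_stats < observed)
  structure(list(observed = observed, statistic_name = statistic_name,
                 p_degree = 1 - t_deg / n_rand, p_size = 1 - t_size / n_rand,
                 t_degree = t_deg, t_size = t_size, n_rand = n_rand),
            class = "perm_result")
}

#' Select candidate modules: significant under both permutation nulls
#' @param results list of `perm_result` objects (named by module id or
#'   parallel to `modules`)
#' @param alpha significance level applied to both p-values (default 0.05)
#' @return logical vector: which results pass `p_degree < alpha` and
#'   `p_size < alpha`
#' @export
select_candidates <- function(results, alpha = 0.05) {
  vapply(results, function(r) {
    r$p_degree < alpha && r$p_size < alpha
  }, logical(1L))
}
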