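#' Remove genes with too many missing values
#'
#' Rows whose fraction of missing (`NA`) cells strictly exceeds
#' `max_missing_fraction` are dropped; a row sitting exactly at the threshold
#' is kept (only "more than" the threshold is removed). Row order of the
#' survivors is preserved.
#'
#' @param matrix numeric matrix (genes x samples), possibly with `NA`s
#' @param max_missing_fraction maximum tolerated missing fraction (default
#'   0.5, i.e. delete rows with more than 50% missing values)
#' @return the filtered matrix
#' @export
filter_missing <- function(matrix, max_missing_fraction = 0.5) {
  stopifnot(is.matrix(matrix), max_missing_fraction >= 0,
            max_missing_fraction <= 1)
  frac <- rowMeans(is.na(matrix))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all rows exceed the missing-value threshold")
  matrix[keep, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing expression values
#'
#' Each missing cell is replaced by a distance-weighted average of the values
#' that the `k` nearest rows carry in that column. Distances are root mean
#' squared differences over the columns both rows observe (a scaled Euclidean
#' distance, so rows with different missingness patterns are comparable);
#' only rows observed in the target column are eligible neighbours. Weights
#' are `1/d`; zero-distance neighbours dominate, so the masked copy of an
#' identical row is restored exactly. Observed cells are never touched.
#'
#' @param matrix numeric matrix with `NA`s marking missing cells; every row
#'   must retain at least one observed value (run [filter_missing()] first)
#' @param k number of neighbours (default 10). When fewer usable neighbours
#'   exist, all available ones are used and a warning is emitted.
#' @return the completed matrix
#' @export
knn_impute <- function(matrix, k = 10) {
  stopifnot(is.matrix(matrix), k >= 1)
  if (!anyNA(matrix)) return(matrix)
  if (any(rowSums(!is.na(matrix)) == 0L)) {
    stop("rows with no observed values cannot be imputed")
  }
  out <- matrix
  obs <- !is.na(matrix)
  need <- which(rowSums(!obs) > 0L)
  warned <- FALSE
  for (i in need) {
    # RMS distance to every other row over co-observed columns
    shared <- obs & rep(obs[i, ], each = nrow(matrix))
    diffs <- sweep(matrix, 2L, matrix[i, ])^2
    diffs[!shared] <- NA
    n_shared <- rowSums(shared)
    d <- sqrt(rowSums(diffs, na.rm = TRUE) / pmax(n_shared, 1L))
    d[n_shared == 0L] <- Inf
    d[i] <- Inf
    for (j in which(!obs[i, ])) {
      cand <- which(obs[, j] & is.finite(d))
      if (length(cand) == 0L) {
        stop("no neighbour observes column ", colnames(matrix)[j] %||% j,
             " for row ", rownames(matrix)[i] %||% i)
      }
      if (length(cand) < k && !warned) {
        warning("fewer than k usable neighbours for some cells; ",
                "falling back to all available neighbours")
        warned <- TRUE
      }
      nb <- cand[order(d[cand], rownames(matrix)[cand])]
      nb <- nb[seq_len(min(k, length(nb)))]
      dn <- d[nb]
      if (any(dn < 1e-12)) {
        out[i, j] <- mean(matrix[nb[dn < 1e-12], j])
      } else {
        w <- 1 / dn
        out[i, j] <- sum(w * matrix[nb, j]) / sum(w)
      }
    }
  }
  out
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to more than one gene are deleted outright; the remaining
#' probes are grouped by gene and averaged (arithmetic mean per sample).
#'
#' @param matrix numeric probe x sample matrix (rownames = probe ids)
#' @param probe_map named list mapping probe id to a character vector of gene
#'   ids (length > 1 marks a multi-gene probe)
#' @param states optional state labels passed through to the result
#' @return an [expr_set()] if `states` is given, otherwise a gene x sample
#'   matrix
#' @export
collapse_probes <- function(matrix, probe_map, states = NULL) {
  stopifnot(is.matrix(matrix))
  if (length(probe_map) == 0L) stop("empty probe map")
  probes <- rownames(matrix)
  miss <- setdiff(probes, names(probe_map))
  if (length(miss) > 0L) {
    stop("probe map does not cover: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  n_genes <- lengths(probe_map[probes])
  keep <- probes[n_genes == 1L]
  if (length(keep) == 0L) stop("no single-gene probes left after filtering")
  gene_of <- vapply(probe_map[keep], `[[`, character(1L), 1L)
  genes <- sort(unique(gene_of))
  out <- matrix(0, length(genes), ncol(matrix),
                dimnames = list(genes, colnames(matrix)))
  for (g in genes) {
    rows <- keep[gene_of == g]
    out[g, ] <- colMeans(matrix[rows, , drop = FALSE])
  }
  if (is.null(states)) out else expr_set(out, states)
}
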