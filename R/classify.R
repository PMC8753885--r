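# Radial-kernel SVM (least-squares formulation) --------------------------
#
# No SVM library ships with the target environment, so the classifier is a
# least-squares SVM (Suykens & Vandewalle 1999): same RBF kernel and C/gamma
# semantics as a soft-margin C-SVC, but the hinge loss is replaced by a
# squared loss, which turns training into one symmetric linear solve —
# exact, deterministic and fast enough for dense LOOCV.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# X: samples x features; y in {-1, +1}. Per-sample weights balance the
# classes (each class contributes equal total weight), the LS-SVM analogue
# of an SVM's class.weights option. Without it, leave-one-out folds are
# systematically unbalanced against the left-out sample's class and the
# null AUC is dragged well below 0.5.
lssvm_train <- function(X, y, C = 1, gamma) {
  n <- nrow(X)
  w <- n / (2 * ifelse(y > 0, sum(y > 0), sum(y < 0)))
  K <- rbf_kernel(X, X, gamma)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(1 / (C * w))))
  sol <- solve(A, c(0, y))
  list(X = X, alpha = sol[-1], b = sol[1], gamma = gamma)
}

lssvm_decision <- function(model, Xnew) {
  drop(rbf_kernel(Xnew, model$X, model$gamma) %*% model$alpha + model$b)
}

#' Leave-one-out cross-validated SVM AUC of a gene signature
#'
#' Each sample of the contrast is left out in turn; a radial-kernel SVM is
#' trained on the rest with features (genes) standardised on the training
#' fold only, and the left-out sample's decision value is recorded. The AUC
#' is computed from the pooled decision values against the true state
#' labels (the second contrast state is the positive class). `gamma`
#' defaults to `1 / (n_features * var)` with `var` the overall variance of
#' the standardised training matrix (so effectively `1/n_features`).
#'
#' @param ds an [expr_set()]
#' @param genes feature gene ids (must be rows of the matrix)
#' @param contrast two state labels, each with at least 3 samples
#' @param C soft-margin cost (default 1)
#' @param gamma RBF width; `NULL` = the default policy above
#' @return list with `auc`, `fold_scores` (decision values named by sample)
#'   and `labels` (logical, `TRUE` = positive class)
#' @export
svm_loocv_auc <- function(ds, genes, contrast, C = 1, gamma = NULL) {
  stopifnot(length(contrast) == 2L, length(genes) >= 1L)
  assert_genes_present(genes, rownames(ds$matrix))
  samples <- c(state_samples(ds, contrast[1]), state_samples(ds, contrast[2]))
  if (length(state_samples(ds, contrast[1])) < 3L ||
      length(state_samples(ds, contrast[2])) < 3L) {
    stop("both states need at least 3 samples for LOOCV")
  }
  X <- t(ds$matrix[genes, samples, drop = FALSE])  # samples x features
  y <- ifelse(ds$states[samples] == contrast[2], 1, -1)
  scores <- stats::setNames(numeric(length(samples)), samples)
  for (i in seq_along(samples)) {
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2L, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
    Xte <- matrix((X[i, ] - mu) / sdv, nrow = 1L)
    g <- gamma
    if (is.null(g)) {
      v <- var(as.vector(Xtr))
      g <- 1 / (ncol(Xtr) * if (v > 0) v else 1)
    }
    model <- lssvm_train(Xtr, y[-i], C = C, gamma = g)
    scores[i] <- lssvm_decision(model, Xte)
  }
  labels <- y > 0
  list(auc = auc_from_scores(scores, labels), fold_scores = scores,
       labels = labels)
}

#' Compare a core gene set against random gene sets by LOOCV AUC
#'
#' Two randomisation schemes mirror the usual controls: `"size"` draws sets
#' of the core set's cardinality uniformly from `pool` (e.g. candidate genes
#' minus core genes); `"composition"` additionally matches the DEG /
#' non-DEG composition of the core set, drawing DEGs from `pool`'s DEGs and
#' non-DEGs from its non-DEGs. Each random set's LOOCV AUC is computed and
#' a two-sided one-sample Wilcoxon signed-rank test compares the random AUC
#' distribution against the core AUC.
#'
#' @param ds an [expr_set()]
#' @param core_genes the core gene set
#' @param pool genes the random sets are drawn from (must not be smaller
#'   than the core set; for `"composition"`, each stratum must be large
#'   enough)
#' @param contrast two state labels
#' @param deg_genes DEG list of the contrast (required for `"composition"`)
#' @param scheme `"size"` or `"composition"`
#' @param n_reps number of random sets (default 100)
#' @param ... forwarded to [svm_loocv_auc()]
#' @return list with `scheme`, `core_auc`, `random_aucs`, `wilcoxon_p`
#' @export
random_set_comparison <- function(ds, core_genes, pool, contrast,
                                  deg_genes = NULL,
                                  scheme = c("size", "composition"),
                                  n_reps = 100, ...) {
  scheme <- match.arg(scheme)
  k <- length(core_genes)
  if (scheme == "size") {
    if (length(pool) < k) stop("pool smaller than the core set")
    draw <- function() sample(pool, k)
  } else {
    if (is.null(deg_genes)) stop("`deg_genes` required for composition scheme")
    n_deg <- length(intersect(core_genes, deg_genes))
    pool_deg <- intersect(pool, deg_genes)
    pool_non <- setdiff(pool, deg_genes)
    if (length(pool_deg) < n_deg || length(pool_non) < k - n_deg) {
      stop("pool cannot supply the core set's DEG composition")
    }
    draw <- function() {
      c(if (n_deg > 0L) sample(pool_deg, n_deg) else character(0),
        if (k - n_deg > 0L) sample(pool_non, k - n_deg) else character(0))
    }
  }
  core_auc <- svm_loocv_auc(ds, core_genes, contrast, ...)$auc
  random_aucs <- vapply(seq_len(n_reps), function(i) {
    svm_loocv_auc(ds, draw(), contrast, ...)$auc
  }, numeric(1L))
  wp <- suppressWarnings(
    wilcox.test(random_aucs, mu = core_auc, exact = FALSE)$p.value)
  list(scheme = scheme, core_auc = core_auc, random_aucs = random_aucs,
       wilcoxon_p = wp)
}
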