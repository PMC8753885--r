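# internal helpers shared across modules

# deterministic per-stage seed fan-out from one global seed; result < 2^31
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(as.numeric(utf8ToInt(stage)) * seq_len(nchar(stage)))
  as.integer((abs(as.numeric(seed)) * 131 + h * 2654435) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rank-based AUC of scores for a binary label vector (TRUE = positive);
# ties in scores handled by midranks (equivalent to the Mann-Whitney U)
auc_from_scores <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs both positive and negative labels")
  }
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

assert_genes_present <- function(genes, universe, what = "expression matrix") {
  missing <- setdiff(genes, universe)
  if (length(missing) > 0L) {
    stop("gene(s) not present in ", what, ": ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  }
  invisible(TRUE)
}
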