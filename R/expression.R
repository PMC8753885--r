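#' Expression dataset with per-sample state labels
#'
#' Container for a log2-scale gene-by-sample expression matrix together with
#' the state (condition) label of every sample. This is the substrate of all
#' downstream statistics: differential expression, differential correlation,
#' MRF module scores and classification.
#'
#' @param matrix numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). Values are assumed to be on log2
#'   scale already; fold changes are computed as differences of group means.
#' @param states named character vector mapping sample id to state label, or
#'   an unnamed vector of length `ncol(matrix)` in column order.
#' @return an object of class `expr_set`: a list with elements `matrix` and
#'   `states` (named character vector aligned to the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expr_set(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' state_samples(ds, "B")
#' @export
expr_set <- function(matrix, states) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("`matrix` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample ids")
  if (is.null(names(states))) {
    if (length(states) != ncol(matrix)) {
      stop("unnamed `states` must match the number of samples")
    }
    names(states) <- colnames(matrix)
  }
  miss <- setdiff(colnames(matrix), names(states))
  if (length(miss) > 0L) {
    stop("samples without a state label: ", paste(miss, collapse = ", "))
  }
  states <- as.character(states[colnames(matrix)])
  names(states) <- colnames(matrix)
  structure(list(matrix = matrix, states = states), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples; states: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", names(table(x$states)),
                            as.integer(table(x$states))), collapse = ", ")))
  invisible(x)
}

#' Sample ids belonging to one state
#' @param ds an [expr_set()]
#' @param state state label
#' @return character vector of sample ids
#' @export
state_samples <- function(ds, state) {
  stopifnot(inherits(ds, "expr_set"))
  names(ds$states)[ds$states == state]
}

# submatrix of one state's samples for a set of genes
state_matrix <- function(ds, genes, state) {
  ds$matrix[genes, state_samples(ds, state), drop = FALSE]
}

#' Read / write expression data as TSV
#'
#' `read_expression` expects genes in rows with the first column holding gene
#' ids; `read_states` expects two columns `sample_id` and `state`.
#'
#' @param expr_file,states_file paths to tab-separated files
#' @return an [expr_set()]
#' @export
read_expression <- function(expr_file, states_file) {
  tab <- read.delim(expr_file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  st <- read.delim(states_file, stringsAsFactors = FALSE)
  expr_set(m, stats::setNames(as.character(st$state), st$sample_id))
}

#' @rdname read_expression
#' @param ds an [expr_set()]
#' @export
write_expression <- function(ds, expr_file, states_file) {
  stopifnot(inherits(ds, "expr_set"))
  tab <- data.frame(gene_id = rownames(ds$matrix), ds$matrix,
                    check.names = FALSE)
  write.table(tab, expr_file, sep = "\t", quote = FALSE, row.names = FALSE)
  st <- data.frame(sample_id = names(ds$states), state = unname(ds$states))
  write.table(st, states_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expr_file, states_file))
}
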