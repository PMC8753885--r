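#' Known disease genes restricted to the network
#'
#' @param net an `igraph` network
#' @param known character vector of known disease gene ids
#' @return list with `all_known` and `in_network`; genes absent from the
#'   network are dropped with a warning (real disease-gene lists typically
#'   overlap a metabolic network only partially)
#' @export
known_gene_set <- function(net, known) {
  known <- unique(as.character(known))
  in_net <- intersect(known, igraph::V(net)$name)
  if (length(in_net) < length(known)) {
    warning(length(known) - length(in_net),
            " known gene(s) not in the network were dropped")
  }
  list(all_known = known, in_network = sort(in_net))
}

#' Read a plain-text known-gene list (one id per line)
#' @param file path
#' @return character vector
#' @export
read_known_genes <- function(file) {
  x <- readLines(file)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Shortest-path linkage scores B(x) of module genes
#'
#' For every unordered pair `(s, t)` of known genes connected in the
#' network and every module gene `x` distinct from both, `x` links the pair
#' iff it lies on at least one shortest s-t path, which holds exactly when
#' `dist(s, x) + dist(x, t) = dist(s, t)` (unweighted hop distances).
#' `B(x)` counts the linked pairs; genes with `B > 0` are candidate core
#' genes. Disconnected known pairs contribute nothing.
#'
#' @param net an `igraph` network
#' @param module_genes genes eligible for scoring (typically the union of
#'   risk-module genes); known genes among them are scored too
#' @param known known gene ids (or a [known_gene_set()])
#' @return data.frame with `gene_id`, `B`, `rank` (descending by `B`, ties
#'   share the minimum rank), `is_candidate`; ordered by rank then gene id
#' @export
pair_linkage_scores <- function(net, module_genes, known) {
  if (!is.list(known)) known <- known_gene_set(net, known)
  kn <- known$in_network
  if (length(kn) < 2L) stop("need at least 2 known genes in the network")
  assert_genes_present(module_genes, igraph::V(net)$name, "network")
  module_genes <- sort(unique(module_genes))
  Dk <- igraph::distances(net, v = kn, to = igraph::V(net))
  colnames(Dk) <- igraph::V(net)$name
  B <- stats::setNames(integer(length(module_genes)), module_genes)
  for (i in seq_len(length(kn) - 1L)) {
    for (j in seq(i + 1L, length(kn))) {
      s <- kn[i]; t <- kn[j]
      dst <- Dk[s, t]
      if (!is.finite(dst)) next
      x <- setdiff(module_genes, c(s, t))
      on_path <- Dk[s, x] + Dk[t, x] == dst
      B[x] <- B[x] + as.integer(on_path)
    }
  }
  out <- data.frame(gene_id = module_genes, B = unname(B),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$B, ties.method = "min")
  out$is_candidate <- out$B > 0L
  out[order(out$rank, out$gene_id), , drop = FALSE]
}

#' Select core genes: top quartile of candidates by B
#'
#' Candidates (genes with `B > 0`) are ranked by `B` descending and the top
#' `floor(quartile * n)` ranks are selected; candidates tied with the
#' boundary gene's `B` are all included, so ties are never split
#' arbitrarily. With fewer than 4 candidates the rank cut degenerates and
#' all candidates are returned with a warning.
#'
#' @param scores data.frame from [pair_linkage_scores()]
#' @param quartile selection fraction (default 0.25)
#' @return character vector of core gene ids (sorted)
#' @export
select_core <- function(scores, quartile = 0.25) {
  cand <- scores[scores$is_candidate, , drop = FALSE]
  n <- nrow(cand)
  if (n == 0L) {
    warning("no candidate genes lie on known-gene shortest paths")
    return(character(0))
  }
  if (n < 4L) {
    warning("fewer than 4 candidates; returning all of them")
    return(sort(cand$gene_id))
  }
  k <- floor(quartile * n)
  if (k < 1L) k <- 1L
  b_sorted <- sort(cand$B, decreasing = TRUE)
  boundary <- b_sorted[k]
  sort(cand$gene_id[cand$B >= boundary])
}
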