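#' Default currency-metabolite exclusion list
#'
#' Ubiquitous compounds whose sharing between reactions says nothing about a
#' functional link; chaining through them would wire spurious hub edges. The
#' defaults cover water, carbon dioxide, the adenylate pool, phosphate,
#' protons, redox carriers and coenzyme A; override per analysis as needed.
#' @return character vector of metabolite ids (lower case, no compartments)
#' @export
default_currency <- function() {
  c("h2o", "co2", "adp", "atp", "amp", "pi", "ppi", "h",
    "nad", "nadh", "nadp", "nadph", "coa", "o2")
}

#' Construct / read a reaction table
#'
#' A Recon-style reaction table: one row per reaction with `;`-separated
#' substrate, product and gene id lists. Reactions without genes are legal
#' but contribute nothing to the network.
#'
#' @param reaction_id character vector
#' @param substrates,products,genes character vectors of `;`-separated ids
#' @param reversible logical vector (default all `FALSE`)
#' @return data.frame of class `reaction_table`
#' @export
reaction_table <- function(reaction_id, substrates, products, genes,
                           reversible = FALSE) {
  stopifnot(length(reaction_id) > 0L, !anyDuplicated(reaction_id))
  df <- data.frame(
    reaction_id = as.character(reaction_id),
    substrates = as.character(substrates),
    products = as.character(products),
    genes = as.character(genes),
    reversible = rep_len(as.logical(reversible), length(reaction_id)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("reaction_table", "data.frame")
  df
}

#' @rdname reaction_table
#' @param file path to a tab-separated reaction table
#' @export
read_reaction_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (is.null(df$reversible)) df$reversible <- FALSE
  reaction_table(df$reaction_id, df$substrates, df$products, df$genes,
                 df$reversible)
}

#' @rdname reaction_table
#' @param rt a `reaction_table`
#' @export
write_reaction_table <- function(rt, file) {
  write.table(rt, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

split_ids <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# strip trailing compartment tags like "[c]" or "_c" and lower-case
normalize_metabolite <- function(x, strip_compartment = TRUE) {
  x <- tolower(x)
  if (strip_compartment) {
    x <- sub("\\[[a-z0-9]+\\]$", "", x)
    x <- sub("_[a-z]$", "", x)
  }
  x
}

#' Reconstruct the gene-gene metabolic network from a reaction table
#'
#' Two genes are linked when the product of the reaction one of them
#' catalyses is the substrate of the reaction the other catalyses — i.e. for
#' every ordered pair of distinct reactions whose product/substrate sets
#' share a non-currency metabolite, every gene of the producing reaction is
#' connected to every gene of the consuming reaction. Reversible reactions
#' play both roles with their substrate and product sets swapped as well.
#' The result is an undirected simple graph; self-loops never arise and
#' parallel links collapse. Genes of reactions that share no metabolite with
#' any other reaction remain as isolated nodes.
#'
#' @param rt a [reaction_table()]
#' @param currency metabolite ids excluded from chaining (compared after
#'   normalisation); default [default_currency()]
#' @param strip_compartments drop trailing compartment tags (`"[c]"`, `"_c"`)
#'   from metabolite ids before matching
#' @param intra_reaction also connect genes catalysing the same reaction
#'   (clique per reaction); off by default — the chaining rule is strictly
#'   cross-reaction
#' @return an `igraph` undirected graph whose vertex names are gene ids
#' @export
build_network <- function(rt, currency = default_currency(),
                          strip_compartments = TRUE,
                          intra_reaction = FALSE) {
  stopifnot(inherits(rt, "reaction_table"), nrow(rt) > 0L)
  genes <- split_ids(rt$genes)
  no_gene <- lengths(genes) == 0L
  if (any(no_gene)) {
    message(sum(no_gene), " reaction(s) without genes contribute no edges")
  }
  all_genes <- sort(unique(unlist(genes)))
  if (length(all_genes) == 0L) stop("no genes in the reaction table")

  cur <- normalize_metabolite(currency, strip_compartments)
  subs <- lapply(split_ids(rt$substrates),
                 normalize_metabolite, strip_compartments)
  prods <- lapply(split_ids(rt$products),
                  normalize_metabolite, strip_compartments)
  rev <- rt$reversible
  # role sets: reversible reactions produce and consume on both sides
  out_mets <- lapply(seq_len(nrow(rt)), function(i) {
    m <- if (rev[i]) union(prods[[i]], subs[[i]]) else prods[[i]]
    setdiff(m, cur)
  })
  in_mets <- lapply(seq_len(nrow(rt)), function(i) {
    m <- if (rev[i]) union(subs[[i]], prods[[i]]) else subs[[i]]
    setdiff(m, cur)
  })

  # index reactions by metabolite role
  producers <- consumers <- list()
  for (i in seq_len(nrow(rt))) {
    for (m in out_mets[[i]]) producers[[m]] <- c(producers[[m]], i)
    for (m in in_mets[[i]]) consumers[[m]] <- c(consumers[[m]], i)
  }

  edges <- character(0)
  for (m in names(producers)) {
    cons <- consumers[[m]]
    if (is.null(cons)) next
    for (i in producers[[m]]) {
      for (j in setdiff(cons, i)) {
        gi <- genes[[i]]; gj <- genes[[j]]
        if (length(gi) == 0L || length(gj) == 0L) next
        pairs <- expand.grid(a = gi, b = gj, stringsAsFactors = FALSE)
        pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
        if (nrow(pairs) > 0L) {
          edges <- c(edges, as.vector(t(as.matrix(pairs))))
        }
      }
    }
  }
  if (intra_reaction) {
    for (gi in genes[lengths(genes) >= 2L]) {
      cmb <- combn(sort(gi), 2L)
      edges <- c(edges, as.vector(cmb))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_genes), name = all_genes)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

#' Count DEGs of each contrast present among network nodes
#' @param net an `igraph` gene network
#' @param degs named list of per-contrast DEG gene sets
#' @return named list with elements `genes` (per-contrast intersections) and
#'   `counts` (their sizes)
#' @export
annotate_degs <- function(net, degs) {
  nodes <- igraph::V(net)$name
  genes <- lapply(degs, function(s) intersect(nodes, s))
  list(genes = genes, counts = vapply(genes, length, integer(1L)))
}

#' Write a network edge list as TSV (isolated nodes listed with empty partner)
#' @param net an `igraph` network
#' @param file output path
#' @export
write_edge_list <- function(net, file) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   stringsAsFactors = FALSE)
  iso <- setdiff(igraph::V(net)$name, unique(as.vector(el)))
  if (length(iso) > 0L) {
    df <- rbind(df, data.frame(gene_a = iso, gene_b = ""))
  }
  write.table(df[order(df$gene_a, df$gene_b), ], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a network from an edge-list TSV written by [write_edge_list()]
#' @param file path
#' @return an `igraph` network
#' @export
read_edge_list <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE,
                   colClasses = c("character", "character"))
  has_b <- nzchar(df$gene_b)
  nodes <- sort(unique(c(df$gene_a, df$gene_b[has_b])))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(has_b)) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(df[has_b, 1:2]))))
  }
  igraph::simplify(g)
}
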