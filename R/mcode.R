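#' MCODE parameter set
#'
#' Parameters of the dense-module mining algorithm of Bader & Hogue (2003).
#' Defaults follow the Cytoscape plugin defaults with the commonly used
#' setting degree cutoff 2, k-core 3, node score cutoff 0.2 and a minimum
#' module size of 4 nodes.
#'
#' @param degree_cutoff nodes below this degree get vertex weight 0
#' @param k_core a predicted complex must contain a k-core of this order
#' @param node_score_cutoff fraction in `[0,1]`; neighbours are admitted when
#'   their weight is at least `(1 - node_score_cutoff)` times the seed weight
#' @param haircut remove singly-connected nodes from each complex (the
#'   complex is reduced to its 2-core)
#' @param fluff unsupported overlap post-processing; must stay `FALSE`
#' @param min_module_size post-filter on module size
#' @return a list of class `mcode_params`
#' @export
mcode_params <- function(degree_cutoff = 2, k_core = 3,
                         node_score_cutoff = 0.2, haircut = TRUE,
                         fluff = FALSE, min_module_size = 4) {
  stopifnot(node_score_cutoff >= 0, node_score_cutoff <= 1, k_core >= 2,
            degree_cutoff >= 0, min_module_size >= 1)
  if (isTRUE(fluff)) stop("fluff post-processing is not implemented")
  structure(list(degree_cutoff = degree_cutoff, k_core = k_core,
                 node_score_cutoff = node_score_cutoff, haircut = haircut,
                 fluff = FALSE, min_module_size = min_module_size),
            class = "mcode_params")
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weighting
#'
#' The weight of a node is the product of the highest core number `k` found
#' in its closed neighbourhood and the edge density of that highest k-core.
#' Nodes whose degree falls below `degree_cutoff` are weighted 0.
#'
#' @param net an `igraph` simple graph with named vertices
#' @param degree_cutoff minimum degree for a non-zero weight
#' @return named numeric vector of weights
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2) {
  deg <- igraph::degree(net)
  w <- stats::setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  for (v in igraph::V(net)$name) {
    if (deg[[v]] < degree_cutoff) next
    nb <- c(v, igraph::V(net)$name[
      igraph::neighbors(net, v)])
    sub <- igraph::induced_subgraph(net, unique(nb))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    kcore <- igraph::induced_subgraph(sub, names(core)[core == kmax])
    w[[v]] <- kmax * graph_density(kcore)
  }
  w
}

# iterative 2-core of a vertex set within net (haircut semantics)
two_core_members <- function(net, members) {
  repeat {
    sub <- igraph::induced_subgraph(net, members)
    drop <- igraph::V(sub)$name[igraph::degree(sub) < 2L]
    if (length(drop) == 0L) return(members)
    members <- setdiff(members, drop)
    if (length(members) == 0L) return(members)
  }
}

#' Predict dense complexes (MCODE complex prediction + post-processing)
#'
#' Seeds are taken in descending weight order (ties broken by lexicographic
#' gene id). Each seed is grown breadth-first: an unassigned, unvisited
#' neighbour joins when its weight is at least `(1 - node_score_cutoff)`
#' times the seed weight. A grown complex is kept only if it contains a
#' 2-core; its nodes are then assigned (excluded from later complexes).
#' Post-processing applies the haircut, requires a k-core of order
#' `params$k_core` and at least `params$min_module_size` nodes, and scores
#' each module by `density * size`. Output is sorted by score (descending),
#' ties by member ids, with ids `M001`, `M002`, ...
#'
#' @param net an `igraph` simple graph with named vertices
#' @param weights named weights from [mcode_vertex_weights()] (computed with
#'   the same `degree_cutoff`); computed on the fly when `NULL`
#' @param params an [mcode_params()] list
#' @return list of modules; each module is a list with `module_id`, `genes`
#'   (sorted character vector), `seed_gene`, `score` and `tags`
#' @export
mcode_find_modules <- function(net, weights = NULL, params = mcode_params()) {
  if (igraph::vcount(net) == 0L) return(list())
  if (is.null(weights)) {
    weights <- mcode_vertex_weights(net, params$degree_cutoff)
  }
  nodes <- igraph::V(net)$name
  seed_order <- nodes[order(-weights[nodes], nodes)]
  assigned <- character(0)
  raw <- list()
  for (seed in seed_order) {
    if (weights[[seed]] <= 0 || seed %in% assigned) next
    threshold <- (1 - params$node_score_cutoff) * weights[[seed]]
    members <- seed
    visited <- seed
    frontier <- seed
    while (length(frontier) > 0L) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in igraph::V(net)$name[igraph::neighbors(net, v)]) {
          if (u %in% visited || u %in% assigned) next
          visited <- c(visited, u)
          if (weights[[u]] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    sub <- igraph::induced_subgraph(net, members)
    if (length(members) < 2L || max(igraph::coreness(sub)) < 2L) next
    assigned <- c(assigned, members)
    raw[[length(raw) + 1L]] <- list(seed = seed, members = members)
  }

  modules <- list()
  for (cx in raw) {
    members <- cx$members
    if (params$haircut) members <- two_core_members(net, members)
    if (length(members) < params$min_module_size) next
    sub <- igraph::induced_subgraph(net, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    modules[[length(modules) + 1L]] <- list(
      genes = sort(members),
      seed_gene = cx$seed,
      score = graph_density(sub) * length(members)
    )
  }
  if (length(modules) == 0L) return(list())
  key <- vapply(modules, function(m) paste(m$genes, collapse = ","),
                character(1L))
  ord <- order(-vapply(modules, `[[`, numeric(1L), "score"), key)
  modules <- modules[ord]
  for (i in seq_along(modules)) {
    modules[[i]] <- c(list(module_id = sprintf("M%03d", i)), modules[[i]],
                      list(tags = character(0)))
  }
  modules
}

#' Tag modules by the contrasts whose DEGs they contain
#'
#' A module receives the tag of contrast X iff it contains at least one DEG
#' of X; untagged modules are dropped (they are not initial modules).
#'
#' @param modules list of modules from [mcode_find_modules()]
#' @param degs named list of per-contrast DEG gene sets
#' @return the tagged subset of `modules`
#' @export
classify_initial <- function(modules, degs) {
  out <- list()
  for (m in modules) {
    tags <- names(degs)[vapply(degs, function(s) {
      length(intersect(s, m$genes)) > 0L
    }, logical(1L))]
    if (length(tags) == 0L) next
    m$tags <- tags
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Write modules to JSON / read them back
#' @param modules module list
#' @param file path
#' @export
write_modules <- function(modules, file) {
  jsonlite::write_json(modules, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_modules
#' @export
read_modules <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(m) {
    m$genes <- as.character(m$genes)
    m$tags <- as.character(m$tags %||% character(0))
    m
  })
}
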