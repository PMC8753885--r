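#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical shape of a three-state disease
#' expression study wired to a metabolic reaction table: a dense planted
#' module whose genes are strongly co-expressed in the disease state but not
#' in the reference state, differentially expressed genes with a clean mean
#' shift, and known disease genes placed as spokes around designated hub
#' genes so that the shortest paths between known genes are forced through
#' the hubs (making shortest-path linkage scores computable by hand).
#'
#' @param n_genes total number of genes (default 200; large enough that
#'   degree-conserved random sets rarely re-draw the planted module's own
#'   genes, mirroring the pool richness of a genome-scale network)
#' @param n_reactions number of reactions; `NULL` = one per gene, larger
#'   values add gene-less filler reactions
#' @param n_samples_per_state samples per state (default 25)
#' @param states ordered state labels; the first is the reference, the
#'   second is the "correlated" disease state carrying the planted structure
#' @param planted_module_size size of the planted dense module (>= 4; the
#'   first four module genes act as hubs)
#' @param corr_within_planted pairwise correlation of module genes in the
#'   correlated state (default 0.9)
#' @param corr_background pairwise correlation of module genes elsewhere
#'   (default 0)
#' @param deg_effect mean log2 shift of planted DEGs in the disease state
#' @param deg_fraction_planted fraction of module genes planted as DEGs
#' @param currency_metabolites currency ids sprinkled into the table
#' @param known_gene_count number of known disease genes (>= 4)
#' @param n_background_degs background genes also planted as DEGs
#' @param noise_sd log2-scale noise standard deviation
#' @param seed integer seed; fixed seed gives byte-identical outputs
#' @return list of class `synth_config`
#' @export
synth_config <- function(n_genes = 200, n_reactions = NULL,
                         n_samples_per_state = 25,
                         states = c("A", "B", "C"),
                         planted_module_size = 8,
                         corr_within_planted = 0.9, corr_background = 0,
                         deg_effect = 2, deg_fraction_planted = 0.5,
                         currency_metabolites = default_currency(),
                         known_gene_count = 8, n_background_degs = 6,
                         noise_sd = 0.5, seed = 1) {
  if (planted_module_size < 4) {
    stop("infeasible config: planted_module_size must be at least 4")
  }
  if (known_gene_count < 4) {
    stop("infeasible config: known_gene_count must be at least 4")
  }
  if (!(corr_background >= 0 && corr_background <= corr_within_planted &&
        corr_within_planted <= 1)) {
    stop("need 0 <= corr_background <= corr_within_planted <= 1")
  }
  if (length(states) < 2L || anyDuplicated(states)) {
    stop("`states` must be >= 2 distinct labels")
  }
  n_reactions <- n_reactions %||% n_genes
  if (n_reactions < n_genes) stop("need at least one reaction per gene")
  if (n_genes < planted_module_size + known_gene_count + 10) {
    stop("n_genes too small for module, known genes and background")
  }
  structure(list(
    n_genes = n_genes, n_reactions = n_reactions,
    n_samples_per_state = n_samples_per_state, states = states,
    planted_module_size = planted_module_size,
    corr_within_planted = corr_within_planted,
    corr_background = corr_background, deg_effect = deg_effect,
    deg_fraction_planted = deg_fraction_planted,
    currency_metabolites = currency_metabolites,
    known_gene_count = known_gene_count,
    n_background_degs = n_background_degs,
    noise_sd = noise_sd, seed = seed
  ), class = "synth_config")
}

synth_gene_ids <- function(cfg) {
  m <- cfg$planted_module_size
  k <- cfg$known_gene_count
  nb <- cfg$n_genes - m - k
  list(module = sprintf("gm%02d", seq_len(m)),
       known = sprintf("gk%02d", seq_len(k)),
       background = sprintf("gb%03d", seq_len(nb)))
}

# spokes per hub: hubs 3 and 4 get one known gene each, the remainder is
# split between hubs 1 and 2 (hub 1 first)
spoke_allocation <- function(k) {
  extra <- k - 2L
  c(ceiling(extra / 2), floor(extra / 2), 1L, 1L)
}

#' Generate a synthetic reaction table with planted network structure
#'
#' Every gene owns one reaction; a designed gene-gene edge `(u, v)` is
#' realised by a private metabolite produced by `u`'s reaction and consumed
#' by `v`'s. The design graph consists of (i) a clique over the planted
#' module (so it survives any 3-core filter), (ii) known genes attached as
#' degree-1 spokes to the four hub genes, (iii) a sparse random background
#' graph tethered to the module's non-hub genes. Currency metabolites are
#' added to at least 10% of reactions; they create no edges because network
#' reconstruction excludes them (unless the exclusion list is overridden).
#'
#' Because spokes have degree 1, every shortest path between two known genes
#' runs spoke - hub (- hub) - spoke, so the linkage count of hub `a` with
#' `c_a` spokes out of `K` known genes is exactly
#' `choose(c_a, 2) + c_a * (K - c_a)` and zero for every other gene. The
#' planted core genes recorded in the ground truth are the hubs attaining
#' the maximal count (the top-quartile rank cut over the four hubs).
#'
#' @param cfg a [synth_config()]
#' @return list with `reactions` (a [reaction_table()]) and `truth` (planted
#'   module, per-contrast DEG sets, known genes, core genes, hub spoke map)
#' @export
generate_reaction_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "reactions"))
  ids <- synth_gene_ids(cfg)
  hubs <- ids$module[1:4]

  edges <- list()
  add_edge <- function(u, v) edges[[length(edges) + 1L]] <<- c(u, v)
  # (i) module clique
  cmb <- combn(ids$module, 2L)
  for (i in seq_len(ncol(cmb))) add_edge(cmb[1, i], cmb[2, i])
  # (ii) known-gene spokes around the hubs
  alloc <- spoke_allocation(cfg$known_gene_count)
  spoke_of <- rep(hubs, alloc)
  for (i in seq_along(ids$known)) add_edge(spoke_of[i], ids$known[i])
  # (iii) background graph with a right-skewed degree distribution: a set
  # of background hubs spans the module genes' degree range, so the
  # degree-conserved null has non-trivial pools (real metabolic networks
  # are heavy-tailed; without this the planted module would be the unique
  # set of high-degree nodes and the null would collapse onto it)
  bg <- ids$background
  pair_key <- new.env(parent = emptyenv())
  try_edge <- function(u, v) {
    if (u == v) return(FALSE)
    key <- paste(sort(c(u, v)), collapse = "|")
    if (!is.null(pair_key[[key]])) return(FALSE)
    pair_key[[key]] <- TRUE
    add_edge(u, v)
    TRUE
  }
  bg_hubs <- sample(bg, max(10L, round(0.2 * length(bg))))
  for (h in bg_hubs) {
    k_h <- sample(5:14, 1L)
    for (b in sample(setdiff(bg, h), k_h)) try_edge(h, b)
  }
  n_bg_edges <- round(1.5 * length(bg))
  drawn <- 0L
  while (drawn < n_bg_edges) {
    uv <- sample(bg, 2L)
    if (try_edge(uv[1], uv[2])) drawn <- drawn + 1L
  }
  tether <- setdiff(ids$module, hubs)
  for (g in tether) for (b in sample(bg, 2L)) add_edge(g, b)

  all_genes <- c(ids$module, ids$known, ids$background)
  subs <- stats::setNames(lapply(all_genes, function(g) paste0("min_", g)),
                          all_genes)
  prods <- stats::setNames(lapply(all_genes, function(g) paste0("mout_", g)),
                           all_genes)
  for (i in seq_along(edges)) {
    u <- edges[[i]][1]; v <- edges[[i]][2]
    met <- sprintf("x_%s_%s", u, v)
    prods[[u]] <- c(prods[[u]], met)
    subs[[v]] <- c(subs[[v]], met)
  }
  # currency metabolites in >= 10% of reactions
  n_cur <- max(1L, ceiling(0.15 * length(all_genes)))
  cur_rx <- sample(all_genes, n_cur)
  cur_ids <- cfg$currency_metabolites[c(1, 2)]
  for (g in cur_rx) {
    subs[[g]] <- c(subs[[g]], paste0(cur_ids[1], "[c]"))
    prods[[g]] <- c(prods[[g]], paste0(cur_ids[2], "[c]"))
  }

  join <- function(x) vapply(x, paste, character(1L), collapse = ";")
  rx_ids <- paste0("R_", all_genes)
  genes_col <- all_genes
  if (cfg$n_reactions > length(all_genes)) {
    extra <- cfg$n_reactions - length(all_genes)
    rx_ids <- c(rx_ids, sprintf("R_fill%03d", seq_len(extra)))
    for (i in seq_len(extra)) {
      subs[[length(subs) + 1L]] <- sprintf("fill_in_%03d", i)
      prods[[length(prods) + 1L]] <- sprintf("fill_out_%03d", i)
    }
    genes_col <- c(genes_col, rep("", extra))
  }
  rt <- reaction_table(rx_ids, join(subs), join(prods), genes_col)

  n_mod_deg <- ceiling(cfg$deg_fraction_planted * cfg$planted_module_size)
  mod_degs <- ids$module[seq_len(n_mod_deg)]
  bg_degs <- sort(sample(bg, min(cfg$n_background_degs, length(bg))))
  shifted <- c(mod_degs, bg_degs)
  s <- cfg$states
  deg_sets <- list()
  for (i in seq_len(length(s) - 1L)) {
    for (j in seq(i + 1L, length(s))) {
      key <- paste(s[i], s[j], sep = "_")
      # shifts apply in state 2 only: contrasts involving it see the DEGs
      deg_sets[[key]] <- if (s[2] %in% c(s[i], s[j])) shifted else character(0)
    }
  }

  K <- cfg$known_gene_count
  b_hub <- choose(alloc, 2) + alloc * (K - alloc)
  core <- hubs[b_hub == max(b_hub)]
  truth <- list(
    planted_module_genes = ids$module,
    planted_deg_sets = deg_sets,
    planted_known_genes = ids$known,
    planted_core_genes = core,
    hubs = hubs, spoke_of = stats::setNames(spoke_of, ids$known),
    hub_linkage = stats::setNames(as.numeric(b_hub), hubs),
    shifted_genes = shifted,
    correlated_state = s[2]
  )
  list(reactions = rt, truth = truth)
}

#' Generate a three-state expression matrix with planted structure
#'
#' Values are drawn directly on log2 scale around gene-specific baselines.
#' Module-gene correlation is induced by a single shared latent factor per
#' state (`x = mu + shift + noise_sd * (sqrt(rho) * f + sqrt(1-rho) * eps)`),
#' which keeps the implied correlation matrix positive definite for any
#' `rho` in `[0, 1]`: `rho = corr_within_planted` in the correlated (second)
#' state and `corr_background` elsewhere. Planted DEGs get a `deg_effect`
#' mean shift in the second state only. Background genes are independent
#' noise.
#'
#' @param cfg a [synth_config()]
#' @param truth ground truth from [generate_reaction_table()]
#' @return an [expr_set()] with `n_genes` rows and
#'   `n_samples_per_state * length(states)` columns
#' @export
generate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(stage_seed(cfg$seed, "expression"))
  ids <- synth_gene_ids(cfg)
  genes <- c(ids$module, ids$known, ids$background)
  n_per <- cfg$n_samples_per_state
  samples <- as.vector(vapply(cfg$states, function(s) {
    sprintf("%s_s%02d", s, seq_len(n_per))
  }, character(n_per)))
  states <- rep(cfg$states, each = n_per)
  mu <- stats::setNames(round(runif(length(genes), 4, 10), 3), genes)

  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (si in seq_along(cfg$states)) {
    s <- cfg$states[si]
    cols <- which(states == s)
    rho <- if (s == truth$correlated_state) cfg$corr_within_planted
           else cfg$corr_background
    eps <- matrix(rnorm(length(genes) * n_per), length(genes), n_per)
    f <- rnorm(n_per)
    load <- genes %in% truth$planted_module_genes
    z <- eps
    z[load, ] <- sqrt(rho) * matrix(f, sum(load), n_per, byrow = TRUE) +
      sqrt(1 - rho) * eps[load, , drop = FALSE]
    m[, cols] <- mu + cfg$noise_sd * z
    if (s == truth$correlated_state) {
      m[truth$shifted_genes, cols] <-
        m[truth$shifted_genes, cols] + cfg$deg_effect
    }
  }
  expr_set(m, stats::setNames(states, samples))
}

#' One-call synthetic dataset
#'
#' @param cfg a [synth_config()]
#' @return list with `config`, `reactions`, `truth` and `expression`
#' @export
generate_synthetic <- function(cfg = synth_config()) {
  rt <- generate_reaction_table(cfg)
  ds <- generate_expression(cfg, rt$truth)
  list(config = cfg, reactions = rt$reactions, truth = rt$truth,
       expression = ds)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `expression.tsv`, `states.tsv`, `reactions.tsv`,
#' `known_genes.txt` and `truth.json`.
#'
#' @param sim result of [generate_synthetic()]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "states.tsv"))
  write_reaction_table(sim$reactions, file.path(dir, "reactions.tsv"))
  writeLines(sim$truth$planted_known_genes,
             file.path(dir, "known_genes.txt"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
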