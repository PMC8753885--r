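#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter of the five-step
#' pipeline. Defaults follow the usual protocol for this analysis:
#' fold-change cut 1 (log2), q cut 0.05, 1000 permutations per null, alpha
#' 0.05, minimum module size 4, top-quartile core-gene cut, 100 random sets
#' in the classification comparison.
#'
#' @param expression_file,states_file,reactions_file,known_genes_file input
#'   paths (TSV / TSV / TSV / plain text)
#' @param out_dir directory receiving per-stage artifacts and the report
#' @param contrasts list of 2-vectors of state labels; `NULL` = all ordered
#'   pairs of the states present, in first-appearance order
#' @param max_missing,knn_k missing-value filter threshold and imputation k
#' @param n_perm_sam,s0_quantile,fc_threshold,q_threshold DEG-caller knobs
#' @param currency currency-metabolite exclusion list
#' @param mcode an [mcode_params()] list
#' @param n_rand permutation draws per null for W and MRFms
#' @param alpha significance level on both permutation p-values
#' @param e_method,mi_bins,g2_pairs MRF-score knobs
#' @param quartile core-gene selection fraction
#' @param n_reps random gene sets per classification comparison
#' @param seed global seed; per-stage seeds are derived deterministically
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(expression_file, states_file, reactions_file,
                            known_genes_file, out_dir,
                            contrasts = NULL, max_missing = 0.5, knn_k = 10,
                            n_perm_sam = 1000, s0_quantile = 0.05,
                            fc_threshold = 1, q_threshold = 0.05,
                            currency = default_currency(),
                            mcode = mcode_params(), n_rand = 1000,
                            alpha = 0.05, e_method = "qnorm", mi_bins = NULL,
                            g2_pairs = "edges", quartile = 0.25,
                            n_reps = 100, seed = 1) {
  structure(list(
    expression_file = expression_file, states_file = states_file,
    reactions_file = reactions_file, known_genes_file = known_genes_file,
    out_dir = out_dir, contrasts = contrasts, max_missing = max_missing,
    knn_k = knn_k, n_perm_sam = n_perm_sam, s0_quantile = s0_quantile,
    fc_threshold = fc_threshold, q_threshold = q_threshold,
    currency = currency, mcode = mcode, n_rand = n_rand, alpha = alpha,
    e_method = e_method, mi_bins = mi_bins, g2_pairs = g2_pairs,
    quartile = quartile, n_reps = n_reps, seed = seed
  ), class = "pipeline_config")
}

art <- function(cfg, name) file.path(cfg$out_dir, name)

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

cfg_contrasts <- function(cfg, ds) {
  if (!is.null(cfg$contrasts)) return(cfg$contrasts)
  st <- unique(unname(ds$states))
  out <- list()
  for (i in seq_len(length(st) - 1L)) {
    for (j in seq(i + 1L, length(st))) {
      out[[length(out) + 1L]] <- c(st[i], st[j])
    }
  }
  out
}

#' Individual pipeline stages
#'
#' Each stage reads its inputs from the configured paths or from the
#' artifacts persisted by the previous stage under `out_dir`, and writes its
#' own artifact, so a later stage re-run from disk equals the end-to-end
#' run. [run_pipeline()] simply chains them.
#'
#' @param cfg a [pipeline_config()]
#' @return each stage returns its main result invisibly
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_prep <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- read_expression(cfg$expression_file, cfg$states_file)
  m <- filter_missing(ds$matrix, cfg$max_missing)
  if (anyNA(m)) m <- knn_impute(m, cfg$knn_k)
  ds <- expr_set(m, ds$states)
  write_expression(ds, art(cfg, "prep_expression.tsv"),
                   art(cfg, "prep_states.tsv"))
  log_stage("prep", nrow(m), " genes x ", ncol(m), " samples after prep")
  invisible(ds)
}

read_prep <- function(cfg) {
  read_expression(art(cfg, "prep_expression.tsv"),
                  art(cfg, "prep_states.tsv"))
}

#' @rdname pipeline_stages
#' @export
stage_deg <- function(cfg) {
  ds <- read_prep(cfg)
  tabs <- list()
  for (ct in cfg_contrasts(cfg, ds)) {
    set.seed(stage_seed(cfg$seed, paste0("deg_", ct[1], "_", ct[2])))
    tabs[[length(tabs) + 1L]] <-
      sam_degs(ds, ct, n_perm = cfg$n_perm_sam,
               s0_quantile = cfg$s0_quantile,
               fc_threshold = cfg$fc_threshold,
               q_threshold = cfg$q_threshold)
  }
  deg_table <- do.call(rbind, tabs)
  write.table(deg_table, art(cfg, "degs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  counts <- table(deg_table$contrast[deg_table$is_deg])
  log_stage("deg", paste(names(counts), as.integer(counts), sep = "=",
                         collapse = ", ") %||% "no DEGs")
  invisible(deg_table)
}

#' @rdname pipeline_stages
#' @export
stage_net <- function(cfg) {
  rt <- read_reaction_table(cfg$reactions_file)
  net <- build_network(rt, currency = cfg$currency)
  write_edge_list(net, art(cfg, "edges.tsv"))
  log_stage("net", igraph::vcount(net), " nodes, ", igraph::ecount(net),
            " edges")
  invisible(net)
}

#' @rdname pipeline_stages
#' @export
stage_mine <- function(cfg) {
  net <- read_edge_list(art(cfg, "edges.tsv"))
  deg_table <- read.delim(art(cfg, "degs.tsv"), stringsAsFactors = FALSE)
  degs <- deg_sets(deg_table)
  modules <- mcode_find_modules(net, params = cfg$mcode)
  tagged <- classify_initial(modules, degs)
  tagged_ids <- vapply(tagged, `[[`, character(1L), "module_id")
  for (i in seq_along(modules)) {
    hit <- match(modules[[i]]$module_id, tagged_ids)
    if (!is.na(hit)) modules[[i]]$tags <- tagged[[hit]]$tags
  }
  write_modules(modules, art(cfg, "modules.json"))
  log_stage("mine", length(modules), " modules, ", length(tagged),
            " initial (tagged)")
  invisible(modules)
}

contrast_from_tag <- function(tag) strsplit(tag, "_", fixed = TRUE)[[1]]

#' @rdname pipeline_stages
#' @export
stage_score <- function(cfg) {
  net <- read_edge_list(art(cfg, "edges.tsv"))
  ds <- read_prep(cfg)
  modules <- read_modules(art(cfg, "modules.json"))
  initial <- Filter(function(m) length(m$tags) > 0L, modules)
  rows <- list()
  for (m in initial) {
    for (tag in m$tags) {
      ct <- contrast_from_tag(tag)
      ws <- w_score(ds, m$genes, ct)
      set.seed(stage_seed(cfg$seed, paste0("score_", m$module_id, "_", tag)))
      pr <- permutation_pvalues(
        net, m$genes,
        function(genes) w_score(ds, genes, ct)$W,
        n_rand = cfg$n_rand, statistic_name = "W")
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m$module_id, contrast = tag, H = ws$H,
        H_prime = ws$H_prime, W = ws$W, p_degree = pr$p_degree,
        p_size = pr$p_size,
        candidate = pr$p_degree < cfg$alpha && pr$p_size < cfg$alpha,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(module_id = character(0), contrast = character(0),
               H = numeric(0), H_prime = numeric(0), W = numeric(0),
               p_degree = numeric(0), p_size = numeric(0),
               candidate = logical(0))
  write.table(tab, art(cfg, "wscores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("score", sum(tab$candidate), " candidate module-contrast pairs")
  invisible(tab)
}

#' @rdname pipeline_stages
#' @export
stage_mrf <- function(cfg) {
  net <- read_edge_list(art(cfg, "edges.tsv"))
  ds <- read_prep(cfg)
  modules <- read_modules(art(cfg, "modules.json"))
  by_id <- stats::setNames(modules,
                           vapply(modules, `[[`, character(1L), "module_id"))
  wtab <- read.delim(art(cfg, "wscores.tsv"), stringsAsFactors = FALSE)
  deg_table <- read.delim(art(cfg, "degs.tsv"), stringsAsFactors = FALSE)
  degs <- deg_sets(deg_table)
  cand <- wtab[wtab$candidate, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    mid <- cand$module_id[i]; tag <- cand$contrast[i]
    ct <- contrast_from_tag(tag)
    m <- by_id[[mid]]
    deg_genes <- degs[[tag]] %||% character(0)
    set.seed(stage_seed(cfg$seed, paste0("mrf_", mid, "_", tag)))
    sel <- select_risk_modules(net, list(m), ds, ct, deg_genes,
                               n_rand = cfg$n_rand, alpha = cfg$alpha,
                               e_method = cfg$e_method,
                               mi_bins = cfg$mi_bins,
                               g2_pairs = cfg$g2_pairs)
    E <- expression_difference(ds, m$genes, ct, method = cfg$e_method)
    sc <- mrfms(net, m$genes, E, deg_genes, ds = ds, contrast = ct,
                mi_bins = cfg$mi_bins, g2_pairs = cfg$g2_pairs)
    pr <- sel$results[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      module_id = mid, contrast = tag, mrfms = sc$mrfms, term1 = sc$term1,
      term2 = sc$term2, p_degree = pr$p_degree, p_size = pr$p_size,
      risk = unname(sel$risk[1]), stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(module_id = character(0), contrast = character(0),
               mrfms = numeric(0), term1 = numeric(0), term2 = numeric(0),
               p_degree = numeric(0), p_size = numeric(0), risk = logical(0))
  write.table(tab, art(cfg, "risk.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("mrf", sum(tab$risk), " risk module-contrast pairs")
  invisible(tab)
}

#' @rdname pipeline_stages
#' @export
stage_core <- function(cfg) {
  net <- read_edge_list(art(cfg, "edges.tsv"))
  modules <- read_modules(art(cfg, "modules.json"))
  by_id <- stats::setNames(modules,
                           vapply(modules, `[[`, character(1L), "module_id"))
  risk <- read.delim(art(cfg, "risk.tsv"), stringsAsFactors = FALSE)
  risk_ids <- unique(risk$module_id[risk$risk])
  known <- read_known_genes(cfg$known_genes_file)
  empty <- data.frame(gene_id = character(0), B = integer(0),
                      rank = integer(0), is_candidate = logical(0),
                      is_core = logical(0))
  if (length(risk_ids) == 0L) {
    write.table(empty, art(cfg, "core_genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    log_stage("core", "no risk modules; no core genes")
    return(invisible(empty))
  }
  risk_genes <- sort(unique(unlist(lapply(by_id[risk_ids], `[[`, "genes"))))
  scores <- pair_linkage_scores(net, risk_genes, known)
  core <- suppressWarnings(select_core(scores, cfg$quartile))
  scores$is_core <- scores$gene_id %in% core
  write.table(scores, art(cfg, "core_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  log_stage("core", sum(scores$is_candidate), " candidate genes, ",
            length(core), " core genes")
  invisible(scores)
}

#' @rdname pipeline_stages
#' @export
stage_classify <- function(cfg) {
  ds <- read_prep(cfg)
  modules <- read_modules(art(cfg, "modules.json"))
  by_id <- stats::setNames(modules,
                           vapply(modules, `[[`, character(1L), "module_id"))
  risk <- read.delim(art(cfg, "risk.tsv"), stringsAsFactors = FALSE)
  core_tab <- read.delim(art(cfg, "core_genes.tsv"),
                         stringsAsFactors = FALSE)
  deg_table <- read.delim(art(cfg, "degs.tsv"), stringsAsFactors = FALSE)
  degs <- deg_sets(deg_table)
  core <- core_tab$gene_id[core_tab$is_core]
  cand_genes <- core_tab$gene_id[core_tab$is_candidate]
  risk_tags <- unique(risk$contrast[risk$risk])
  risk_genes <- sort(unique(unlist(
    lapply(by_id[unique(risk$module_id[risk$risk])], `[[`, "genes"))))

  auc_rows <- list()
  comparisons <- list()
  if (length(core) > 0L) {
    for (tag in risk_tags) {
      ct <- contrast_from_tag(tag)
      res <- svm_loocv_auc(ds, core, ct)
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        feature_set = "core_genes", contrast = tag, auc = res$auc,
        stringsAsFactors = FALSE)
      deg_genes <- degs[[tag]] %||% character(0)
      pool1 <- setdiff(cand_genes, core)
      set.seed(stage_seed(cfg$seed, paste0("classify_size_", tag)))
      comparisons[[paste0(tag, ".size")]] <- if (length(pool1) >= length(core)) {
        random_set_comparison(ds, core, pool1, ct, scheme = "size",
                              n_reps = cfg$n_reps)
      } else list(scheme = "size", note = "pool smaller than core set")
      set.seed(stage_seed(cfg$seed, paste0("classify_comp_", tag)))
      comparisons[[paste0(tag, ".composition")]] <- tryCatch(
        random_set_comparison(ds, core, risk_genes, ct,
                              deg_genes = deg_genes,
                              scheme = "composition", n_reps = cfg$n_reps),
        error = function(e) list(scheme = "composition",
                                 note = conditionMessage(e)))
    }
  }
  auc_tab <- if (length(auc_rows) > 0L) do.call(rbind, auc_rows) else
    data.frame(feature_set = character(0), contrast = character(0),
               auc = numeric(0))
  write.table(auc_tab, art(cfg, "classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(comparisons, art(cfg, "comparison.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("classify", nrow(auc_tab), " AUC rows, ", length(comparisons),
            " comparisons")
  invisible(list(auc = auc_tab, comparisons = comparisons))
}

#' Run the five-step pipeline end to end
#'
#' Chains preprocessing, DEG calling, network reconstruction, module mining
#' and tagging, differential-correlation candidate selection, MRF risk-module
#' selection, shortest-path core-gene identification and SVM evaluation.
#' Every stage persists its artifact under `cfg$out_dir`; the assembled
#' report (all intermediate counts, the seed, the core genes and the AUCs)
#' is written to `report.json` and returned. Re-running with the same
#' configuration reproduces the report byte-identically.
#'
#' @param cfg a [pipeline_config()]
#' @return the report, invisibly
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- Sys.time()
  ds <- stage_prep(cfg)
  deg_table <- stage_deg(cfg)
  net <- stage_net(cfg)
  modules <- stage_mine(cfg)
  wtab <- stage_score(cfg)
  rtab <- stage_mrf(cfg)
  core_tab <- stage_core(cfg)
  cls <- stage_classify(cfg)

  degs <- deg_sets(deg_table)
  initial <- Filter(function(m) length(m$tags) > 0L, modules)
  tag_counts <- table(unlist(lapply(initial, `[[`, "tags")))
  ann <- annotate_degs(net, degs)
  report <- list(
    seed = cfg$seed,
    n_genes = nrow(ds$matrix),
    n_samples = ncol(ds$matrix),
    degs_per_contrast = as.list(vapply(degs, length, integer(1L))),
    network = list(nodes = igraph::vcount(net),
                   edges = igraph::ecount(net),
                   degs_in_network = as.list(ann$counts)),
    n_modules = length(modules),
    n_initial_per_tag = as.list(stats::setNames(as.integer(tag_counts),
                                                names(tag_counts))),
    n_candidate_pairs = sum(wtab$candidate),
    candidate_modules = unique(wtab$module_id[wtab$candidate]),
    n_risk_pairs = sum(rtab$risk),
    risk_modules = unique(rtab$module_id[rtab$risk]),
    n_candidate_genes = sum(core_tab$is_candidate),
    core_genes = core_tab$gene_id[core_tab$is_core],
    auc = cls$auc,
    comparisons = lapply(cls$comparisons, function(x) {
      x[setdiff(names(x), "random_aucs")]
    }),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  )
  # elapsed time would break byte-identity; keep it out of the file
  file_report <- report[setdiff(names(report), "elapsed_s")]
  jsonlite::write_json(file_report, art(cfg, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("run_all", "done in ", report$elapsed_s, "s")
  invisible(report)
}
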