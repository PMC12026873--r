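# End-to-end orchestration: screen -> predict -> differential expression ->
# intersect -> networks -> enrichment, driven by a single flat config, with
# every intermediate written as plain text and a run report whose counts
# can be re-derived from the emitted files. Identical config + seed gives
# an identical output bundle.

#' Default pipeline configuration
#'
#' Thresholds: `bs_min` 0.10 (bioavailability screen), `tc_threshold` 0.45
#' (similarity cutoff, strict >), `z_min` 3.0 (prediction acceptance),
#' `lfc_min` 0.5 and `p_max` 0.05 (DEG filter, both inclusive),
#' `ppi_score_min` 400 (STRING medium confidence), `p_adj_max` 0.01
#' (enrichment cutoff on adjusted p, inclusive).
#'
#' @param ... Overrides merged over the defaults.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    compounds = NULL, compound_fps = NULL, target_db = NULL,
    chips = NULL, groups = NULL, probe_map = NULL,
    disease_lists = character(0), ppi = NULL, gmt = NULL,
    bs_min = 0.10, tc_threshold = 0.45, z_min = 3.0,
    lfc_min = 0.5, p_max = 0.05, ppi_score_min = 400, p_adj_max = 0.01,
    deg_method = "moderated", probe_collapse = "max_abs_lfc",
    background_samples = 1000, background_set_sizes = c(2, 5, 10, 20),
    top_k = 20, seed = 1, outdir = "netpharm_out"
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) np_stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
    # resolve relative input paths against the config file's directory
    for (f in c("compounds", "compound_fps", "target_db", "chips", "groups",
                "probe_map", "disease_lists", "ppi", "gmt")) {
      if (!is.null(cfg[[f]])) {
        cfg[[f]] <- ifelse(grepl("^(/|[A-Za-z]:)", cfg[[f]]),
                           cfg[[f]], file.path(base, cfg[[f]]))
      }
    }
    config <- cfg
  }
  do.call(default_config, config)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: bioavailability screening, similarity-ensemble
#' target prediction (with background calibration), per-chip differential
#' expression with the fold-change/p filter and probe collapsing, the
#' cross-chip DEG union and disease-target union, the key-target
#' intersection, compound-target and PPI network construction with degree
#' and betweenness centrality, and over-representation analysis. Every
#' intermediate is written under `outdir`.
#'
#' @param config A config list (see [default_config()]) or the path of a
#'   YAML file with the same keys.
#' @return A `RunReport`: list of per-stage counts, the echoed config, and
#'   stage timings (timings are not written to disk, so reruns with the
#'   same seed produce byte-identical files).
#' @export
run_pipeline <- function(config) {
  cfg <- read_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- with_stage(stage, expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    r
  }
  report <- list()

  # -- screen ---------------------------------------------------------------
  scr <- clock("screen", {
    if (is.null(cfg$compounds) || !file.exists(cfg$compounds)) {
      np_stop("compound table not found: ", cfg$compounds)
    }
    compounds <- read_tsv(cfg$compounds)
    s <- screen_compounds(compounds, cfg$bs_min)
    write_tsv(s$kept, out("compounds_kept.tsv"))
    write_tsv(s$removed, out("compounds_removed.tsv"))
    s
  })
  report$compounds_in <- scr$report$n_in
  report$compounds_kept <- scr$report$n_kept

  # -- predict --------------------------------------------------------------
  pred <- clock("predict", {
    for (f in c("compound_fps", "target_db")) {
      if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
        np_stop(f, " file not found: ", cfg[[f]])
      }
    }
    fps <- read_fingerprints(cfg$compound_fps)
    fps <- fps[rownames(fps) %in% scr$kept$id, , drop = FALSE]
    db <- read_target_db(cfg$target_db)
    model <- calibrate_background(
      db, set_sizes = cfg$background_set_sizes,
      n_samples = cfg$background_samples,
      tc_threshold = cfg$tc_threshold, seed = cfg$seed)
    p <- predict_targets_all(fps, db, model, z_min = cfg$z_min)
    write_tsv(p, out("predictions.tsv"))
    p
  })
  predicted_genes <- normalize_symbols(pred$gene_symbol)
  report$predicted_pairs <- nrow(pred)
  report$predicted_targets <- length(predicted_genes)

  # -- deg ------------------------------------------------------------------
  degs <- clock("deg", {
    if (length(cfg$chips) < 1) np_stop("no expression chips configured")
    if (length(cfg$groups) != length(cfg$chips)) {
      np_stop("need one group sidecar per chip")
    }
    for (f in c(cfg$chips, cfg$groups, cfg$probe_map)) {
      if (!file.exists(f)) np_stop("file not found: ", f)
    }
    pmap <- read_tsv(cfg$probe_map)
    lapply(seq_along(cfg$chips), function(i) {
      m <- read_series_matrix(cfg$chips[i], cfg$groups[i])
      de <- differential_expression(m, method = cfg$deg_method,
                                    probe_gene_map = pmap)
      hits <- filter_degs(de, cfg$lfc_min, cfg$p_max)
      genes <- collapse_probes(hits, how = cfg$probe_collapse)
      write_tsv(de, out(sprintf("deg_chip%d_all.tsv", i)))
      write_tsv(genes, out(sprintf("deg_chip%d_genes.tsv", i)))
      list(n_probe = nrow(hits), genes = genes$gene_symbol)
    })
  })
  for (i in seq_along(degs)) {
    report[[sprintf("deg_chip%d_probes", i)]] <- degs[[i]]$n_probe
    report[[sprintf("deg_chip%d_genes", i)]] <- length(degs[[i]]$genes)
  }
  deg_union <- union_deg_sets(lapply(degs, `[[`, "genes"))
  writeLines(deg_union, out("deg_union.txt"))
  report$deg_union <- length(deg_union)

  disease <- clock("disease", {
    build_disease_targets(deg_union, as.list(cfg$disease_lists))
  })
  writeLines(disease, out("disease_targets.txt"))
  report$disease_targets <- length(disease)

  # -- network --------------------------------------------------------------
  nets <- clock("network", {
    key <- intersect_targets(predicted_genes, disease)
    writeLines(key, out("key_targets.txt"))
    ct <- build_ct_network(pred, key)
    ct_tab <- centrality_table(ct)
    write_tsv(ct_tab, out("ct_nodes.tsv"))
    write_sif(ct, out("ct_network.sif"))
    write_graphml(ct, out("ct_network.graphml"))
    hubs <- rank_hubs(ct, deg_set = deg_union)
    writeLines(hubs$core, out("ct_core_targets.txt"))
    ppi <- NULL
    if (!is.null(cfg$ppi)) {
      ppi <- read_ppi_edges(cfg$ppi, cfg$ppi_score_min, allowed_nodes = key)
      write_tsv(centrality_table(ppi), out("ppi_nodes.tsv"))
      write_sif(ppi, out("ppi_network.sif"))
      write_graphml(ppi, out("ppi_network.graphml"))
    }
    list(key = key, ct = ct, ct_tab = ct_tab, hubs = hubs, ppi = ppi)
  })
  report$key_targets <- length(nets$key)
  report$ct_nodes <- igraph::vcount(nets$ct)
  report$ct_edges <- igraph::ecount(nets$ct)
  cmp_deg <- nets$ct_tab$degree[nets$ct_tab$kind == "compound"]
  report$ct_mean_compound_degree <- if (length(cmp_deg)) mean(cmp_deg) else 0
  report$ct_core_targets <- length(nets$hubs$core)
  if (!is.null(nets$ppi)) {
    report$ppi_nodes <- igraph::vcount(nets$ppi)
    report$ppi_edges <- igraph::ecount(nets$ppi)
  }

  # -- enrich ---------------------------------------------------------------
  enr <- clock("enrich", {
    if (is.null(cfg$gmt)) return(NULL)
    if (!file.exists(cfg$gmt)) np_stop("GMT file not found: ", cfg$gmt)
    collection <- read_gmt(cfg$gmt)
    rows <- enrich(nets$key, collection, p_adj_max = cfg$p_adj_max)
    write_tsv(rows, out("enrichment.tsv"))
    write_tsv(top_terms(rows, cfg$top_k), out("enrichment_top.tsv"))
    rows
  })
  if (!is.null(enr)) {
    report$terms_tested <- nrow(enr)
    report$terms_significant <- sum(enr$significant)
  }

  # report file: deterministic (no timings)
  write_tsv(data.frame(key = names(report),
                       value = vapply(report, function(x)
                         format(x, digits = 10), ""),
                       stringsAsFactors = FALSE),
            out("report.tsv"))
  structure(list(counts = report, config = cfg, timings = timings),
            class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("netpharm run report\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-26s %s\n", k, format(x$counts[[k]], digits = 6)))
  }
  invisible(x)
}

#' Write a complete synthetic demo input bundle
#'
#' Generates a coherent synthetic study — ligand universe, query compounds
#' with planted compound-target associations, two expression chips with
#' planted differentially expressed genes (the planted set includes the
#' genes of the truly targeted proteins, so the key-target intersection is
#' recoverable), a disease gene list, an annotation collection with one
#' planted term (the truly targeted genes), and random PPI edges — and
#' writes every file plus the ground-truth tables and a ready-to-run
#' `config.yaml`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param n_targets,ligands_per_target,fp_length,within_set_similarity
#'   Ligand-universe settings.
#' @param n_actives,n_decoys,perturb_bits Query-compound settings.
#' @param n_genes,n_case,n_control,n_planted,effect,sigma Expression
#'   settings.
#' @param n_terms,term_size_range Annotation settings.
#' @param n_disease_extra Extra (non-DEG) disease genes.
#' @param ppi_edge_prob PPI edge probability.
#' @return The path of the written `config.yaml`, invisibly; the truth
#'   tables live under `outdir/truth/`.
#' @export
make_demo <- function(outdir, seed = 7,
                      n_targets = 30, ligands_per_target = 8,
                      fp_length = 512, within_set_similarity = 0.65,
                      n_actives = 25, n_decoys = 10, perturb_bits = 8,
                      n_genes = 2000, n_case = 20, n_control = 20,
                      n_planted = 60, effect = 2, sigma = 0.5,
                      n_terms = 120, term_size_range = c(10, 50),
                      n_disease_extra = 120, ppi_edge_prob = 0.05) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  set.seed(seed)
  target_genes <- sample(genes[seq_len(min(400, n_genes))], n_targets)

  uni <- generate_ligand_universe(
    n_targets, ligands_per_target, fp_length, within_set_similarity,
    seed = seed, gene_symbols = target_genes)
  cmp <- generate_query_compounds(uni, n_actives, n_decoys, perturb_bits,
                                  seed = seed + 1)
  gene_of <- vapply(uni$universe, `[[`, "", "gene_symbol")
  active_genes <- sort(unique(gene_of[cmp$truth$active_pairs$target_id]))

  set.seed(seed + 2)
  planted <- unique(c(active_genes,
                      sample(setdiff(genes, active_genes),
                             max(0, n_planted - length(active_genes)))))
  chips <- generate_expression_chips(
    n_genes, n_case, n_control, n_planted = length(planted),
    effect = effect, sigma = sigma, seed = seed + 3,
    gene_symbols = genes, planted_genes = planted)

  set.seed(seed + 4)
  disease_extra <- sort(sample(setdiff(genes, planted), n_disease_extra))
  ann <- generate_annotations(genes, n_terms, term_size_range,
                              planted_term_genes = active_genes,
                              seed = seed + 5)
  ppi_nodes <- unique(c(active_genes,
                        sample(genes, min(250, n_genes))))
  ppi <- generate_ppi_edges(ppi_nodes, ppi_edge_prob, seed = seed + 6)

  write_tsv(cmp$compounds, p("compounds.tsv"))
  write_fingerprints(cmp$fingerprints, p("compound_fps.tsv"))
  write_target_db(uni, p("target_db.tsv"))
  write_series_matrix(chips$chips[[1]], p("chip1.tsv"), p("groups1.tsv"))
  write_series_matrix(chips$chips[[2]], p("chip2.tsv"), p("groups2.tsv"))
  write_tsv(chips$probe_gene_map, p("probe_map.tsv"))
  writeLines(disease_extra, p("disease_genes.txt"))
  write_string_edges(ppi, p("ppi.tsv"))
  write_gmt(ann$collection, p("annotations.gmt"))

  write_tsv(cmp$truth$active_pairs, p("truth/active_pairs.tsv"))
  write_tsv(data.frame(gene_symbol = names(chips$truth$planted_effect),
                       effect = unname(chips$truth$planted_effect),
                       stringsAsFactors = FALSE),
            p("truth/planted_degs.tsv"))
  writeLines(active_genes, p("truth/active_target_genes.txt"))
  writeLines(ann$truth$enriched_terms, p("truth/enriched_terms.txt"))

  cfg <- list(compounds = "compounds.tsv", compound_fps = "compound_fps.tsv",
              target_db = "target_db.tsv",
              chips = c("chip1.tsv", "chip2.tsv"),
              groups = c("groups1.tsv", "groups2.tsv"),
              probe_map = "probe_map.tsv",
              disease_lists = "disease_genes.txt",
              ppi = "ppi.tsv", gmt = "annotations.gmt",
              seed = seed, outdir = file.path(outdir, "results"))
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}
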