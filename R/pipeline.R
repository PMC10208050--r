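#' Default pipeline configuration
#'
#' Builds the declarative configuration driving [run_cerna_pipeline()].
#' Defaults carry the analysis thresholds used throughout the package: DE
#' cutoffs `|logFC| > 1` at FDR < 0.05 (the FDR cutoff is deliberately a
#' parameter — see the methods vignette for the 0.01 vs 0.05 discussion),
#' enrichment FDR < 0.01, and a top-6 hub lncRNA ranking. In `"synthetic"`
#' input mode the pipeline first writes a fully synthetic input bundle
#' (see [write_synthetic_inputs()]) and then runs on those files; in
#' `"files"` mode the six input paths must be supplied.
#'
#' @param ... Named overrides merged (recursively) into the defaults, e.g.
#'   `de = list(fdr_max = 0.01)` or `inputs = list(mode = "files", paths = ...)`.
#' @return A list of class `cerna_config`.
#' @export
cerna_config <- function(...) {
  defaults <- list(
    seed = 1L,
    inputs = list(
      mode = "synthetic",
      synth = list(),       # overrides for synth_config()
      paths = list()        # used in "files" mode
    ),
    filter = list(min_value = 0, min_fraction = 1),
    log2 = list(offset = 1),
    de = list(lfc_min = 1, fdr_max = 0.05, paired = FALSE,
              group_a = "day0", group_b = "day8"),
    enrichment = list(fdr_threshold = 0.01),
    ranking = list(top_k = 6),
    export_formats = c("sif", "graphml", "tsv"),
    qpcr = list(reference_gene = "GAPDH")
  )
  cfg <- utils::modifyList(defaults, list(...))
  validate_cerna_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a `cerna_config` list or the path to a YAML file with the same
#' structure. Every violation is collected and reported together, not just
#' the first.
#'
#' @param config A list or a YAML file path.
#' @return The validated configuration, classed `cerna_config`; invalid
#'   configurations abort with the full violation report.
#' @export
validate_cerna_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_cernet(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  chk_num <- function(x, name, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      note(sprintf("%s must be in [%s, %s]", name, format(lo), format(hi)))
    }
  }
  chk_num(config$de$fdr_max %||% NA, "de.fdr_max", 0, 1)
  chk_num(config$de$lfc_min %||% NA, "de.lfc_min", 0, Inf)
  chk_num(config$filter$min_fraction %||% NA, "filter.min_fraction", 0, 1)
  chk_num(config$log2$offset %||% NA, "log2.offset", 0, Inf)
  chk_num(config$enrichment$fdr_threshold %||% NA, "enrichment.fdr_threshold", 0, 1)
  if (!is.numeric(config$ranking$top_k %||% NA) || (config$ranking$top_k %||% 0) < 1) {
    note("ranking.top_k must be at least 1")
  }
  seed <- config$seed %||% NA
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    note("seed must be an integer")
  }
  mode <- config$inputs$mode %||% ""
  if (!mode %in% c("synthetic", "files")) {
    note("inputs.mode must be 'synthetic' or 'files'")
  }
  if (identical(mode, "files")) {
    required <- c("expression", "groups", "annotation", "lnc_mi",
                  "mi_m_db1", "mi_m_db2", "gene_sets")
    for (key in required) {
      path <- config$inputs$paths[[key]]
      if (is.null(path)) {
        note(sprintf("inputs.paths.%s is required in files mode", key))
      } else if (!file.exists(path)) {
        note(sprintf("inputs.paths.%s does not exist: %s", key, path))
      }
    }
  }
  bad_fmt <- setdiff(config$export_formats %||% character(), c("sif", "graphml", "tsv"))
  if (length(bad_fmt)) {
    note(paste0("unknown export formats: ", paste(bad_fmt, collapse = ", ")))
  }
  if (length(problems)) {
    stop_cernet(paste0(
      "invalid pipeline configuration:\n",
      paste0("  - ", problems, collapse = "\n")
    ), class = "cernet_config_error")
  }
  structure(config, class = unique(c("cerna_config", class(config))))
}

#' Run the full ceRNA analysis pipeline
#'
#' Executes every stage in order — input generation or loading, expression
#' preprocessing, differential expression, interaction integration,
#' network construction and ranking, per-lncRNA subnetworks with
#' enrichment, and (when a Ct table is available) qPCR quantification —
#' writing all artifacts into a run directory. A manifest with per-stage
#' row counts is written even when a stage fails, and every log line that
#' reports a count mirrors the quantities a study would report narratively
#' (probes kept, DEM/DEL counts, network summary).
#'
#' @param config A [cerna_config()] (or YAML path accepted by
#'   [validate_cerna_config()]).
#' @param outdir Run directory; created if needed.
#' @return Invisibly, a list with `outdir` and the run `manifest`.
#' @export
run_cerna_pipeline <- function(config, outdir) {
  config <- validate_cerna_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("cernet")),
    counts = list(),
    timestamps = list(started = format(Sys.time(), usetz = TRUE))
  )
  log_line <- function(...) {
    cat(sprintf("INFO %s\n", sprintf(...)), file = log_path, append = TRUE)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("stage '%s' failed: %s", name, conditionMessage(e))
      manifest$timestamps$failed_stage <<- name
      write_manifest()
      stop_cernet(sprintf("stage '%s': %s", name, conditionMessage(e)),
                  class = "cernet_stage_error")
    })
  }
  quiet <- function(expr) withCallingHandlers(
    expr, message = function(m) invokeRestart("muffleMessage")
  )

  # --- inputs ---------------------------------------------------------
  paths <- stage("inputs", {
    if (identical(config$inputs$mode, "synthetic")) {
      synth_args <- config$inputs$synth
      synth_args$seed <- synth_args$seed %||% config$seed
      scfg <- do.call(synth_config, synth_args)
      bundle <- write_synthetic_inputs(scfg, file.path(outdir, "inputs"))
      log_line("inputs: synthetic bundle written to %s", file.path(outdir, "inputs"))
      bundle$paths
    } else {
      config$inputs$paths
    }
  })

  # --- expression preprocessing --------------------------------------
  prep <- stage("expression", quiet({
    raw <- read_expression_matrix(paths$expression, paths$groups)
    annot <- read_probe_annotation(paths$annotation)
    kept <- filter_unexpressed(raw, config$filter$min_value, config$filter$min_fraction)
    logged <- log2_transform(kept, offset = config$log2$offset)
    norm <- quantile_normalize(logged)
    genes <- collapse_probes(norm, annot)
    split <- split_by_biotype(genes, annot)
    list(raw = raw, kept = kept, genes = genes, split = split, annot = annot)
  }))
  manifest$counts$probes_total <- nrow(prep$raw)
  manifest$counts$probes_kept <- nrow(prep$kept)
  manifest$counts$genes <- nrow(prep$genes)
  manifest$counts$mrna_genes <- nrow(prep$split$mrna)
  manifest$counts$lncrna_genes <- nrow(prep$split$lncrna)
  log_line("expression: %d/%d probes kept; %d genes (%d mRNA, %d lncRNA)",
           nrow(prep$kept), nrow(prep$raw), nrow(prep$genes),
           nrow(prep$split$mrna), nrow(prep$split$lncrna))

  # --- differential expression ---------------------------------------
  de <- stage("differential_expression", {
    run_de <- function(mat) {
      differential_expression(mat, config$de$group_a, config$de$group_b,
                              paired = config$de$paired) |>
        apply_thresholds(lfc_min = config$de$lfc_min, fdr_max = config$de$fdr_max)
    }
    de_m <- run_de(prep$split$mrna)
    de_l <- run_de(prep$split$lncrna)
    write_de_table(de_m, file.path(outdir, "de_mrna.tsv"))
    write_de_table(de_l, file.path(outdir, "de_lncrna.tsv"))
    list(mrna = de_m, lncrna = de_l)
  })
  gm <- glance(de$mrna); gl <- glance(de$lncrna)
  manifest$counts$dem_up <- gm$n_up; manifest$counts$dem_down <- gm$n_down
  manifest$counts$del_up <- gl$n_up; manifest$counts$del_down <- gl$n_down
  log_line("de: %d DEMs up, %d down; %d DELs up, %d down",
           gm$n_up, gm$n_down, gl$n_up, gl$n_down)

  # --- interaction integration ---------------------------------------
  inter <- stage("interactions", {
    dem <- de_genes(de$mrna)
    del <- de_genes(de$lncrna)
    if (length(dem) == 0L) stop_cernet("empty DE list: no differentially expressed mRNAs")
    if (length(del) == 0L) stop_cernet("empty DE list: no differentially expressed lncRNAs")
    lnc_mi <- read_interaction_table(paths$lnc_mi, "lncRNA-miRNA",
                                     source_db = "lnc_mi_db") |>
      restrict_to_de(del, side = "regulator") |>
      deduplicate_interactions()
    db1 <- read_interaction_table(paths$mi_m_db1, "miRNA-mRNA", source_db = "db1")
    db2 <- read_interaction_table(paths$mi_m_db2, "miRNA-mRNA", source_db = "db2")
    mi_m <- intersect_databases(db1, db2) |>
      restrict_to_de(dem, side = "target") |>
      deduplicate_interactions()
    merged <- bind_rows(
      mutate(as_tibble(lnc_mi), kind = "lncRNA-miRNA"),
      mutate(as_tibble(mi_m), kind = "miRNA-mRNA")
    )
    readr::write_tsv(merged, file.path(outdir, "interactions_merged.tsv"),
                     progress = FALSE)
    list(lnc_mi = lnc_mi, mi_m = mi_m)
  })
  manifest$counts$lnc_mi_interactions <- nrow(inter$lnc_mi)
  manifest$counts$mi_m_interactions <- nrow(inter$mi_m)
  log_line("interactions: %d lncRNA-miRNA, %d miRNA-mRNA (both DBs, DE-restricted)",
           nrow(inter$lnc_mi), nrow(inter$mi_m))

  # --- network --------------------------------------------------------
  net_res <- stage("network", {
    net <- build_cerna_network(inter$lnc_mi, inter$mi_m)
    if (nrow(net$edges) == 0L) stop_cernet("network is empty after pruning")
    for (fmt in config$export_formats) {
      export_network(net, file.path(outdir, paste0("network.", fmt)), format = fmt)
    }
    summary_tbl <- network_summary(net)
    jsonlite::write_json(as.list(summary_tbl), file.path(outdir, "network_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    ranking <- rank_lncrnas(net, top_k = config$ranking$top_k)
    readr::write_tsv(ranking, file.path(outdir, "lncrna_ranking.tsv"), progress = FALSE)
    list(net = net, ranking = ranking, summary = summary_tbl)
  })
  s <- net_res$summary
  manifest$counts$network <- as.list(s)
  log_line("network: %d lncRNA / %d miRNA / %d mRNA nodes, %d edges",
           s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges)

  # --- enrichment (global + per-lncRNA subnet) -----------------------
  stage("enrichment", quiet({
    gene_sets <- read_gmt(paths$gene_sets)
    universe <- prep$split$mrna$feature_id
    net <- net_res$net
    net_mrnas <- net$nodes$id[net$nodes$node_type == "mRNA"]
    global <- enrich(net_mrnas, gene_sets, universe,
                     fdr_threshold = config$enrichment$fdr_threshold)
    readr::write_tsv(as_tibble(global), file.path(outdir, "enrichment_global.tsv"),
                     progress = FALSE)
    for (lnc in net_res$ranking$lncrna) {
      sub <- extract_subnetwork(net, lnc)
      export_network(sub, file.path(outdir, sprintf("subnet_%s.sif", lnc)),
                     format = "sif")
      sub_mrnas <- sub$nodes$id[sub$nodes$node_type == "mRNA"]
      sub_enr <- enrich(sub_mrnas, gene_sets, universe,
                        fdr_threshold = config$enrichment$fdr_threshold)
      readr::write_tsv(as_tibble(sub_enr),
                       file.path(outdir, sprintf("enrichment_%s.tsv", lnc)),
                       progress = FALSE)
    }
    log_line("enrichment: global + %d subnet analyses", nrow(net_res$ranking))
  }))

  # --- qPCR (optional) ------------------------------------------------
  if (!is.null(paths$ct) && file.exists(paths$ct)) {
    stage("qpcr", {
      ct <- read_ct_table(paths$ct)
      rel <- relative_expression(ct, reference_gene = config$qpcr$reference_gene)
      res <- qpcr_summary(rel)
      readr::write_tsv(res, file.path(outdir, "qpcr_results.tsv"), progress = FALSE)
      manifest$counts$qpcr_genes <- nrow(res)
      log_line("qpcr: %d genes quantified by 2^-deltaCt", nrow(res))
    })
  }

  manifest$timestamps$finished <- format(Sys.time(), usetz = TRUE)
  write_manifest()
  log_line("pipeline finished")
  invisible(list(outdir = outdir, manifest = manifest))
}
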