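#' Configuration for the synthetic ceRNA study generator
#'
#' Parameterizes a synthetic two-timepoint microarray study with planted
#' structure: a probe-level expression matrix over an mRNA/lncRNA mixture
#' with planted differentially expressed genes, lncRNA-miRNA and
#' miRNA-mRNA interaction tables with planted hub lncRNAs, a gene-set
#' library with planted enriched sets, and an RT-qPCR Ct table. All
#' randomness is fixed by `seed`, so identical configurations yield
#' byte-identical outputs.
#'
#' Defaults describe the regime the package is calibrated on: 2,000 genes
#' (10\% lncRNA), two probes per gene, 20 samples per timepoint, Gaussian
#' noise of 0.5 log2-units around a baseline of 8, planted shifts of 2
#' log2-units, 60 miRNAs, 5 hub lncRNAs sponging 8 miRNAs each over a 1\%
#' background interaction rate, and 50 gene sets of 15-50 genes with 3
#' planted enriched sets.
#'
#' @param n_genes Total genes (mRNA + lncRNA).
#' @param frac_lncrna Fraction of genes that are lncRNAs, in (0, 1).
#' @param probes_per_gene Probes per gene: a single count, or a length-2
#'   range sampled per gene.
#' @param n_samples_per_group Samples in each of the day0 / day8 groups.
#' @param n_de_mrna,n_de_lncrna Planted differentially expressed mRNAs /
#'   lncRNAs.
#' @param effect_size Planted group-mean shift, log2-units.
#' @param noise_sd Per-measurement Gaussian noise, log2-units.
#' @param baseline_mean Baseline log2 intensity.
#' @param n_mirnas miRNAs in the interaction tables.
#' @param n_hub_lncrnas Planted hub lncRNAs (each also planted DE).
#' @param hub_degree miRNA partners per planted hub.
#' @param bg_interaction_prob Probability of each background
#'   regulator-target pair.
#' @param db_overlap_frac Fraction of background miRNA-mRNA pairs written
#'   to both target databases (planted hub-supporting pairs always are).
#' @param n_gene_sets Gene sets in the library.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param n_enriched_sets Sets planted to draw >= 70\% of members from the
#'   planted DE mRNAs.
#' @param paired Generate patient-paired day0/day8 samples.
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         frac_lncrna = 0.1,
                         probes_per_gene = 2,
                         n_samples_per_group = 20,
                         n_de_mrna = 150,
                         n_de_lncrna = 20,
                         effect_size = 2,
                         noise_sd = 0.5,
                         baseline_mean = 8,
                         n_mirnas = 60,
                         n_hub_lncrnas = 5,
                         hub_degree = 8,
                         bg_interaction_prob = 0.01,
                         db_overlap_frac = 0.5,
                         n_gene_sets = 50,
                         set_size_range = c(15, 50),
                         n_enriched_sets = 3,
                         paired = FALSE,
                         seed = 1) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes", 2),
    frac_lncrna = assert_scalar_number(frac_lncrna, "frac_lncrna", 0, 1,
                                       strict_lower = TRUE, strict_upper = TRUE),
    probes_per_gene = probes_per_gene,
    n_samples_per_group = assert_count(n_samples_per_group, "n_samples_per_group", 2),
    n_de_mrna = assert_count(n_de_mrna, "n_de_mrna"),
    n_de_lncrna = assert_count(n_de_lncrna, "n_de_lncrna"),
    effect_size = assert_scalar_number(effect_size, "effect_size", lower = 0),
    noise_sd = assert_scalar_number(noise_sd, "noise_sd", lower = 0),
    baseline_mean = assert_scalar_number(baseline_mean, "baseline_mean"),
    n_mirnas = assert_count(n_mirnas, "n_mirnas", 1),
    n_hub_lncrnas = assert_count(n_hub_lncrnas, "n_hub_lncrnas"),
    hub_degree = assert_count(hub_degree, "hub_degree", 1),
    bg_interaction_prob = assert_scalar_number(bg_interaction_prob,
                                               "bg_interaction_prob", 0, 1),
    db_overlap_frac = assert_scalar_number(db_overlap_frac, "db_overlap_frac", 0, 1),
    n_gene_sets = assert_count(n_gene_sets, "n_gene_sets"),
    set_size_range = set_size_range,
    n_enriched_sets = assert_count(n_enriched_sets, "n_enriched_sets"),
    paired = isTRUE(paired),
    seed = assert_count(seed, "seed")
  )
  if (!length(probes_per_gene) %in% 1:2 || any(probes_per_gene < 1) ||
      any(probes_per_gene != round(probes_per_gene))) {
    stop_cernet("`probes_per_gene` must be a positive count or a length-2 range")
  }
  if (length(set_size_range) != 2L || set_size_range[1] > set_size_range[2] ||
      set_size_range[1] < 1) {
    stop_cernet("`set_size_range` must be an increasing pair of positive counts")
  }
  n_lnc <- round(cfg$n_genes * cfg$frac_lncrna)
  n_mrna <- cfg$n_genes - n_lnc
  if (n_lnc < 1 || n_mrna < 1) stop_cernet("`frac_lncrna` leaves a biotype empty")
  if (cfg$n_de_mrna > n_mrna) {
    stop_cernet(sprintf("n_de_mrna (%d) exceeds the mRNA count (%d)", cfg$n_de_mrna, n_mrna))
  }
  if (cfg$n_de_lncrna > n_lnc) {
    stop_cernet(sprintf("n_de_lncrna (%d) exceeds the lncRNA count (%d)",
                        cfg$n_de_lncrna, n_lnc))
  }
  if (cfg$n_hub_lncrnas > cfg$n_de_lncrna) {
    stop_cernet(sprintf("n_hub_lncrnas (%d) exceeds n_de_lncrna (%d)",
                        cfg$n_hub_lncrnas, cfg$n_de_lncrna))
  }
  if (cfg$n_hub_lncrnas > 0 && cfg$n_de_mrna < 1) {
    stop_cernet("planted hubs need at least one planted DE mRNA to target")
  }
  if (cfg$n_enriched_sets > cfg$n_gene_sets) {
    stop_cernet("n_enriched_sets exceeds n_gene_sets")
  }
  cfg$n_mrna <- n_mrna
  cfg$n_lncrna <- n_lnc
  structure(cfg, class = "synth_config")
}

synth_gene_table <- function(config) {
  tibble(
    gene = c(sprintf("MRNA%04d", seq_len(config$n_mrna)),
             sprintf("LNC%04d", seq_len(config$n_lncrna))),
    biotype = rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  )
}

#' Generate a probe-level expression dataset with planted DE genes
#'
#' Non-DE genes have the same mean (`baseline_mean`) in both groups; each
#' planted DE gene's day8 mean is shifted by plus or minus `effect_size`
#' log2-units (direction random). Probes of a gene share the gene's mean,
#' and every probe-sample measurement receives independent Gaussian noise
#' of `noise_sd` log2-units. The returned matrix is on the linear intensity
#' scale (`2^log2value`), as an array-summarization step would deliver it,
#' so the full preprocessing path (filter, log2, normalize, collapse) can
#' be exercised.
#'
#' @param config A [synth_config()].
#' @return A list: `expr` (a probe-level, linear-scale [expr_matrix]),
#'   `annot` (probe annotation tibble), and `truth` (a `cerna_ground_truth`
#'   list recording the planted DE genes and hub lncRNAs).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(config$seed, {
    genes <- synth_gene_table(config)

    ppg <- config$probes_per_gene
    n_probes_per_gene <- if (length(ppg) == 2L) {
      sample(ppg[1]:ppg[2], nrow(genes), replace = TRUE)
    } else {
      rep(as.integer(ppg), nrow(genes))
    }
    annot <- tibble(
      probe_id = sprintf("P%06d", seq_len(sum(n_probes_per_gene))),
      gene_symbol = rep(genes$gene, n_probes_per_gene),
      biotype = rep(genes$biotype, n_probes_per_gene)
    )
    chr <- sample(c(1:22, "X"), nrow(genes), replace = TRUE)
    band <- sprintf("%s%s%d%d", chr, sample(c("p", "q"), nrow(genes), TRUE),
                    sample(1:3, nrow(genes), TRUE), sample(1:9, nrow(genes), TRUE))
    start <- sample.int(2e8, nrow(genes))
    annot$chromosome_band <- rep(band, n_probes_per_gene)
    annot$start <- rep(start, n_probes_per_gene)
    annot$end <- annot$start + rep(sample(500:200000, nrow(genes), TRUE),
                                   n_probes_per_gene)

    de_mrna <- sample(genes$gene[genes$biotype == "mRNA"], config$n_de_mrna)
    de_lnc <- sample(genes$gene[genes$biotype == "lncRNA"], config$n_de_lncrna)
    de_all <- c(de_mrna, de_lnc)
    direction <- sample(c("up", "down"), length(de_all), replace = TRUE)
    truth_de <- tibble(
      gene = de_all,
      biotype = rep(c("mRNA", "lncRNA"), c(config$n_de_mrna, config$n_de_lncrna)),
      direction = direction,
      true_logfc = ifelse(direction == "up", 1, -1) * config$effect_size
    )
    hubs <- if (config$n_hub_lncrnas > 0) {
      sample(de_lnc, config$n_hub_lncrnas)
    } else {
      character()
    }

    n <- config$n_samples_per_group
    samples <- c(sprintf("D0_S%03d", seq_len(n)), sprintf("D8_S%03d", seq_len(n)))
    groups <- setNames(rep(c("day0", "day8"), each = n), samples)

    shift <- setNames(rep(0, nrow(genes)), genes$gene)
    shift[truth_de$gene] <- truth_de$true_logfc
    gene_mean_d0 <- setNames(rep(config$baseline_mean, nrow(genes)), genes$gene)
    probe_mean_d0 <- gene_mean_d0[annot$gene_symbol]
    probe_shift <- shift[annot$gene_symbol]

    n_probes <- nrow(annot)
    log2_vals <- matrix(rnorm(n_probes * 2 * n, sd = config$noise_sd),
                        nrow = n_probes)
    log2_vals <- log2_vals + probe_mean_d0 +
      outer(probe_shift, c(rep(0, n), rep(1, n)))
    if (config$paired) {
      # shared per-patient offset links sample i of day0 with sample i of day8
      patient <- matrix(rnorm(n_probes * n, sd = config$noise_sd / 2), nrow = n_probes)
      log2_vals <- log2_vals + cbind(patient, patient)
    }
    dimnames(log2_vals) <- list(annot$probe_id, samples)

    expr <- expr_matrix(
      dplyr::bind_cols(tibble(feature_id = annot$probe_id),
                       as_tibble(2^log2_vals, .name_repair = "minimal")),
      groups = groups, scale = "linear", level = "probe"
    )
    truth <- structure(
      list(de_genes = truth_de, hub_lncrnas = hubs,
           enriched_sets = character(), interactions = NULL),
      class = "cerna_ground_truth"
    )
    list(expr = expr, annot = annot, truth = truth)
  })
}

#' Generate lncRNA-miRNA and dual-database miRNA-mRNA interaction tables
#'
#' Each planted hub lncRNA is paired with exactly `hub_degree` distinct
#' miRNAs; each of those miRNAs targets at least one planted DE mRNA, and
#' the hub-supporting miRNA-mRNA pairs are written to **both** target
#' databases so hubs survive the validated-by-both rule by construction.
#' Every remaining regulator-target pair is included independently with
#' probability `bg_interaction_prob`; a background miRNA-mRNA pair lands in
#' both databases with probability `db_overlap_frac`, otherwise in exactly
#' one. Tables contain no duplicate rows.
#'
#' @param config A [synth_config()].
#' @param truth Ground truth from [generate_expression_dataset()].
#' @param annot Probe annotation from the same call.
#' @return A list: `lnc_mi`, `mi_m_db1`, `mi_m_db2` (interaction tables)
#'   and `truth` updated with the generated pair sets.
#' @export
generate_interaction_tables <- function(config, truth, annot) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_mirnas < config$hub_degree) {
    stop_cernet(sprintf("n_mirnas (%d) is smaller than hub_degree (%d)",
                        config$n_mirnas, config$hub_degree))
  }
  with_rng(config$seed + 1L, {
    genes <- distinct(annot, gene = .data$gene_symbol, .data$biotype)
    lncs <- genes$gene[genes$biotype == "lncRNA"]
    mrnas <- genes$gene[genes$biotype == "mRNA"]
    mirnas <- sprintf("MIR%04d", seq_len(config$n_mirnas))
    de_mrna <- truth$de_genes$gene[truth$de_genes$biotype == "mRNA"]

    planted_lm <- planted_mm <- tibble(regulator = character(), target = character())
    for (hub in truth$hub_lncrnas) {
      partners <- sample(mirnas, config$hub_degree)
      planted_lm <- bind_rows(planted_lm, tibble(regulator = hub, target = partners))
      for (mi in partners) {
        tg <- sample(de_mrna, min(3L, length(de_mrna)))
        planted_mm <- bind_rows(planted_mm, tibble(regulator = mi, target = tg))
      }
    }
    planted_mm <- distinct(planted_mm)

    bg_pairs <- function(regs, targs, exclude) {
      all_pairs <- tidyr::expand_grid(regulator = regs, target = targs)
      all_pairs <- dplyr::anti_join(all_pairs, exclude, by = c("regulator", "target"))
      all_pairs[runif(nrow(all_pairs)) < config$bg_interaction_prob, , drop = FALSE]
    }
    # hubs get no background partners: their degree is exactly hub_degree
    bg_lm <- bg_pairs(setdiff(lncs, truth$hub_lncrnas), mirnas, planted_lm)
    bg_mm <- bg_pairs(mirnas, mrnas, planted_mm)

    in_both <- runif(nrow(bg_mm)) < config$db_overlap_frac
    to_db1 <- runif(nrow(bg_mm)) < 0.5
    db1_bg <- bg_mm[in_both | to_db1, , drop = FALSE]
    db2_bg <- bg_mm[in_both | !to_db1, , drop = FALSE]

    lm_all <- bind_rows(planted_lm, bg_lm)
    db1 <- bind_rows(planted_mm, db1_bg)
    db2 <- bind_rows(planted_mm, db2_bg)

    lnc_mi <- interaction_table(lm_all$regulator, lm_all$target,
                                "lncRNA-miRNA", "mircode_sim")
    mi_m_db1 <- interaction_table(db1$regulator, db1$target,
                                  "miRNA-mRNA", "targetscan_sim")
    mi_m_db2 <- interaction_table(db2$regulator, db2$target,
                                  "miRNA-mRNA", "mirtarbase_sim")
    truth$interactions <- list(
      lnc_mi = as_tibble(lnc_mi)[c("regulator", "target")],
      mi_m = distinct(bind_rows(as_tibble(mi_m_db1), as_tibble(mi_m_db2))[
        c("regulator", "target")
      ])
    )
    list(lnc_mi = lnc_mi, mi_m_db1 = mi_m_db1, mi_m_db2 = mi_m_db2, truth = truth)
  })
}

#' Generate a gene-set library with planted enriched sets
#'
#' Builds `n_gene_sets` sets over the mRNA universe. The first
#' `n_enriched_sets` are planted: at least 70\% of each planted set's
#' members are drawn from the planted DE mRNAs, the remainder uniformly
#' from the rest of the universe. All other sets are drawn uniformly.
#'
#' @param config A [synth_config()].
#' @param truth Ground truth from [generate_expression_dataset()].
#' @param annot Probe annotation from the same call.
#' @return A list: `library` (a `gene_set_library`) and `truth` updated
#'   with the planted set names.
#' @export
generate_gene_set_library <- function(config, truth, annot) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(config$seed + 2L, {
    universe <- unique(annot$gene_symbol[annot$biotype == "mRNA"])
    if (max(config$set_size_range) > length(universe)) {
      stop_cernet("set_size_range maximum exceeds the mRNA universe size")
    }
    de_mrna <- truth$de_genes$gene[truth$de_genes$biotype == "mRNA"]
    sizes <- sample(config$set_size_range[1]:config$set_size_range[2],
                    config$n_gene_sets, replace = TRUE)
    sets <- vector("list", config$n_gene_sets)
    names(sets) <- sprintf("GS%03d", seq_len(config$n_gene_sets))
    enriched <- names(sets)[seq_len(config$n_enriched_sets)]
    for (i in seq_len(config$n_gene_sets)) {
      if (i <= config$n_enriched_sets) {
        n_planted <- ceiling(0.7 * sizes[i])
        if (n_planted > length(de_mrna)) {
          stop_cernet("not enough planted DE mRNAs to build an enriched set")
        }
        core <- sample(de_mrna, n_planted)
        rest <- sample(setdiff(universe, core), sizes[i] - n_planted)
        members <- sample(c(core, rest))
        desc <- "synthetic planted-enriched set"
      } else {
        members <- sample(universe, sizes[i])
        desc <- "synthetic background set"
      }
      sets[[i]] <- list(description = desc, members = members)
    }
    truth$enriched_sets <- enriched
    list(library = structure(sets, class = "gene_set_library"), truth = truth)
  })
}

#' Generate an RT-qPCR Ct table with planted fold changes
#'
#' Emulates a validation experiment: a control cohort and several case
#' cohorts, a reference gene of roughly constant Ct, and target genes whose
#' Ct in case samples is shifted by `-log2(fold change)` so that the
#' 2^-deltaCt method recovers the planted fold change. Replicate Ct values
#' get independent Gaussian noise.
#'
#' @param config A [synth_config()].
#' @param truth Ground truth from [generate_expression_dataset()]; planted
#'   fold changes default to `2^true_logfc` of the hub lncRNAs.
#' @param genes Target genes (default: the planted hub lncRNAs).
#' @param fold_changes Named vector of case/control fold changes per target
#'   gene (default: from `truth`; genes without a plant get 1).
#' @param group_sizes Named integer vector of samples per group; the first
#'   name is the control group. Default mirrors a typical validation
#'   cohort: 15 controls and 9 + 17 + 7 cases across three ALL subtypes.
#' @param n_replicates Technical replicates per (sample, gene).
#' @param ct_noise_sd Replicate noise, cycles.
#' @param reference_gene Internal control gene name.
#' @param ref_ct,target_ct Baseline cycles for reference and target genes.
#' @return A Ct tibble (`sample`, `group`, `gene`, `replicate`, `ct`).
#' @export
generate_ct_table <- function(config, truth,
                              genes = NULL,
                              fold_changes = NULL,
                              group_sizes = c(control = 15, ph_pos = 9,
                                              ph_neg = 17, t_all = 7),
                              n_replicates = 3,
                              ct_noise_sd = 0.25,
                              reference_gene = "GAPDH",
                              ref_ct = 20,
                              target_ct = 25) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(genes)) {
    genes <- if (length(truth$hub_lncrnas)) {
      truth$hub_lncrnas
    } else {
      head(truth$de_genes$gene, 3L)
    }
  }
  if (length(genes) == 0L) stop_cernet("no target genes for the Ct table")
  if (is.null(fold_changes)) {
    fc <- setNames(rep(1, length(genes)), genes)
    hit <- intersect(genes, truth$de_genes$gene)
    fc[hit] <- 2^truth$de_genes$true_logfc[match(hit, truth$de_genes$gene)]
    fold_changes <- fc
  }
  if (is.null(names(group_sizes)) || length(group_sizes) < 2L) {
    stop_cernet("group_sizes must be a named vector with >= 2 groups")
  }
  control <- names(group_sizes)[1L]
  with_rng(config$seed + 3L, {
    samples <- tibble(
      sample = unlist(lapply(names(group_sizes), function(g) {
        sprintf("%s_%02d", g, seq_len(group_sizes[[g]]))
      })),
      group = rep(names(group_sizes), group_sizes)
    )
    grid <- tidyr::expand_grid(
      samples,
      gene = c(reference_gene, genes),
      replicate = seq_len(n_replicates)
    )
    base <- ifelse(grid$gene == reference_gene, ref_ct, target_ct)
    shift <- ifelse(
      grid$gene == reference_gene | grid$group == control,
      0,
      -log2(fold_changes[grid$gene])
    )
    grid$ct <- base + shift + rnorm(nrow(grid), sd = ct_noise_sd)
    validate_ct_table(grid)
  })
}

#' Generate and write every pipeline input for a synthetic study
#'
#' Runs all four generators and serializes their outputs: the probe-level
#' expression matrix and sample-group map, the probe annotation, the
#' lncRNA-miRNA table, the two miRNA-mRNA tables, the GMT gene-set library,
#' the Ct table, and the ground truth as JSON.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and a `paths`
#'   element naming every file written.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- generate_expression_dataset(config)
  it <- generate_interaction_tables(config, ds$truth, ds$annot)
  gs <- generate_gene_set_library(config, it$truth, ds$annot)
  ct <- generate_ct_table(config, gs$truth)
  truth <- gs$truth

  p <- function(f) file.path(dir, f)
  paths <- list(
    expression = p("expression.tsv"),
    groups = p("sample_groups.tsv"),
    annotation = p("probe_annotation.tsv"),
    lnc_mi = p("lncrna_mirna.tsv"),
    mi_m_db1 = p("mirna_mrna_db1.tsv"),
    mi_m_db2 = p("mirna_mrna_db2.tsv"),
    gene_sets = p("gene_sets.gmt"),
    ct = p("ct_table.tsv"),
    truth = p("ground_truth.json")
  )
  write_expression_matrix(ds$expr, paths$expression)
  readr::write_tsv(
    tibble(sample = names(expr_groups(ds$expr)), group = unname(expr_groups(ds$expr))),
    paths$groups, progress = FALSE
  )
  readr::write_tsv(ds$annot, paths$annotation, progress = FALSE)
  write_interaction_table(it$lnc_mi, paths$lnc_mi)
  write_interaction_table(it$mi_m_db1, paths$mi_m_db1)
  write_interaction_table(it$mi_m_db2, paths$mi_m_db2)
  write_gmt(gs$library, paths$gene_sets)
  readr::write_tsv(ct, paths$ct, progress = FALSE)
  jsonlite::write_json(
    list(
      de_genes = truth$de_genes,
      hub_lncrnas = truth$hub_lncrnas,
      enriched_sets = truth$enriched_sets,
      interactions = truth$interactions
    ),
    paths$truth, dataframe = "columns", auto_unbox = FALSE, digits = NA
  )
  invisible(list(
    config = config, expr = ds$expr, annot = ds$annot, truth = truth,
    lnc_mi = it$lnc_mi, mi_m_db1 = it$mi_m_db1, mi_m_db2 = it$mi_m_db2,
    library = gs$library, ct = ct, paths = paths
  ))
}
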