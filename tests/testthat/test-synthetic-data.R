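test_that("identical configurations produce identical outputs from every generator", {
  cfg <- tiny_config(seed = 11)
  a <- generate_expression_dataset(cfg)
  b <- generate_expression_dataset(cfg)
  expect_identical(tibble::as_tibble(a$expr), tibble::as_tibble(b$expr))
  expect_identical(a$annot, b$annot)
  expect_identical(a$truth, b$truth)

  ia <- generate_interaction_tables(cfg, a$truth, a$annot)
  ib <- generate_interaction_tables(cfg, b$truth, b$annot)
  expect_identical(tibble::as_tibble(ia$lnc_mi), tibble::as_tibble(ib$lnc_mi))
  expect_identical(tibble::as_tibble(ia$mi_m_db1), tibble::as_tibble(ib$mi_m_db1))

  ga <- generate_gene_set_library(cfg, ia$truth, a$annot)
  gb <- generate_gene_set_library(cfg, ib$truth, b$annot)
  expect_identical(unclass(ga$library), unclass(gb$library))

  expect_identical(generate_ct_table(cfg, ga$truth), generate_ct_table(cfg, gb$truth))
})

test_that("planted differential expression has the configured mean shift", {
  cfg <- tiny_config(seed = 3, effect_size = 2, noise_sd = 0.3,
                     n_samples_per_group = 15)
  ds <- generate_expression_dataset(cfg)
  vals <- log2(expr_values(ds$expr))
  grp <- expr_groups(ds$expr)
  diff <- rowMeans(vals[, grp == "day8"]) - rowMeans(vals[, grp == "day0"])
  # probes_per_gene = 1, so probe ids map 1:1 to genes
  gene_of <- setNames(ds$annot$gene_symbol, ds$annot$probe_id)
  planted <- ds$truth$de_genes
  obs <- diff[match(planted$gene, gene_of[names(diff)])]
  se <- cfg$noise_sd * sqrt(2 / cfg$n_samples_per_group)
  expect_true(all(abs(obs - planted$true_logfc) < 5 * se))
  # non-planted genes sit near zero
  null_diff <- diff[!gene_of[names(diff)] %in% planted$gene]
  expect_lt(max(abs(null_diff)), 5 * se)
})

test_that("a configuration with no planted effects yields an empty ground truth", {
  cfg <- tiny_config(seed = 5, n_de_mrna = 0, n_de_lncrna = 0, n_hub_lncrnas = 0)
  ds <- generate_expression_dataset(cfg)
  expect_equal(nrow(ds$truth$de_genes), 0)
  expect_length(ds$truth$hub_lncrnas, 0)
  vals <- log2(expr_values(ds$expr))
  grp <- expr_groups(ds$expr)
  diff <- rowMeans(vals[, grp == "day8"]) - rowMeans(vals[, grp == "day0"])
  expect_lt(mean(abs(diff)), 3 * cfg$noise_sd * sqrt(2 / cfg$n_samples_per_group))
})

test_that("invalid configurations are rejected with the violated bound named", {
  expect_error(tiny_config(n_de_mrna = 1000), "n_de_mrna")
  expect_error(tiny_config(n_hub_lncrnas = 10, n_de_lncrna = 4), "n_hub_lncrnas")
  expect_error(tiny_config(frac_lncrna = 1.2), "frac_lncrna")
  expect_error(tiny_config(bg_interaction_prob = -0.1), "bg_interaction_prob")
  expect_error(tiny_config(set_size_range = c(20, 10)), "set_size_range")
})

test_that("each planted hub lncRNA sponges exactly hub_degree distinct miRNAs", {
  cfg <- tiny_config(seed = 9, n_hub_lncrnas = 2, hub_degree = 5)
  ds <- generate_expression_dataset(cfg)
  it <- generate_interaction_tables(cfg, ds$truth, ds$annot)
  lm <- tibble::as_tibble(it$lnc_mi)
  for (hub in ds$truth$hub_lncrnas) {
    partners <- lm$target[lm$regulator == hub]
    expect_length(unique(partners), 5)
    expect_equal(anyDuplicated(partners), 0)
  }
  # hub-supporting miRNAs target planted DE mRNAs in BOTH databases
  de_mrna <- ds$truth$de_genes$gene[ds$truth$de_genes$biotype == "mRNA"]
  both <- intersect_databases(it$mi_m_db1, it$mi_m_db2)
  for (hub in ds$truth$hub_lncrnas) {
    for (mi in lm$target[lm$regulator == hub]) {
      hits <- both$target[both$regulator == mi]
      expect_gt(length(intersect(hits, de_mrna)), 0)
    }
  }
  expect_error(
    generate_interaction_tables(tiny_config(hub_degree = 31), ds$truth, ds$annot),
    "n_mirnas"
  )
})

test_that("database overlap fraction boundaries behave as set operations", {
  base <- tiny_config(seed = 21, bg_interaction_prob = 0, db_overlap_frac = 0)
  ds <- generate_expression_dataset(base)
  it0 <- generate_interaction_tables(base, ds$truth, ds$annot)
  pairs <- function(x) paste(x$regulator, x$target)
  # no background and overlap 0: only planted pairs, present in both by design
  expect_setequal(pairs(it0$mi_m_db1), pairs(it0$mi_m_db2))
  both0 <- intersect_databases(it0$mi_m_db1, it0$mi_m_db2)
  expect_setequal(pairs(both0), unique(pairs(it0$mi_m_db1)))

  full <- tiny_config(seed = 21, bg_interaction_prob = 0.05, db_overlap_frac = 1)
  ds1 <- generate_expression_dataset(full)
  it1 <- generate_interaction_tables(full, ds1$truth, ds1$annot)
  expect_setequal(pairs(it1$mi_m_db1), pairs(it1$mi_m_db2))

  # no duplicated rows in any generated table
  for (tb in list(it1$lnc_mi, it1$mi_m_db1, it1$mi_m_db2)) {
    expect_equal(anyDuplicated(tibble::as_tibble(tb)[c("regulator", "target")]), 0)
  }
})

test_that("planted enriched sets overlap the DE mRNAs by at least 70 percent", {
  cfg <- tiny_config(seed = 13)
  ds <- generate_expression_dataset(cfg)
  it <- generate_interaction_tables(cfg, ds$truth, ds$annot)
  gs <- generate_gene_set_library(cfg, it$truth, ds$annot)
  de_mrna <- ds$truth$de_genes$gene[ds$truth$de_genes$biotype == "mRNA"]
  expect_length(gs$truth$enriched_sets, cfg$n_enriched_sets)
  for (nm in gs$truth$enriched_sets) {
    members <- gs$library[[nm]]$members
    expect_gte(length(intersect(members, de_mrna)), ceiling(0.7 * length(members)) - 1)
  }
  expect_error(
    generate_gene_set_library(tiny_config(set_size_range = c(10, 10000)),
                              ds$truth, ds$annot),
    "universe"
  )
})

test_that("the gene-set library round-trips through the GMT format", {
  cfg <- tiny_config(seed = 17)
  ds <- generate_expression_dataset(cfg)
  gs <- generate_gene_set_library(cfg, ds$truth, ds$annot)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs$library, path)
  back <- read_gmt(path)
  expect_identical(unclass(back), unclass(gs$library))
})

test_that("the Ct table encodes planted fold changes on the cycle scale", {
  cfg <- tiny_config(seed = 19)
  ds <- generate_expression_dataset(cfg)
  hub <- ds$truth$hub_lncrnas[1]
  # noiseless table: a 4-fold plant shifts case Ct by exactly -2 cycles
  ct <- generate_ct_table(cfg, ds$truth, genes = hub,
                          fold_changes = setNames(4, hub),
                          group_sizes = c(control = 4, case = 4),
                          ct_noise_sd = 0)
  mean_ct <- tapply(ct$ct[ct$gene == hub], ct$group[ct$gene == hub], mean)
  expect_equal(unname(mean_ct["case"] - mean_ct["control"]), -2)
  # replicates are identical when replicate noise is zero
  one <- ct[ct$sample == ct$sample[1] & ct$gene == hub, ]
  expect_equal(length(unique(one$ct)), 1)
  # fold change 1 leaves group means equal up to noise
  ct1 <- generate_ct_table(cfg, ds$truth, genes = hub,
                           fold_changes = setNames(1, hub),
                           group_sizes = c(control = 10, case = 10),
                           ct_noise_sd = 0.2)
  m1 <- tapply(ct1$ct[ct1$gene == hub], ct1$group[ct1$gene == hub], mean)
  expect_lt(abs(m1["case"] - m1["control"]), 0.5)
})
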