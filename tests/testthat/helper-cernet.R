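# Fixture builders and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick expr_matrix from a plain matrix (columns auto-named, two groups)
make_expr <- function(values, groups = NULL, scale = "log2", level = "gene",
                      features = NULL) {
  n <- ncol(values)
  samples <- colnames(values) %||% sprintf("s%02d", seq_len(n))
  features <- features %||% rownames(values) %||% sprintf("g%04d", seq_len(nrow(values)))
  if (is.null(groups)) {
    groups <- setNames(rep(c("day0", "day8"), length.out = n), samples)
  }
  tb <- tibble::as_tibble(values, .name_repair = "minimal")
  names(tb) <- samples
  tb <- dplyr::bind_cols(tibble::tibble(feature_id = features), tb)
  expr_matrix(tb, groups, scale = scale, level = level)
}

# small, fast synthetic study used by most generator-driven tests
tiny_config <- function(...) {
  defaults <- list(
    n_genes = 200, frac_lncrna = 0.15, probes_per_gene = 1,
    n_samples_per_group = 6, n_de_mrna = 20, n_de_lncrna = 6,
    n_mirnas = 30, n_hub_lncrnas = 3, hub_degree = 5,
    bg_interaction_prob = 0.01, db_overlap_frac = 0.5,
    n_gene_sets = 15, set_size_range = c(10, 20), n_enriched_sets = 2
  )
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# gene-level DE table from a generated dataset (exact log2 inversion of the
# linear-scale matrix, then probe collapse)
de_from_dataset <- function(ds, paired = FALSE) {
  suppressMessages({
    genes <- ds$expr |>
      log2_transform(offset = 0) |>
      collapse_probes(ds$annot)
  })
  differential_expression(genes, paired = paired)
}

# random tripartite instance built through the full interaction route,
# restricted by the generator's planted truth
random_network <- function(seed) {
  cfg <- tiny_config(seed = seed, n_genes = 120, n_de_mrna = 15, n_de_lncrna = 5,
                     n_mirnas = 15, n_hub_lncrnas = 2, hub_degree = 4,
                     bg_interaction_prob = 0.05)
  ds <- generate_expression_dataset(cfg)
  it <- generate_interaction_tables(cfg, ds$truth, ds$annot)
  de <- ds$truth$de_genes
  lnc_mi <- restrict_to_de(it$lnc_mi, de$gene[de$biotype == "lncRNA"], "regulator")
  mi_m <- intersect_databases(it$mi_m_db1, it$mi_m_db2) |>
    restrict_to_de(de$gene[de$biotype == "mRNA"], "target")
  list(net = build_cerna_network(lnc_mi, mi_m), lnc_mi = lnc_mi, mi_m = mi_m,
       truth = ds$truth)
}

# --- independent statistical oracles --------------------------------------

# brute-force BH: q_i = min over tails of sorted p * m / rank, clipped at 1
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# exact hypergeometric upper tail by binomial-coefficient enumeration
hyper_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# textbook one-way ANOVA from sums of squares
anova_oracle <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# random p-value vectors with a realistic mixture of nulls and signals
random_p_vector <- function(n) {
  mix <- stats::runif(n)
  ifelse(stats::runif(n) < 0.2, mix^4, mix)
}
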