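#' Read an RT-qPCR Ct table
#'
#' Expects a TSV with columns `sample`, `group`, `gene`, `replicate`, `ct`
#' (threshold cycles).
#'
#' @param path Ct TSV path.
#' @return A validated tibble.
#' @export
read_ct_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "group", "gene", "replicate", "ct")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop_cernet(paste0("Ct table is missing columns: ", paste(missing, collapse = ", ")))
  }
  validate_ct_table(tb)
}

validate_ct_table <- function(tb) {
  if (!is.numeric(tb$ct) || anyNA(tb$ct) || any(!is.finite(tb$ct)) || any(tb$ct <= 0)) {
    stop_cernet("Ct values must be finite and positive")
  }
  as_tibble(tb)
}

#' Relative expression by the 2^-deltaCt method
#'
#' Technical replicates are averaged on the Ct scale first; then for each
#' (sample, gene), `deltaCt = meanCt(gene) - meanCt(reference)` and
#' `rel_expr = 2^-deltaCt`, i.e. expression relative to the internal
#' control (typically GAPDH). The reference gene's own relative expression
#' is 1 by construction, and adding a constant to every Ct of a sample
#' (a global efficiency shift) leaves every `rel_expr` unchanged.
#'
#' @param ct A Ct tibble with columns `sample`, `group`, `gene`,
#'   `replicate`, `ct`.
#' @param reference_gene Internal control gene measured in every sample
#'   (default `"GAPDH"`).
#' @return A tibble of class `cerna_relexpr`: one row per (sample, gene)
#'   with `group`, `mean_ct`, `delta_ct`, `rel_expr`.
#' @export
relative_expression <- function(ct, reference_gene = "GAPDH") {
  ct <- validate_ct_table(ct)
  means <- ct |>
    group_by(.data$sample, .data$group, .data$gene) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  ref <- means |>
    filter(.data$gene == reference_gene) |>
    select("sample", ref_ct = "mean_ct")
  missing_ref <- setdiff(unique(means$sample), ref$sample)
  if (length(missing_ref)) {
    stop_cernet(paste0(
      "samples missing the reference gene '", reference_gene, "': ",
      paste(missing_ref, collapse = ", ")
    ))
  }
  out <- means |>
    left_join(ref, by = "sample") |>
    mutate(
      delta_ct = .data$mean_ct - .data$ref_ct,
      rel_expr = 2^(-.data$delta_ct)
    ) |>
    select("sample", "group", "gene", "mean_ct", "delta_ct", "rel_expr")
  structure(out,
    reference_gene = reference_gene,
    class = c("cerna_relexpr", class(out))
  )
}

#' Compare relative expression of one gene between groups
#'
#' Two groups are compared with Welch's t-test; three or more with one-way
#' ANOVA. The test that ran is recorded in the output. Relative expression
#' can optionally be compared on the log2 scale.
#'
#' @param rel A `cerna_relexpr` table from [relative_expression()].
#' @param gene Gene to test.
#' @param groups Group labels to include (default: all groups present).
#' @param log_scale Compare `log2(rel_expr)` instead of `rel_expr`.
#' @return A one-row tibble: `gene`, `test` (`"welch_t"` or `"anova"`),
#'   `statistic`, `p`, `n_groups`.
#' @export
compare_groups <- function(rel, gene, groups = NULL, log_scale = FALSE) {
  df <- as_tibble(rel) |> filter(.data$gene == !!gene)
  if (nrow(df) == 0L) stop_cernet(sprintf("gene '%s' not present", gene))
  if (!is.null(groups)) df <- df |> filter(.data$group %in% groups)
  sizes <- table(df$group)
  if (length(sizes) < 2L) stop_cernet("need at least 2 groups")
  if (any(sizes < 2L)) {
    stop_cernet(paste0("groups with fewer than 2 samples: ",
                       paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  y <- if (log_scale) log2(df$rel_expr) else df$rel_expr
  g <- factor(df$group)
  if (stats::var(y) == 0) {
    # constant response: no evidence of a difference
    return(tibble(gene = gene, test = if (nlevels(g) == 2L) "welch_t" else "anova",
                  statistic = 0, p = 1, n_groups = nlevels(g)))
  }
  if (nlevels(g) == 2L) {
    ht <- t.test(y ~ g)
    tibble(gene = gene, test = "welch_t",
           statistic = unname(ht$statistic), p = ht$p.value, n_groups = 2L)
  } else {
    fit <- aov(y ~ g)
    s <- summary(fit)[[1L]]
    tibble(gene = gene, test = "anova",
           statistic = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
           n_groups = nlevels(g))
  }
}

#' Per-gene group comparison table
#'
#' Runs [compare_groups()] for every non-reference gene, reports per-group
#' mean relative expression and the fold difference between the extreme
#' group means, and adjusts p-values across genes with Benjamini-Hochberg.
#'
#' @param rel A `cerna_relexpr` table.
#' @param groups Group labels to include (default: all).
#' @param log_scale Passed to [compare_groups()].
#' @return A tibble with one row per gene.
#' @export
qpcr_summary <- function(rel, groups = NULL, log_scale = FALSE) {
  ref <- attr(rel, "reference_gene")
  genes <- setdiff(unique(rel$gene), ref)
  stats_tbl <- bind_rows(lapply(genes, function(g) {
    compare_groups(rel, g, groups = groups, log_scale = log_scale)
  }))
  df <- as_tibble(rel)
  if (!is.null(groups)) df <- df |> filter(.data$group %in% groups)
  gm <- df |>
    filter(.data$gene %in% genes) |>
    group_by(.data$gene, .data$group) |>
    summarise(mean_rel = mean(.data$rel_expr), .groups = "drop") |>
    group_by(.data$gene) |>
    summarise(
      group_means = paste(sprintf("%s=%.4g", .data$group, .data$mean_rel), collapse = ";"),
      fold_range = max(.data$mean_rel) / min(.data$mean_rel),
      .groups = "drop"
    )
  out <- left_join(stats_tbl, gm, by = "gene")
  out$q <- adjust_bh(out$p)
  out
}

#' Box plot of relative expression by group
#'
#' @param object A `cerna_relexpr` table.
#' @param genes Genes to show (default: all non-reference genes).
#' @param ... Unused.
#' @return A ggplot object, one facet per gene.
#' @export
autoplot.cerna_relexpr <- function(object, genes = NULL, ...) {
  ref <- attr(object, "reference_gene")
  df <- as_tibble(object) |> filter(.data$gene != ref)
  if (!is.null(genes)) df <- df |> filter(.data$gene %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$rel_expr, fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = expression(2^{-Delta * Ct}), fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
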