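#' Two-group differential expression
#'
#' Per-gene two-sample comparison on a log2-scale, gene-level matrix. The
#' log2 fold change is `mean(group_b) - mean(group_a)`. Unpaired mode uses
#' Welch's t-statistic with Welch-Satterthwaite degrees of freedom; paired
#' mode uses the one-sample t-test on within-pair differences, pairing the
#' i-th sample of each group by column order. Genes with zero variance in
#' both groups carry no evidence and are assigned `p = 1`.
#'
#' The statistics are computed with vectorized matrix formulas, so a matrix
#' with tens of thousands of genes tests in milliseconds.
#'
#' @param x A gene-level, log2-scale [expr_matrix].
#' @param group_a,group_b Group labels; `group_a` is the baseline (e.g.
#'   diagnosis, day 0) and `group_b` the comparison (e.g. day 8).
#' @param paired Use the paired t-test (requires equal group sizes).
#' @return A tibble of class `cerna_de` with columns `gene`, `logFC`, `t`,
#'   `df`, `p`, `q` (Benjamini-Hochberg), `direction` (`up` iff
#'   `logFC > 0`) and `passed` (all `NA` until [apply_thresholds()]).
#' @seealso [apply_thresholds()], [adjust_bh()]
#' @export
differential_expression <- function(x, group_a = "day0", group_b = "day8",
                                    paired = FALSE) {
  if (expr_scale(x) != "log2") stop_cernet("differential_expression needs log2-scale data")
  if (expr_level(x) != "gene") stop_cernet("differential_expression needs gene-level data")
  grp <- expr_groups(x)
  a_cols <- names(grp)[grp == group_a]
  b_cols <- names(grp)[grp == group_b]
  if (length(a_cols) < 2L || length(b_cols) < 2L) {
    stop_cernet("both groups need at least 2 samples")
  }
  vals <- expr_values(x)
  A <- vals[, a_cols, drop = FALSE]
  B <- vals[, b_cols, drop = FALSE]

  if (paired) {
    if (length(a_cols) != length(b_cols)) {
      stop_cernet("paired mode requires equal group sizes")
    }
    D <- B - A
    n <- ncol(D)
    md <- rowMeans(D)
    sdd <- sqrt(.row_vars(D))
    se <- sdd / sqrt(n)
    lfc <- md
    df <- rep(n - 1, nrow(D))
  } else {
    na <- ncol(A)
    nb <- ncol(B)
    va <- .row_vars(A) / na
    vb <- .row_vars(B) / nb
    se <- sqrt(va + vb)
    lfc <- rowMeans(B) - rowMeans(A)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }

  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pt(-abs(tstat), df), 1)
  out <- tibble(
    gene = rownames(vals),
    logFC = unname(lfc),
    t = unname(tstat),
    df = unname(ifelse(se > 0, df, NA_real_)),
    p = unname(p),
    q = adjust_bh(unname(p)),
    direction = unname(ifelse(lfc > 0, "up", "down")),
    passed = NA
  )
  structure(out,
    group_a = group_a, group_b = group_b, paired = paired,
    class = c("cerna_de", class(out))
  )
}

.row_vars <- function(m) {
  ctr <- m - rowMeans(m)
  rowSums(ctr * ctr) / (ncol(m) - 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: on sorted p-values, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, clipped to 1 and mapped back to the input order. The
#' result is equivariant under permutation of the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_cernet("p-values must all lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes by effect-size and FDR thresholds
#'
#' A gene passes iff `|logFC| > lfc_min` and `q < fdr_max` — both strict
#' inequalities, so a gene sitting exactly on a threshold fails.
#'
#' @param de A `cerna_de` table from [differential_expression()].
#' @param lfc_min Minimum absolute log2 fold change (strict; default 1).
#' @param fdr_max Maximum BH-adjusted p-value (strict; default 0.05).
#' @return `de` with its `passed` column set; the thresholds and the
#'   up/down counts are attached as attributes and reported by
#'   [glance.cerna_de()].
#' @export
apply_thresholds <- function(de, lfc_min = 1, fdr_max = 0.05) {
  assert_scalar_number(lfc_min, "lfc_min", lower = 0)
  assert_scalar_number(fdr_max, "fdr_max", 0, 1)
  if (anyNA(de$q)) stop_cernet("q-values must be computed before thresholding")
  de$passed <- abs(de$logFC) > lfc_min & de$q < fdr_max
  structure(de,
    lfc_min = lfc_min, fdr_max = fdr_max,
    n_up = sum(de$passed & de$direction == "up"),
    n_down = sum(de$passed & de$direction == "down"),
    class = unique(c("cerna_de", class(de)))
  )
}

#' Genes passing the differential expression thresholds
#'
#' @param de A thresholded `cerna_de` table.
#' @param direction Optionally restrict to `"up"` or `"down"` genes.
#' @return Character vector of gene identifiers.
#' @export
de_genes <- function(de, direction = NULL) {
  if (anyNA(de$passed)) stop_cernet("run apply_thresholds() first")
  keep <- de$passed
  if (!is.null(direction)) keep <- keep & de$direction == direction
  de$gene[keep]
}

#' One-row summary of a differential expression analysis
#'
#' @param x A `cerna_de` table (thresholded or not).
#' @param ... Unused.
#' @return A one-row tibble with the number of genes tested, the thresholds
#'   and the up/down counts (NA before [apply_thresholds()]).
#' @export
glance.cerna_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    lfc_min = attr(x, "lfc_min") %||% NA_real_,
    fdr_max = attr(x, "fdr_max") %||% NA_real_,
    n_up = attr(x, "n_up") %||% NA_integer_,
    n_down = attr(x, "n_down") %||% NA_integer_,
    paired = attr(x, "paired") %||% NA
  )
}

#' Volcano plot of a differential expression table
#'
#' @param object A `cerna_de` table, ideally after [apply_thresholds()].
#' @param ... Unused.
#' @return A ggplot object: logFC against -log10(q), passing genes
#'   highlighted.
#' @export
autoplot.cerna_de <- function(object, ...) {
  df <- as_tibble(object)
  df$status <- dplyr::case_when(
    is.na(df$passed) ~ "untested",
    df$passed & df$direction == "up" ~ "up",
    df$passed ~ "down",
    TRUE ~ "not significant"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$logFC, -log10(.data$q), colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      up = "#c0392b", down = "#2980b9",
      `not significant` = "grey60", untested = "grey40"
    )) +
    ggplot2::labs(
      x = "log2 fold change", y = expression(-log[10] ~ "FDR"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Write a differential expression table to TSV
#'
#' @param de A `cerna_de` table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(as_tibble(de), path, progress = FALSE)
  invisible(path)
}
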