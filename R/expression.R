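#' Remove features with (near-)zero expression
#'
#' Keeps rows in which at least `min_fraction` of the samples exceed
#' `min_value`. The defaults (`min_value = 0`, `min_fraction = 1`) drop
#' features whose intensity is zero or negative in any sample, i.e. the
#' classic removal of unexpressed probes before differential testing.
#'
#' @param x An [expr_matrix].
#' @param min_value Intensity a sample must exceed (strictly) to count as
#'   expressed.
#' @param min_fraction Minimum fraction of samples, in `[0, 1]`, that must
#'   exceed `min_value` for the row to be kept.
#' @return The filtered [expr_matrix]; row order is preserved. The number of
#'   kept rows is reported via `inform()`.
#' @export
filter_unexpressed <- function(x, min_value = 0, min_fraction = 1) {
  assert_scalar_number(min_fraction, "min_fraction", 0, 1)
  vals <- expr_values(x)
  frac <- rowMeans(vals > min_value)
  keep <- frac >= min_fraction
  inform(sprintf("filter_unexpressed: kept %d of %d rows", sum(keep), nrow(vals)))
  new_expr_matrix(
    as_tibble(x)[keep, , drop = FALSE],
    expr_groups(x), expr_scale(x), expr_level(x)
  )
}

#' Quantile-normalize an expression matrix across samples
#'
#' After normalization every column carries the identical multiset of
#' values: the across-sample mean of each order statistic. Ties within a
#' column receive the mean of the target values their ranks span, which
#' makes the operation deterministic. This is the normalization step used
#' inside RMA, applied here at the level of an already-summarized matrix.
#'
#' @param x An [expr_matrix] with at least two samples.
#' @return The normalized [expr_matrix].
#' @export
quantile_normalize <- function(x) {
  vals <- expr_values(x)
  if (ncol(vals) < 2L) {
    warn("quantile_normalize: single-column matrix returned unchanged")
    return(x)
  }
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  expr_from_values(norm, x)
}

#' Log2-transform a linear-scale matrix
#'
#' @param x An [expr_matrix] with `scale = "linear"`.
#' @param offset Non-negative pseudo-count added before taking logs
#'   (default 1, so zeros map to 0).
#' @return The [expr_matrix] on the log2 scale.
#' @export
log2_transform <- function(x, offset = 1) {
  if (expr_scale(x) == "log2") {
    stop_cernet("matrix is already on the log2 scale", class = "cernet_double_log")
  }
  assert_scalar_number(offset, "offset", lower = 0)
  vals <- expr_values(x) + offset
  if (any(vals <= 0)) {
    stop_cernet("non-positive value under log; increase `offset`")
  }
  expr_from_values(log2(vals), x, scale = "log2")
}

#' Read a probe annotation table
#'
#' Expects a TSV with columns `probe_id`, `gene_symbol`, `biotype`
#' (`mRNA` or `lncRNA`), `chromosome_band`, `start`, `end`.
#'
#' @param path Annotation TSV path.
#' @return A tibble with one row per probe.
#' @export
read_probe_annotation <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("probe_id", "gene_symbol", "biotype", "chromosome_band", "start", "end")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    stop_cernet(paste0("annotation is missing columns: ", paste(missing, collapse = ", ")))
  }
  validate_probe_annotation(tb)
  tb
}

validate_probe_annotation <- function(annot) {
  if (anyDuplicated(annot$probe_id)) {
    stop_cernet("annotation maps some probes to more than one gene symbol")
  }
  if (!all(annot$biotype %in% c("mRNA", "lncRNA"))) {
    stop_cernet("biotype must be 'mRNA' or 'lncRNA' for every probe")
  }
  if (any(annot$start >= annot$end)) {
    stop_cernet("annotation rows with start >= end")
  }
  invisible(annot)
}

#' Collapse probe-level rows to gene level by the mean
#'
#' Each gene's expression in a sample is the arithmetic mean of its probes'
#' values in that sample. Probes absent from the annotation are dropped
#' (with a reported count); the result is a gene-level matrix.
#'
#' @param x A probe-level [expr_matrix].
#' @param annot Probe annotation tibble (see [read_probe_annotation()]).
#' @return A gene-level [expr_matrix] whose `feature_id` column holds gene
#'   symbols.
#' @export
collapse_probes <- function(x, annot) {
  if (expr_level(x) != "probe") stop_cernet("collapse_probes needs a probe-level matrix")
  map <- setNames(annot$gene_symbol, annot$probe_id)
  annotated <- x$feature_id %in% names(map)
  if (!any(annotated)) {
    stop_cernet("no overlap between matrix probes and annotation")
  }
  if (any(!annotated)) {
    inform(sprintf("collapse_probes: dropped %d unannotated probes", sum(!annotated)))
  }
  vals <- expr_values(x)[annotated, , drop = FALSE]
  genes <- unname(map[rownames(vals)])
  collapsed <- rowsum(vals, group = genes, reorder = FALSE) /
    as.vector(table(factor(genes, levels = unique(genes))))
  expr_from_values(collapsed, x, level = "gene")
}

#' Split a gene-level matrix into mRNA and lncRNA matrices
#'
#' @param x A gene-level [expr_matrix].
#' @param annot Probe annotation tibble; the gene-to-biotype map is derived
#'   from it. A gene whose probes disagree on biotype is an error.
#' @return A named list with elements `mrna` and `lncrna`, both
#'   [expr_matrix] objects; their row counts sum to `nrow(x)`.
#' @export
split_by_biotype <- function(x, annot) {
  if (expr_level(x) != "gene") stop_cernet("split_by_biotype needs a gene-level matrix")
  bt <- distinct(annot, .data$gene_symbol, .data$biotype)
  conflicted <- bt$gene_symbol[duplicated(bt$gene_symbol)]
  if (length(conflicted)) {
    stop_cernet(paste0(
      "genes with conflicting biotypes: ", paste(unique(conflicted), collapse = ", ")
    ))
  }
  map <- setNames(bt$biotype, bt$gene_symbol)
  known <- x$feature_id %in% names(map)
  if (any(!known)) {
    stop_cernet(paste0(
      "genes missing from annotation: ",
      paste(head(x$feature_id[!known], 5), collapse = ", ")
    ))
  }
  pick <- function(biotype) {
    new_expr_matrix(
      as_tibble(x)[map[x$feature_id] == biotype, , drop = FALSE],
      expr_groups(x), expr_scale(x), expr_level(x)
    )
  }
  list(mrna = pick("mRNA"), lncrna = pick("lncRNA"))
}
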