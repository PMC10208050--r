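#' Expression matrix objects
#'
#' An `expr_matrix` is a tibble whose first column, `feature_id`, identifies
#' a probe or gene and whose remaining columns are numeric per-sample
#' intensities. Three attributes travel with it: `groups`, a named character
#' vector mapping every sample column to its group label (e.g. `day0` /
#' `day8`); `scale`, either `"linear"` or `"log2"`; and `level`, either
#' `"probe"` or `"gene"`. All preprocessing verbs in the package accept and
#' return this class, so a pipeline chains with the pipe.
#'
#' @param data A data frame with a `feature_id` column followed by numeric
#'   sample columns.
#' @param groups Named character vector: `sample id -> group label`. Every
#'   sample column must be assigned.
#' @param scale `"linear"` or `"log2"`.
#' @param level `"probe"` or `"gene"`.
#'
#' @return A tibble of class `expr_matrix`.
#' @examples
#' m <- expr_matrix(
#'   tibble::tibble(feature_id = c("p1", "p2"), s1 = c(1, 2), s2 = c(3, 4)),
#'   groups = c(s1 = "day0", s2 = "day8")
#' )
#' expr_samples(m)
#' @export
expr_matrix <- function(data, groups, scale = "linear", level = "probe") {
  data <- as_tibble(data)
  if (!"feature_id" %in% names(data)) {
    stop_cernet("expression data must have a `feature_id` column")
  }
  data <- dplyr::relocate(data, "feature_id")
  samples <- setdiff(names(data), "feature_id")
  if (length(samples) == 0L) stop_cernet("no sample columns found")
  bad <- samples[!vapply(data[samples], is.numeric, logical(1))]
  if (length(bad)) {
    stop_cernet(paste0("non-numeric sample columns: ", paste(bad, collapse = ", ")))
  }
  vals <- as.matrix(data[samples])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop_cernet("expression values must all be finite")
  }
  scale <- match.arg(scale, c("linear", "log2"))
  level <- match.arg(level, c("probe", "gene"))
  if (is.null(names(groups)) || !all(samples %in% names(groups))) {
    missing <- if (is.null(names(groups))) samples else setdiff(samples, names(groups))
    stop_cernet(paste0(
      "samples without a group assignment: ", paste(missing, collapse = ", ")
    ), class = "cernet_group_error")
  }
  if (level == "gene" && anyDuplicated(data$feature_id)) {
    stop_cernet("duplicate feature_id values are not allowed at gene level")
  }
  groups <- as.character(groups[samples]) |> setNames(samples)
  new_expr_matrix(data, groups, scale, level)
}

new_expr_matrix <- function(data, groups, scale, level) {
  structure(
    data,
    groups = groups,
    scale = scale,
    level = level,
    class = c("expr_matrix", class(tibble()))
  )
}

# rebuild an expr_matrix from a plain numeric matrix (rownames = features)
expr_from_values <- function(values, template, scale = NULL, level = NULL) {
  tb <- as_tibble(values, .name_repair = "minimal")
  tb <- dplyr::bind_cols(tibble(feature_id = rownames(values)), tb)
  new_expr_matrix(
    tb,
    groups = attr(template, "groups")[colnames(values)],
    scale = scale %||% expr_scale(template),
    level = level %||% expr_level(template)
  )
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
expr_samples <- function(x) setdiff(names(x), "feature_id")

#' @rdname expr_matrix
#' @export
expr_groups <- function(x) attr(x, "groups")

#' @rdname expr_matrix
#' @export
expr_scale <- function(x) attr(x, "scale")

#' @rdname expr_matrix
#' @export
expr_level <- function(x) attr(x, "level")

#' @rdname expr_matrix
#' @export
expr_values <- function(x) {
  v <- as.matrix(as_tibble(x)[expr_samples(x)])
  rownames(v) <- x$feature_id
  v
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d samples [%s, %s-level]\n",
    nrow(x), length(expr_samples(x)), expr_scale(x), expr_level(x)
  ))
  grp <- table(expr_groups(x))
  cat("groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  NextMethod()
}

#' Tidy an expression matrix into long format
#'
#' @param x An [expr_matrix].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample`, `group`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  grp <- expr_groups(x)
  tidyr::pivot_longer(as_tibble(x), -"feature_id",
    names_to = "sample", values_to = "value"
  ) |>
    mutate(group = unname(grp[.data$sample]), .before = "value")
}

#' Read an expression matrix and its sample-group map from TSV files
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and the first column holding probe (or gene) identifiers. The group map
#' assigns every sample column to a group (columns `sample`, `group`).
#'
#' @param path Path to the matrix TSV.
#' @param group_map Either a path to a two-column TSV (`sample`, `group`) or
#'   a named character vector / data frame giving the mapping directly.
#' @param scale,level Flags describing the stored values; defaults assume a
#'   linear-scale probe-level matrix.
#' @return An [expr_matrix].
#' @export
read_expression_matrix <- function(path, group_map, scale = "linear", level = "probe") {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tb) == 0L) stop_cernet("no data rows in expression matrix file")
  names(tb)[1] <- "feature_id"
  tb$feature_id <- as.character(tb$feature_id)
  bad <- setdiff(names(tb)[-1], names(tb)[-1][vapply(tb[-1], is.numeric, logical(1))])
  if (length(bad)) {
    stop_cernet(paste0("non-numeric cells in sample columns: ", paste(bad, collapse = ", ")))
  }
  groups <- read_group_map(group_map)
  expr_matrix(tb, groups, scale = scale, level = level)
}

read_group_map <- function(group_map) {
  if (is.character(group_map) && is.null(names(group_map)) && length(group_map) == 1L) {
    gm <- readr::read_tsv(group_map, show_col_types = FALSE, progress = FALSE)
    if (!all(c("sample", "group") %in% names(gm))) {
      stop_cernet("group map file must have columns `sample` and `group`")
    }
    return(setNames(as.character(gm$group), gm$sample))
  }
  if (is.data.frame(group_map)) {
    return(setNames(as.character(group_map$group), group_map$sample))
  }
  group_map
}

#' Write an expression matrix to TSV
#'
#' @param x An [expr_matrix].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
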