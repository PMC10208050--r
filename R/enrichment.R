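#' Read a gene-set library in GMT format
#'
#' Each GMT line is tab-separated: set name, description, then member gene
#' symbols. Duplicate members within a set are collapsed with a warning;
#' duplicate set names or lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return A named list of class `gene_set_library`; each element has
#'   `description` and a character vector `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_cernet("no gene sets in GMT file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    stop_cernet(sprintf("GMT lines with fewer than 3 fields: %s",
                        paste(which(short), collapse = ", ")))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop_cernet(paste0("duplicate gene-set names: ",
                       paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warn(sprintf("set '%s': duplicate members collapsed", f[[1L]]))
      members <- unique(members)
    }
    list(description = f[[2L]], members = members)
  })
  structure(setNames(sets, nm), class = "gene_set_library")
}

#' Write a gene-set library to GMT
#'
#' @param library A `gene_set_library` (or named list with `description`
#'   and `members` elements).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library), function(nm) {
    s <- library[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' The probability of observing at least `k` query genes inside a set of
#' size `K`, when `n` genes are drawn without replacement from a universe
#' of `N`: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. Computed via
#' the survival function, so small tail probabilities are stable.
#'
#' @param k Observed overlap.
#' @param K Set size within the universe.
#' @param n Query-list size within the universe.
#' @param N Universe size.
#' @return The p-value; `k = 0` gives exactly 1.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  assert_count(k, "k"); assert_count(K, "K")
  assert_count(n, "n"); assert_count(N, "N")
  if (K > N || n > N || k > min(K, n)) {
    stop_cernet("need k <= min(K, n), K <= N, n <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Gene-set over-representation analysis
#'
#' Tests every set in the library for over-representation of the query list
#' within a universe, using the one-sided hypergeometric test (equivalently
#' Fisher's exact upper tail), with Benjamini-Hochberg correction across
#' the tested sets. Query genes outside the universe are dropped (with a
#' reported count) and each set is intersected with the universe before
#' testing.
#'
#' @param query Character vector of genes of interest (e.g. the mRNAs of a
#'   ceRNA subnetwork).
#' @param library A `gene_set_library` from [read_gmt()].
#' @param universe Character vector: the background gene population,
#'   typically all mRNAs surviving the expression filter.
#' @param fdr_threshold A set passes iff `q < fdr_threshold`
#'   (default 0.01).
#' @return A tibble of class `cerna_enrichment`, one row per set, sorted by
#'   increasing p (ties broken by set name): `set`, `k`, `K`, `n`, `N`,
#'   `p`, `q`, `neg_log10_p`, `passed`.
#' @export
enrich <- function(query, library, universe, fdr_threshold = 0.01) {
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  if (dropped > 0) {
    inform(sprintf("enrich: dropped %d query genes outside the universe", dropped))
  }
  if (length(query) == 0L) {
    stop_cernet("no query genes remain after intersecting with the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map(names(library), function(nm) {
    members <- intersect(library[[nm]]$members, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    tibble(set = nm, k = k, K = K, n = n, N = N,
           p = if (K == 0L) 1 else hypergeometric_test(k, K, n, N))
  })
  out <- bind_rows(rows)
  out$q <- adjust_bh(out$p)
  out$neg_log10_p <- -log10(out$p)
  out$passed <- out$q < fdr_threshold
  out <- arrange(out, .data$p, .data$set)
  structure(out,
    fdr_threshold = fdr_threshold,
    class = c("cerna_enrichment", class(out))
  )
}

#' One-row summary of an enrichment analysis
#'
#' @param x A `cerna_enrichment` table.
#' @param ... Unused.
#' @return A one-row tibble: sets tested, sets passing, threshold, and the
#'   top set name.
#' @export
glance.cerna_enrichment <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_passed = sum(x$passed),
    fdr_threshold = attr(x, "fdr_threshold"),
    top_set = if (nrow(x)) x$set[[1L]] else NA_character_
  )
}

#' Bar plot of enrichment results
#'
#' @param object A `cerna_enrichment` table.
#' @param top_n Number of top sets to show (default 15).
#' @param ... Unused.
#' @return A ggplot object: sets on the x-axis, `-log10(p)` on the y-axis,
#'   passing sets highlighted.
#' @export
autoplot.cerna_enrichment <- function(object, top_n = 15, ...) {
  df <- head(as_tibble(object), top_n)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(.data$set, .data$neg_log10_p, fill = .data$passed)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ italic(p)), fill = "significant") +
    ggplot2::theme_minimal()
}
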