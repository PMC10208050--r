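#' Interaction tables
#'
#' Typed regulator-target pair tables with database provenance. Two kinds
#' exist: `"lncRNA-miRNA"` (miRcode-style sponge interactions, regulator =
#' lncRNA, target = miRNA) and `"miRNA-mRNA"` (TargetScan / miRTarBase-style
#' target interactions, regulator = miRNA, target = mRNA).
#'
#' @param regulator,target Character vectors of identifiers.
#' @param kind `"lncRNA-miRNA"` or `"miRNA-mRNA"`.
#' @param source_db Provenance label recycled over rows.
#' @return A tibble of class `interaction_table` with columns `regulator`,
#'   `target`, `source_db` and a `kind` attribute.
#' @export
interaction_table <- function(regulator, target, kind, source_db = "user") {
  kind <- match.arg(kind, c("lncRNA-miRNA", "miRNA-mRNA"))
  regulator <- trimws(as.character(regulator))
  target <- trimws(as.character(target))
  if (any(!nzchar(regulator)) || any(!nzchar(target))) {
    stop_cernet("interaction identifiers must be non-empty")
  }
  out <- tibble(regulator = regulator, target = target,
                source_db = rep_len(as.character(source_db), length(regulator)))
  structure(out, kind = kind, class = c("interaction_table", class(out)))
}

interaction_kind <- function(x) attr(x, "kind")

as_interaction <- function(tb, kind) {
  structure(as_tibble(tb), kind = kind,
            class = c("interaction_table", class(tibble())))
}

#' Read a regulator-target interaction table from TSV
#'
#' Column names differ between database exports, so they are configurable;
#' identifiers are whitespace-trimmed and case-preserved (set `fold_case`
#' for messy inputs). An optional alias map (e.g. miRNA family label to
#' mature name) is applied to both columns after reading.
#'
#' @param path TSV path.
#' @param kind `"lncRNA-miRNA"` or `"miRNA-mRNA"`.
#' @param regulator_col,target_col Names of the columns holding the
#'   regulator and target identifiers.
#' @param source_db Provenance label stored with every row.
#' @param alias_map Optional named character vector or two-column data frame
#'   (`alias`, `canonical`) mapping identifiers to canonical form.
#' @param fold_case Lower-case identifiers after trimming (default FALSE).
#' @return An `interaction_table`.
#' @export
read_interaction_table <- function(path, kind,
                                   regulator_col = "regulator",
                                   target_col = "target",
                                   source_db = "user",
                                   alias_map = NULL,
                                   fold_case = FALSE) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(regulator_col, target_col), names(tb))
  if (length(missing)) {
    stop_cernet(sprintf(
      "columns %s not found; available columns: %s",
      paste(missing, collapse = ", "), paste(names(tb), collapse = ", ")
    ))
  }
  if (nrow(tb) == 0L) {
    warn("read_interaction_table: empty table")
    return(interaction_table(character(), character(), kind, source_db))
  }
  out <- interaction_table(tb[[regulator_col]], tb[[target_col]], kind, source_db)
  if (fold_case) {
    out$regulator <- tolower(out$regulator)
    out$target <- tolower(out$target)
  }
  if (!is.null(alias_map)) out <- apply_alias_map(out, alias_map)
  out
}

#' Apply an identifier alias map to an interaction table
#'
#' @param x An `interaction_table`.
#' @param alias_map Named character vector (`alias = canonical`) or a data
#'   frame with columns `alias` and `canonical`.
#' @return The table with aliased identifiers replaced on both sides.
#' @export
apply_alias_map <- function(x, alias_map) {
  if (is.data.frame(alias_map)) {
    alias_map <- setNames(as.character(alias_map$canonical), alias_map$alias)
  }
  swap <- function(v) ifelse(v %in% names(alias_map), unname(alias_map[v]), v)
  x$regulator <- swap(x$regulator)
  x$target <- swap(x$target)
  x
}

#' Intersect two miRNA-mRNA interaction databases
#'
#' Keeps the (miRNA, mRNA) pairs present in both tables — the "validated by
#' both databases" rule — with provenance recorded as `"both"`. The result
#' is deduplicated; an empty intersection triggers a warning.
#'
#' @param db1,db2 `interaction_table`s of kind `"miRNA-mRNA"`.
#' @return An `interaction_table` of the common pairs.
#' @export
intersect_databases <- function(db1, db2) {
  if (!identical(interaction_kind(db1), "miRNA-mRNA") ||
      !identical(interaction_kind(db2), "miRNA-mRNA")) {
    stop_cernet("intersect_databases expects two miRNA-mRNA tables")
  }
  a <- deduplicate_interactions(db1)
  b <- deduplicate_interactions(db2)
  common <- inner_join(
    select(as_tibble(a), "regulator", "target"),
    select(as_tibble(b), "regulator", "target"),
    by = c("regulator", "target")
  )
  if (nrow(common) == 0L) warn("intersect_databases: no shared interactions")
  common$source_db <- rep_len("both", nrow(common))
  as_interaction(common, "miRNA-mRNA")
}

#' Restrict an interaction table to differentially expressed identifiers
#'
#' @param x An `interaction_table`.
#' @param de_ids Non-empty character vector of identifiers to keep.
#' @param side Which side of the pair must match: `"regulator"` or
#'   `"target"`.
#' @return The filtered table.
#' @export
restrict_to_de <- function(x, de_ids, side = c("regulator", "target")) {
  side <- match.arg(side)
  if (length(de_ids) == 0L) {
    stop_cernet("de_ids is empty: upstream differential expression produced no genes")
  }
  as_interaction(as_tibble(x)[x[[side]] %in% de_ids, , drop = FALSE],
                 interaction_kind(x))
}

#' Drop duplicate regulator-target pairs
#'
#' Keeps the first occurrence of each (regulator, target) pair, preserving
#' its provenance and the original row order.
#'
#' @param x An `interaction_table`.
#' @return The deduplicated table.
#' @export
deduplicate_interactions <- function(x) {
  keep <- !duplicated(paste(x$regulator, x$target, sep = "\r"))
  as_interaction(as_tibble(x)[keep, , drop = FALSE], interaction_kind(x))
}

#' Write an interaction table to TSV
#'
#' @param x An `interaction_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
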