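#' Tripartite ceRNA networks
#'
#' A `cerna_network` holds the competing-endogenous-RNA graph: lncRNA,
#' miRNA and mRNA nodes with undirected edges only between lncRNA-miRNA and
#' miRNA-mRNA pairs. It is a list with two tibbles, `nodes` (`id`,
#' `node_type`) and `edges` (`from`, `to`, `edge_type`, `source_db`), both
#' kept in a deterministic sort order so exports are byte-reproducible.
#'
#' @name cerna_network
NULL

new_cerna_network <- function(nodes, edges) {
  nodes <- arrange(as_tibble(nodes), .data$node_type, .data$id)
  edges <- arrange(as_tibble(edges), .data$edge_type, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

empty_network <- function() {
  new_cerna_network(
    tibble(id = character(), node_type = character()),
    tibble(from = character(), to = character(),
           edge_type = character(), source_db = character())
  )
}

#' Build the ceRNA network from interaction tables
#'
#' Takes the lncRNA-miRNA sponge table and the (database-intersected,
#' DE-restricted) miRNA-mRNA target table, unions their edges, and prunes
#' iteratively to a fixed point: a miRNA must keep at least one lncRNA
#' neighbour **and** one mRNA neighbour; lncRNAs and mRNAs left without any
#' edge are dropped. Without pruning, miRNAs dangling on one side would
#' inflate hub degrees.
#'
#' @param lnc_mi An `interaction_table` of kind `"lncRNA-miRNA"`.
#' @param mi_m An `interaction_table` of kind `"miRNA-mRNA"`.
#' @return A [cerna_network].
#' @export
build_cerna_network <- function(lnc_mi, mi_m) {
  if (!identical(interaction_kind(lnc_mi), "lncRNA-miRNA")) {
    stop_cernet("lnc_mi must be a lncRNA-miRNA table")
  }
  if (!identical(interaction_kind(mi_m), "miRNA-mRNA")) {
    stop_cernet("mi_m must be a miRNA-mRNA table")
  }
  lnc_mi <- deduplicate_interactions(lnc_mi)
  mi_m <- deduplicate_interactions(mi_m)

  roles <- bind_rows(
    tibble(id = lnc_mi$regulator, node_type = "lncRNA"),
    tibble(id = lnc_mi$target, node_type = "miRNA"),
    tibble(id = mi_m$regulator, node_type = "miRNA"),
    tibble(id = mi_m$target, node_type = "mRNA")
  ) |> distinct()
  conflicts <- roles$id[duplicated(roles$id)]
  if (length(conflicts)) {
    stop_cernet(paste0(
      "identifiers used with conflicting node types: ",
      paste(sort(unique(conflicts)), collapse = ", ")
    ))
  }

  e_lm <- tibble(from = lnc_mi$regulator, to = lnc_mi$target,
                 edge_type = "lnc-mi", source_db = lnc_mi$source_db)
  e_mm <- tibble(from = mi_m$regulator, to = mi_m$target,
                 edge_type = "mi-m", source_db = mi_m$source_db)

  repeat {
    keep_mi <- intersect(e_lm$to, e_mm$from)
    e_lm2 <- e_lm[e_lm$to %in% keep_mi, , drop = FALSE]
    e_mm2 <- e_mm[e_mm$from %in% keep_mi, , drop = FALSE]
    if (nrow(e_lm2) == nrow(e_lm) && nrow(e_mm2) == nrow(e_mm)) break
    e_lm <- e_lm2
    e_mm <- e_mm2
  }

  edges <- bind_rows(e_lm, e_mm)
  node_ids <- unique(c(edges$from, edges$to))
  nodes <- roles[roles$id %in% node_ids, , drop = FALSE]
  new_cerna_network(nodes, edges)
}

#' Validate the structural invariants of a ceRNA network
#'
#' Checks that the graph is strictly tripartite (edges only lncRNA-miRNA
#' and miRNA-mRNA), that every node has degree at least one, and that every
#' miRNA keeps a neighbour on both sides. Called throughout the test suite
#' after every network operation.
#'
#' @param net A [cerna_network].
#' @return `net`, invisibly; an invariant violation raises an error.
#' @export
validate_cerna_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  if (anyDuplicated(nodes$id)) stop_cernet("duplicate node ids")
  type_of <- setNames(nodes$node_type, nodes$id)
  if (nrow(edges)) {
    ft <- type_of[edges$from]
    tt <- type_of[edges$to]
    if (anyNA(ft) || anyNA(tt)) stop_cernet("edge endpoint missing from node table")
    ok <- (edges$edge_type == "lnc-mi" & ft == "lncRNA" & tt == "miRNA") |
      (edges$edge_type == "mi-m" & ft == "miRNA" & tt == "mRNA")
    if (!all(ok)) stop_cernet("network is not strictly tripartite")
  }
  deg <- node_degrees(net)
  if (nrow(nodes) && (nrow(deg) < nrow(nodes) || any(deg$degree < 1))) {
    stop_cernet("network contains degree-0 nodes")
  }
  mi <- nodes$id[nodes$node_type == "miRNA"]
  if (length(mi)) {
    has_lnc <- mi %in% edges$to[edges$edge_type == "lnc-mi"]
    has_m <- mi %in% edges$from[edges$edge_type == "mi-m"]
    if (!all(has_lnc & has_m)) {
      stop_cernet("miRNA node lacking a neighbour on one side")
    }
  }
  invisible(net)
}

#' Node degrees of a ceRNA network
#'
#' @param net A [cerna_network].
#' @return A tibble with columns `id`, `node_type`, `degree` (count of
#'   incident edges); the degree sum equals twice the edge count.
#' @export
node_degrees <- function(net) {
  if (nrow(net$edges) == 0L) {
    return(tibble(id = character(), node_type = character(), degree = integer()))
  }
  counts <- table(c(net$edges$from, net$edges$to))
  left_join(net$nodes,
    tibble(id = names(counts), degree = as.integer(counts)),
    by = "id"
  ) |>
    mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree))
}

#' Rank lncRNAs by network degree
#'
#' Hub candidate lncRNAs are those sponging the most miRNAs in the pruned
#' network. Ties are broken lexicographically by identifier so rankings are
#' deterministic.
#'
#' @param net A [cerna_network].
#' @param top_k Number of top lncRNAs to return (default all).
#' @return A tibble (`lncrna`, `degree`) sorted by decreasing degree.
#' @export
rank_lncrnas <- function(net, top_k = Inf) {
  if (top_k < 1) stop_cernet("top_k must be at least 1")
  deg <- node_degrees(net)
  out <- deg |>
    filter(.data$node_type == "lncRNA") |>
    arrange(desc(.data$degree), .data$id) |>
    select(lncrna = "id", "degree")
  if (is.finite(top_k)) out <- slice_head(out, n = as.integer(top_k))
  out
}

#' Extract the subnetwork anchored at one lncRNA
#'
#' The subnetwork contains the lncRNA, its miRNA neighbours, every mRNA
#' targeted by those miRNAs, the anchoring lncRNA-miRNA edges, and all
#' miRNA-mRNA edges of those miRNAs. The union of the subnetworks over all
#' lncRNAs recovers the parent network's edge set.
#'
#' @param net A [cerna_network].
#' @param lncrna_id Identifier of an lncRNA node of `net`.
#' @return A [cerna_network].
#' @export
extract_subnetwork <- function(net, lncrna_id) {
  type_of <- setNames(net$nodes$node_type, net$nodes$id)
  if (is.na(type_of[lncrna_id]) || type_of[lncrna_id] != "lncRNA") {
    stop_cernet(sprintf("'%s' is not an lncRNA node of this network", lncrna_id))
  }
  e <- net$edges
  mi <- e$to[e$edge_type == "lnc-mi" & e$from == lncrna_id]
  keep <- (e$edge_type == "lnc-mi" & e$from == lncrna_id) |
    (e$edge_type == "mi-m" & e$from %in% mi)
  edges <- e[keep, , drop = FALSE]
  ids <- unique(c(edges$from, edges$to))
  new_cerna_network(net$nodes[net$nodes$id %in% ids, , drop = FALSE], edges)
}

#' Summary counts of a ceRNA network
#'
#' @param net A [cerna_network].
#' @return A one-row tibble: `n_lncrna`, `n_mirna`, `n_mrna`, `n_edges`.
#' @export
network_summary <- function(net) {
  tibble(
    n_lncrna = sum(net$nodes$node_type == "lncRNA"),
    n_mirna = sum(net$nodes$node_type == "miRNA"),
    n_mrna = sum(net$nodes$node_type == "mRNA"),
    n_edges = nrow(net$edges)
  )
}

#' @rdname network_summary
#' @param x A [cerna_network].
#' @param ... Unused.
#' @export
glance.cerna_network <- function(x, ...) network_summary(x)

#' Edge table of a ceRNA network
#'
#' @param x A [cerna_network].
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `edge_type`, `source_db`) with
#'   endpoint node types joined in.
#' @export
tidy.cerna_network <- function(x, ...) {
  type_of <- setNames(x$nodes$node_type, x$nodes$id)
  mutate(x$edges,
    from_type = unname(type_of[.data$from]),
    to_type = unname(type_of[.data$to])
  )
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(
    "<cerna_network> %d lncRNA / %d miRNA / %d mRNA nodes, %d edges\n",
    s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges
  ))
  invisible(x)
}

#' Export a ceRNA network to Cytoscape-readable formats
#'
#' Supported formats: `"sif"` (one edge per line,
#' `source<TAB>interaction<TAB>target` with interaction `lnc-mi` / `mi-m`),
#' `"graphml"` (with a `node_type` vertex attribute), and `"tsv"` (the edge
#' table, re-readable with [read_network_edges()]). Output order is the
#' network's stable sort, so repeated exports are byte-identical.
#'
#' @param net A [cerna_network].
#' @param path Output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (nrow(net$edges) == 0L) warn("export_network: network is empty")
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", net$edges$from, net$edges$edge_type, net$edges$to)
    writeLines(lines, path)
  } else if (format == "tsv") {
    readr::write_tsv(net$edges, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      d = net$edges,
      directed = FALSE,
      vertices = net$nodes
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network edge table written by [export_network()] (`"tsv"` format)
#'
#' @param path Edge TSV path.
#' @return A tibble (`from`, `to`, `edge_type`, `source_db`).
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Plot a ceRNA network in a three-column tripartite layout
#'
#' @param object A [cerna_network].
#' @param ... Unused.
#' @return A ggplot object with lncRNAs, miRNAs and mRNAs in separate
#'   columns and edges drawn between adjacent columns.
#' @export
autoplot.cerna_network <- function(object, ...) {
  xcol <- c(lncRNA = 0, miRNA = 1, mRNA = 2)
  nodes <- object$nodes |>
    group_by(.data$node_type) |>
    mutate(y = seq_len(n()) / (n() + 1)) |>
    ungroup() |>
    mutate(x = unname(xcol[.data$node_type]))
  pos <- setNames(split(nodes[c("x", "y")], seq_len(nrow(nodes))), nodes$id)
  seg <- object$edges |>
    mutate(
      x = vapply(.data$from, function(i) pos[[i]]$x, numeric(1)),
      y = vapply(.data$from, function(i) pos[[i]]$y, numeric(1)),
      xend = vapply(.data$to, function(i) pos[[i]]$x, numeric(1)),
      yend = vapply(.data$to, function(i) pos[[i]]$y, numeric(1))
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, colour = .data$node_type), size = 2
    ) +
    ggplot2::scale_x_continuous(
      breaks = unname(xcol), labels = names(xcol), limits = c(-0.3, 2.3)
    ) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}
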