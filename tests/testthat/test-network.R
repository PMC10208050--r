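# hand example used throughout: m2 has no mRNA target and must be pruned
hand_network <- function() {
  lnc_mi <- interaction_table(c("L1", "L1", "L2"), c("m1", "m2", "m3"),
                              "lncRNA-miRNA", "mircode")
  mi_m <- interaction_table(c("m1", "m1", "m3"), c("G1", "G2", "G3"),
                            "miRNA-mRNA", "both")
  build_cerna_network(lnc_mi, mi_m)
}

test_that("network construction prunes one-sided miRNAs and keeps valid structure", {
  net <- hand_network()
  validate_cerna_network(net)
  expect_setequal(net$nodes$id, c("L1", "L2", "m1", "m3", "G1", "G2", "G3"))
  expect_false("m2" %in% net$nodes$id)
  expect_equal(nrow(net$edges), 5)

  s <- network_summary(net)
  expect_equal(unlist(s), c(n_lncrna = 2, n_mirna = 2, n_mrna = 3, n_edges = 5))
  expect_identical(glance(net), s)

  # node-type conflict is an error listing the offender
  bad_lnc <- interaction_table("G1", "m1", "lncRNA-miRNA")
  bad_mi <- interaction_table("m1", "G1", "miRNA-mRNA")
  expect_error(build_cerna_network(bad_lnc, bad_mi), "G1")

  # empty miRNA-mRNA side cascades to an empty network
  empty <- build_cerna_network(
    interaction_table("L1", "m1", "lncRNA-miRNA"),
    interaction_table(character(), character(), "miRNA-mRNA")
  )
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(unname(unlist(network_summary(empty))), c(0, 0, 0, 0))
})

test_that("degrees follow the handshake lemma and min degree is 1 after pruning", {
  net <- hand_network()
  deg <- node_degrees(net)
  expect_equal(deg$degree[deg$id == "m1"], 3)
  expect_equal(sum(deg$degree), 2 * nrow(net$edges))
  expect_gte(min(deg$degree), 1)
  expect_equal(nrow(node_degrees(empty_net <- build_cerna_network(
    interaction_table(character(), character(), "lncRNA-miRNA"),
    interaction_table(character(), character(), "miRNA-mRNA")
  ))), 0)
})

test_that("prune is a fixed point: rebuilding from the pruned edges changes nothing", {
  for (seed in c(1, 2, 3)) {
    net <- random_network(seed)$net
    e <- net$edges
    lnc_mi <- interaction_table(e$from[e$edge_type == "lnc-mi"],
                                e$to[e$edge_type == "lnc-mi"], "lncRNA-miRNA")
    mi_m <- interaction_table(e$from[e$edge_type == "mi-m"],
                              e$to[e$edge_type == "mi-m"], "miRNA-mRNA")
    rebuilt <- build_cerna_network(lnc_mi, mi_m)
    expect_equal(rebuilt$edges[c("from", "to", "edge_type")],
                 net$edges[c("from", "to", "edge_type")])
  }
})

test_that("lncRNA ranking is degree-descending with lexicographic ties", {
  net <- hand_network()
  r <- rank_lncrnas(net)
  expect_equal(r$lncrna, c("L1", "L2"))  # degrees 2 and 1
  expect_equal(rank_lncrnas(net, top_k = 1)$lncrna, "L1")
  expect_error(rank_lncrnas(net, top_k = 0), "top_k")

  # tie broken lexicographically
  tie <- build_cerna_network(
    interaction_table(c("LB", "LA"), c("m1", "m2"), "lncRNA-miRNA"),
    interaction_table(c("m1", "m2"), c("G1", "G2"), "miRNA-mRNA")
  )
  expect_equal(rank_lncrnas(tie)$lncrna, c("LA", "LB"))
})

test_that("subnetworks are valid, sound, and union back to the parent", {
  net <- hand_network()
  sub <- extract_subnetwork(net, "L1")
  validate_cerna_network(sub)
  expect_setequal(sub$nodes$id, c("L1", "m1", "G1", "G2"))
  expect_equal(nrow(sub$edges), 3)
  expect_error(extract_subnetwork(net, "m1"), "not an lncRNA")
  expect_error(extract_subnetwork(net, "nope"), "not an lncRNA")

  edge_key <- function(n) paste(n$edges$from, n$edges$to)
  for (seed in 4:8) {
    parent <- random_network(seed)$net
    if (nrow(parent$edges) == 0) next
    lncs <- parent$nodes$id[parent$nodes$node_type == "lncRNA"]
    union_edges <- character()
    for (l in lncs) {
      s <- extract_subnetwork(parent, l)
      validate_cerna_network(s)
      expect_true(all(edge_key(s) %in% edge_key(parent)))  # soundness
      union_edges <- union(union_edges, edge_key(s))
    }
    expect_setequal(union_edges, edge_key(parent))
  }
})

test_that("planted hubs occupy the top degree ranks", {
  hits <- 0L
  for (seed in 1:10) {
    rn <- random_network(seed + 100)
    hubs <- rn$truth$hub_lncrnas
    top <- rank_lncrnas(rn$net, top_k = length(hubs))$lncrna
    hits <- hits + as.integer(setequal(top, hubs))
  }
  expect_gte(hits, 9)
})

test_that("exports produce Cytoscape-readable files that round-trip", {
  net <- hand_network()
  dir <- withr::local_tempdir()

  sif <- file.path(dir, "net.sif")
  export_network(net, sif, format = "sif")
  lines <- readLines(sif)
  expect_length(lines, 5)
  expect_true(all(grepl("^\\S+\t(lnc-mi|mi-m)\t\\S+$", lines)))

  tsv <- file.path(dir, "net.tsv")
  export_network(net, tsv, format = "tsv")
  back <- read_network_edges(tsv)
  expect_equal(back$from, net$edges$from)
  expect_equal(back$to, net$edges$to)

  gml <- file.path(dir, "net.graphml")
  export_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "node_type"), net$nodes$node_type)

  # byte-reproducibility of repeated exports
  sif2 <- file.path(dir, "net2.sif")
  export_network(net, sif2, format = "sif")
  expect_identical(readLines(sif), readLines(sif2))

  empty <- build_cerna_network(
    interaction_table(character(), character(), "lncRNA-miRNA"),
    interaction_table(character(), character(), "miRNA-mRNA")
  )
  expect_warning(export_network(empty, file.path(dir, "empty.sif"), "sif"), "empty")
  expect_error(export_network(net, file.path(dir, "x"), format = "xml"))
})
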