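make_matrix_file <- function(tb, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  readr::write_tsv(tb, path, progress = FALSE)
  path
}

test_that("expression matrices round-trip through TSV with group assignment", {
  tb <- tibble::tibble(
    probe = c("p1", "p2", "p3"),
    a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9), d = c(10, 11, 12)
  )
  path <- make_matrix_file(tb)
  groups <- c(a = "day0", b = "day0", c = "day8", d = "day8")
  m <- read_expression_matrix(path, groups)
  expect_equal(dim(expr_values(m)), c(3L, 4L))
  expect_equal(unname(table(expr_groups(m))["day0"]), 2L, ignore_attr = TRUE)

  # a sample absent from the group map is an error naming the sample
  expect_error(read_expression_matrix(path, groups[-4]), "d",
               class = "cernet_group_error")

  empty <- make_matrix_file(tb[0, ])
  expect_error(read_expression_matrix(empty, groups), "no data rows")
})

test_that("filter_unexpressed keeps rows expressed in enough samples", {
  vals <- rbind(
    zero = c(0, 0, 0, 0),
    ok = c(1, 2, 3, 4)
  )
  m <- make_expr(vals, scale = "linear")
  suppressMessages({
    kept <- filter_unexpressed(m, min_value = 0, min_fraction = 1)
    expect_equal(kept$feature_id, "ok")
    # min_value = -Inf keeps everything
    expect_equal(nrow(filter_unexpressed(m, min_value = -Inf)), 2)
  })

  # 10 rows, exactly 4 exceed the threshold everywhere
  vals10 <- matrix(5, nrow = 10, ncol = 4)
  vals10[5:10, 2] <- 0.1   # rows 5..10 dip below in one sample
  m10 <- make_expr(vals10, scale = "linear")
  suppressMessages(expect_equal(nrow(filter_unexpressed(m10, min_value = 1)), 4))

  expect_error(filter_unexpressed(m, min_fraction = 2), "min_fraction")
})

test_that("filter_unexpressed is monotone in min_value", {
  set.seed(42)
  m <- make_expr(matrix(stats::rexp(200), 50, 4), scale = "linear")
  suppressMessages({
    for (cut in c(0.1, 0.5, 1, 2)) {
      lo <- filter_unexpressed(m, min_value = cut / 2, min_fraction = 0.5)
      hi <- filter_unexpressed(m, min_value = cut, min_fraction = 0.5)
      expect_true(all(hi$feature_id %in% lo$feature_id))
    }
  })
})

test_that("quantile normalization equalizes column distributions", {
  m <- make_expr(cbind(a = c(1, 2, 3), b = c(4, 5, 6)),
                 groups = c(a = "day0", b = "day8"))
  norm <- expr_values(quantile_normalize(m))
  expect_equal(unname(norm[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(norm[, "b"]), c(2.5, 3.5, 4.5))

  set.seed(1)
  r <- make_expr(matrix(stats::rnorm(300), 50, 6))
  rn <- expr_values(quantile_normalize(r))
  sorted <- apply(rn, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])

  # idempotence to machine precision
  rn2 <- expr_values(quantile_normalize(quantile_normalize(r)))
  expect_equal(rn2, rn, tolerance = 1e-12)

  one <- make_expr(matrix(1:3, 3, 1, dimnames = list(NULL, "a")),
                   groups = c(a = "day0"))
  expect_warning(quantile_normalize(one), "single-column")
})

test_that("log2 transform applies the offset and guards against double logs", {
  m <- make_expr(matrix(c(7, 0), 2, 2), scale = "linear")
  out <- log2_transform(m, offset = 1)
  expect_equal(unname(expr_values(out)[, 1]), c(3, 0))
  expect_equal(expr_scale(out), "log2")
  expect_error(log2_transform(out), class = "cernet_double_log")
  expect_error(log2_transform(m, offset = 0), "non-positive")
})

test_that("collapse_probes averages a gene's probes per sample", {
  vals <- rbind(p1 = c(2, 4, 6), p2 = c(4, 6, 8), p3 = c(10, 10, 10))
  m <- make_expr(vals, level = "probe",
                 groups = c(s01 = "day0", s02 = "day0", s03 = "day8"))
  annot <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                          gene_symbol = c("G1", "G1", "G2"),
                          biotype = "mRNA")
  g <- collapse_probes(m, annot)
  expect_equal(expr_level(g), "gene")
  v <- expr_values(g)
  expect_equal(unname(v["G1", ]), c(3, 5, 7))
  expect_equal(unname(v["G2", ]), c(10, 10, 10))  # single probe passes through

  # 100 probes over 40 genes collapse to exactly 40 rows
  set.seed(7)
  big <- make_expr(matrix(stats::rnorm(400), 100, 4), level = "probe")
  map <- tibble::tibble(
    probe_id = big$feature_id,
    gene_symbol = sprintf("G%02d", c(seq_len(40), sample(40, 60, replace = TRUE))),
    biotype = "mRNA"
  )
  expect_equal(nrow(collapse_probes(big, map)), 40)

  # collapsing commutes with averaging over samples
  cg <- collapse_probes(big, map)
  by_gene <- tapply(rowMeans(expr_values(big)), map$gene_symbol, mean)
  expect_equal(as.numeric(by_gene[cg$feature_id]), unname(rowMeans(expr_values(cg))))

  expect_error(collapse_probes(m, annot[0, ]), "no overlap")
})

test_that("split_by_biotype partitions rows without loss", {
  genes <- c(sprintf("M%d", 1:9), sprintf("L%d", 1:4))
  m <- make_expr(matrix(stats::rnorm(52), 13, 4), features = genes)
  annot <- tibble::tibble(
    probe_id = paste0("p", seq_along(genes)),
    gene_symbol = genes,
    biotype = rep(c("mRNA", "lncRNA"), c(9, 4))
  )
  parts <- split_by_biotype(m, annot)
  expect_equal(nrow(parts$mrna), 9)
  expect_equal(nrow(parts$lncrna), 4)
  expect_equal(nrow(parts$mrna) + nrow(parts$lncrna), nrow(m))

  all_m <- annot
  all_m$biotype <- "mRNA"
  parts2 <- split_by_biotype(m, all_m)
  expect_equal(nrow(parts2$lncrna), 0)

  conflicted <- rbind(annot, tibble::tibble(
    probe_id = "px", gene_symbol = "M1", biotype = "lncRNA"
  ))
  expect_error(split_by_biotype(m, conflicted), "conflicting")
})
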