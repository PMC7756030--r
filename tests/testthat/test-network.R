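test_that("Pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  expect_equal(as.numeric(pcc(x, y, min_pairs = 4)), pcc_oracle(x, y))
  expect_equal(pcc_oracle(x, y), 0.6)  # hand: 3 / sqrt(5 * 5)
  # perfect linear relations
  expect_equal(as.numeric(pcc(x, 2 * x + 1, min_pairs = 4)), 1.0)
  expect_equal(as.numeric(pcc(x, -x, min_pairs = 4)), -1.0)
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(as.numeric(pcc(a, b, 10)), pcc_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("correlations drop incomplete pairs and flag degenerate input", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  got <- pcc(x, y, min_pairs = 3)
  expect_equal(as.numeric(got), pcc_oracle(c(1, 4, 5), c(2, 8, 10)))
  expect_equal(attr(got, "n"), 3L)
  too_few <- pcc(x, y, min_pairs = 4)
  expect_true(is.na(too_few))
  expect_equal(attr(too_few, "reason"), "too few complete pairs")
  flat <- pcc(rep(1, 12), rnorm(12), min_pairs = 10)
  expect_true(is.na(flat))
  expect_equal(attr(flat, "reason"), "zero variance")
})

test_that("correlation differences follow |a - b|", {
  expect_equal(pcc_difference(0.14, 0.83), 0.69)
  expect_equal(pcc_difference(0.5, 0.5), 0)
  expect_equal(pcc_difference(-0.5, 0.5), 1.0)
  expect_error(pcc_difference(1.4, 0))
})

test_that("network assembly keeps only pairs past the delta threshold", {
  st <- sim_one(sim_config(seed = 37, n_tumor = 80, n_normal = 80,
                           n_genes = 60, n_intergenic_probes = 20))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  th <- eqtm_thresholds()
  net <- build_network(dms, pairs, pp$beta_tumor, pp$beta_normal,
                       pp$expr_tumor, pp$expr_normal, th)
  expect_true(all(net$edges$delta_pcc > th$delta_pcc))
  expect_true(all(net$candidates$delta_pcc[
    !paste(net$candidates$probe_id, net$candidates$gene_id) %in%
      paste(net$edges$probe_id, net$edges$gene_id)] <= th$delta_pcc))
  # every edge's probe is a DMS and its pair is a mapped pair
  expect_true(all(net$edges$probe_id %in% dms$records$probe_id))
  expect_true(all(paste(net$edges$probe_id, net$edges$gene_id) %in%
                  paste(pairs$probe_id, pairs$gene_id)))
  # node sets equal the union of edge endpoints
  expect_setequal(net$dms_nodes, unique(net$edges$probe_id))
  expect_setequal(net$lncRNA_nodes, unique(net$edges$gene_id))
  # sign classes partition the edges
  s <- network_stats(net)
  expect_equal(s$n_positive + s$n_negative, s$n_edges)
})

test_that("raising the delta threshold never adds edges", {
  st <- sim_one(small_config(41))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  prev <- NULL
  for (d in c(0.2, 0.3, 0.5, 0.9)) {
    net <- suppressWarnings(
      build_network(dms, pairs, pp$beta_tumor, pp$beta_normal,
                    pp$expr_tumor, pp$expr_normal,
                    eqtm_thresholds(delta_pcc = d)))
    keys <- paste(net$edges$probe_id, net$edges$gene_id)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("swapping condition labels preserves the edge set", {
  st <- sim_one(small_config(43))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  net <- suppressWarnings(
    build_network(dms, pairs, pp$beta_tumor, pp$beta_normal,
                  pp$expr_tumor, pp$expr_normal))
  swapped <- suppressWarnings(
    build_network(dms, pairs, pp$beta_normal, pp$beta_tumor,
                  pp$expr_normal, pp$expr_tumor))
  k1 <- sort(paste(net$edges$probe_id, net$edges$gene_id))
  k2 <- sort(paste(swapped$edges$probe_id, swapped$edges$gene_id))
  expect_identical(k1, k2)
  m <- match(paste(net$edges$probe_id, net$edges$gene_id),
             paste(swapped$edges$probe_id, swapped$edges$gene_id))
  expect_equal(net$edges$delta_pcc, swapped$edges$delta_pcc[m])
})

test_that("network statistics count an assembled toy network exactly", {
  edges <- rbind(edge_row("p1", "gA", 0.5, -0.2),
                 edge_row("p2", "gA", 0.4, -0.3),
                 edge_row("p3", "gB", 0.6, 0.1),
                 edge_row("p4", "gC", -0.5, 0.2),
                 edge_row("p5", "gC", -0.4, 0.3))
  net <- make_net(edges)
  s <- network_stats(net)
  expect_equal(s$n_edges, 5)
  expect_equal(s$n_positive, 3)
  expect_equal(s$n_negative, 2)
  expect_equal(s$n_dms, 5)
  expect_equal(s$n_lncRNA, 3)
  expect_equal(s$degree$degree[s$degree$node == "gA"], 2)
  # empty network: all zeros
  s0 <- network_stats(make_net(edges[0, ]))
  expect_equal(s0$n_edges, 0)
  expect_equal(s0$n_dms, 0)
})

test_that("exports are readable by graph tooling", {
  edges <- rbind(edge_row("p1", "gA", 0.5, -0.2),
                 edge_row("p2", "gB", -0.4, 0.3))
  net <- make_net(edges)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), 2)
  expect_match(lines[1], "^p1\tpositive\tgA$")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::edge_attr(g, "sign_class"),
                  c("positive", "negative"))
})
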