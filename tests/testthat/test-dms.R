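test_that("probe t-test matches the textbook two-sample test", {
  tum <- c(0.9, 0.8, 0.85); nor <- c(0.2, 0.3, 0.25)
  got <- test_probe(tum, nor)
  want <- t.test(tum, nor, var.equal = TRUE)
  expect_equal(got$t_stat, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)
  expect_lt(got$p_value, 0.01)
  expect_equal(got$delta, 0.6)

  set.seed(55)
  for (i in 1:20) {
    x <- runif(sample(3:30, 1)); y <- runif(sample(3:30, 1))
    ve <- i %% 2 == 0
    got <- test_probe(x, y, var_equal = ve)
    want <- t.test(x, y, var.equal = ve)
    expect_equal(got$t_stat, unname(want$statistic))
    expect_equal(got$p_value, want$p.value)
  }
})

test_that("degenerate probes: identical groups, tiny groups, NAs", {
  g <- c(0.4, 0.5, 0.6)
  r <- test_probe(g, g)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_value, 1)
  # (2,2) with tiny variance still yields finite t and valid p
  r2 <- test_probe(c(0.5, 0.5001), c(0.6, 0.6001))
  expect_true(is.finite(r2$t_stat))
  expect_true(r2$p_value > 0 && r2$p_value <= 1)
  # NAs dropped per group
  r3 <- test_probe(c(0.1, NA, 0.2, 0.15), c(0.5, 0.6, NA, 0.55))
  want <- t.test(c(0.1, 0.2, 0.15), c(0.5, 0.6, 0.55), var.equal = TRUE)
  expect_equal(r3$p_value, want$p.value)
  # <2 observed values, or constant-in-both with unequal means: untestable
  expect_false(test_probe(c(0.1), c(0.2, 0.3))$testable)
  expect_false(test_probe(c(0.2, 0.2), c(0.7, 0.7))$testable)
})

test_that("vectorised row tests agree with the scalar path", {
  set.seed(66)
  bt <- matrix(runif(200), 20); bn <- matrix(runif(160), 20)
  bt[sample(200, 10)] <- NA
  tt <- lnceqtm:::row_ttest(bt, bn)
  for (i in c(1, 7, 20)) {
    want <- test_probe(bt[i, ], bn[i, ])
    expect_equal(tt$t_stat[i], want$t_stat)
    expect_equal(tt$p_value[i], want$p_value)
  }
})

test_that("BH q-values equal the brute-force step-up procedure", {
  set.seed(77)
  for (i in 1:5) {
    p <- runif(sample(10:100, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
  # and the q-values emitted by call_dms are the BH transform of its p's
  st <- sim_one(small_config(12))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  expect_equal(dms$tested$fdr_q, brute_bh(dms$tested$p_value),
               tolerance = 1e-12)
})

test_that("DMS calls respect both FDR and effect-size criteria", {
  # planted large-delta probes are called; a significant but small-delta
  # probe is excluded
  set.seed(88)
  n <- 30
  mk_group <- function(means, n) {
    t(vapply(means, function(m) rnorm(n, m, 0.01), numeric(n)))
  }
  means_n <- c(0.50, 0.50, 0.30)
  means_t <- c(0.90, 0.70, 0.30)  # deltas 0.4, 0.2, 0
  bt <- mk_group(means_t, n); bn <- mk_group(means_n, n)
  rownames(bt) <- rownames(bn) <- c("big", "small", "null")
  colnames(bt) <- sprintf("t%d", 1:n); colnames(bn) <- sprintf("n%d", 1:n)
  pairs <- data.frame(probe_id = c("big", "small", "null"),
                      gene_id = "G1", biotype_class = "lincRNA")
  dms <- call_dms(bt, bn, pairs)
  expect_equal(dms$records$probe_id, "big")
  expect_equal(dms$records$direction, "up")
  small_row <- dms$tested[dms$tested$probe_id == "small", ]
  expect_lt(small_row$fdr_q, 0.05)  # significant yet excluded by delta
})

test_that("tightening thresholds never increases the call count", {
  st <- sim_one(small_config(19))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  n_prev <- Inf
  for (db in c(0.1, 0.3, 0.5)) {
    n <- nrow(call_dms(pp$beta_tumor, pp$beta_normal, pairs,
                       eqtm_thresholds(delta_beta = db))$records)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  n_prev <- Inf
  for (a in c(0.2, 0.05, 0.001)) {
    n <- nrow(call_dms(pp$beta_tumor, pp$beta_normal, pairs,
                       eqtm_thresholds(fdr_alpha = a))$records)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("unmapped probes never enter the FDR family", {
  st <- sim_one(small_config(23))
  pp <- preprocess_subtype(st$expr_tumor, st$expr_normal,
                           st$beta_tumor, st$beta_normal)
  pairs <- map_probes(st$probes, st$genes)
  dms <- call_dms(pp$beta_tumor, pp$beta_normal, pairs)
  expect_true(all(dms$tested$probe_id %in% pairs$probe_id))
  intergenic <- setdiff(rownames(pp$beta_tumor), pairs$probe_id)
  expect_length(intersect(dms$tested$probe_id, intergenic), 0)
})

test_that("DMS summaries count probes, genes and directions correctly", {
  records <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    direction = c("up", "up", "up", "down", "up"),
    stringsAsFactors = FALSE)
  links <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5", "p5"),
    gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"),
    biotype_class = c(rep("lincRNA", 4), "other_lncRNA", "other_lncRNA"),
    stringsAsFactors = FALSE)
  s <- summarize_dms(list(records = records, links = links))
  linc <- s$by_class[s$by_class$biotype_class == "lincRNA", ]
  expect_equal(linc$n_dms, 4)
  expect_equal(linc$n_genes, 2)
  expect_equal(linc$pct_up, 75)  # 3 up of 4
  other <- s$by_class[s$by_class$biotype_class == "other_lncRNA", ]
  expect_equal(other$n_dms, 1)   # p5 counted once in the class
  expect_equal(other$n_genes, 2) # but contributes to both genes
  # empty class reports NA percent
  s2 <- summarize_dms(list(records = records[4, ], links = links[4, ]))
  expect_true(is.na(s2$by_class$pct_up[s2$by_class$biotype_class ==
                                       "other_lncRNA"]))
})
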