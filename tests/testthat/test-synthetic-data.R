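test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(frac_dms = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "positive count")
  expect_error(sim_config(dms_effect = 0.95), "dms_effect")
  expect_error(sim_config(coupling_normal = 1.5), "target correlation")
  expect_error(sim_config(n_probes_per_gene = c(4, 1)), "min, max")
})

test_that("annotation honors requested counts and biotype fractions", {
  cfg <- sim_config(seed = 3, n_genes = 10, fraction_lincRNA = 0.5,
                    n_probes_per_gene = c(3, 3), n_intergenic_probes = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_equal(sum(ann$genes$biotype_class == "lincRNA"), 5)
  expect_equal(nrow(ann$probes), 30)
  expect_true(all(!is.na(ann$probes$host_gene)))
  # non-overlapping spans on the synthetic chromosome
  o <- order(ann$genes$start)
  expect_true(all(ann$genes$start[o][-1] > ann$genes$end[o][-10]))
  # every in-gene probe lies inside its host span
  gi <- match(ann$probes$host_gene, ann$genes$gene_id)
  expect_true(all(ann$probes$pos >= ann$genes$start[gi] &
                  ann$probes$pos <= ann$genes$end[gi]))
  expect_error(generate_annotation(sim_config(chrom_length = 1000)),
               "cannot hold")
})

test_that("planted and degenerate-feature counts are exact", {
  cfg <- sim_config(seed = 11, n_genes = 50, n_probes_per_gene = c(2, 2),
                    n_intergenic_probes = 0, frac_dms = 0.2,
                    frac_all_na_probes = 0.1, frac_all_zero_genes = 0.2,
                    n_tumor = 20, n_normal = 20)
  st <- simulate_study(cfg, "A")$subtypes$A
  expect_equal(nrow(st$truth$dms), round(0.2 * 100))
  all_na <- rowSums(!is.na(cbind(st$beta_tumor, st$beta_normal))) == 0
  expect_equal(sum(all_na), 10)  # round(0.1 * 100) probes
  expect_setequal(rownames(st$beta_tumor)[all_na], st$truth$all_na_probes)
  all_zero <- rowSums(st$expr_tumor != 0) + rowSums(st$expr_normal != 0) == 0
  expect_equal(sum(all_zero), 10)  # round(0.2 * 50) genes
  expect_setequal(rownames(st$expr_tumor)[all_zero], st$truth$all_zero_genes)
})

test_that("value-range invariants hold: betas in [0,1] or NA, expression >= 0", {
  st <- simulate_study(small_config(5), "A")$subtypes$A
  b <- c(st$beta_tumor, st$beta_normal)
  expect_true(all(is.na(b) | (b >= 0 & b <= 1)))
  expect_true(all(c(st$expr_tumor, st$expr_normal) >= 0))
})

test_that("identical seed gives byte-identical study bundles", {
  cfg <- small_config(42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, d1, subtypes = c("A", "B"))
  generate_study(cfg, d2, subtypes = c("A", "B"))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  m1 <- unname(tools::md5sum(file.path(d1, f1)))
  m2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(m1, m2)
})

test_that("two subtype bundles share annotation but have disjoint samples", {
  res <- simulate_study(small_config(9), c("A", "B"))
  sa <- c(colnames(res$subtypes$A$beta_tumor),
          colnames(res$subtypes$A$beta_normal))
  sb <- c(colnames(res$subtypes$B$beta_tumor),
          colnames(res$subtypes$B$beta_normal))
  expect_length(intersect(sa, sb), 0)
  # planted DMS overlap follows frac_shared
  n_dms <- nrow(res$subtypes$A$truth$dms)
  common <- intersect(res$subtypes$A$truth$dms$probe_id,
                      res$subtypes$B$truth$dms$probe_id)
  expect_equal(length(common), round(0.5 * n_dms))
})

test_that("planted DMS effect is recovered in expectation", {
  cfg <- sim_config(seed = 21, n_tumor = 50, n_normal = 50, n_genes = 60,
                    n_intergenic_probes = 0, dms_effect = 0.4,
                    frac_probe_na = 0, frac_all_na_probes = 0)
  st <- simulate_study(cfg, "A")$subtypes$A
  tr <- st$truth$dms
  obs <- rowMeans(st$beta_tumor[tr$probe_id, ]) -
    rowMeans(st$beta_normal[tr$probe_id, ])
  # per-probe sampling SE of a mean difference at concentration 20
  se <- sqrt(2 * 0.25 / 21 / 50)
  expect_true(all(abs(obs - tr$true_delta) < 6 * se))
  expect_lt(abs(mean(abs(obs)) - 0.4), 3 * se / sqrt(nrow(tr)))
})

test_that("null probes give uniform t-test p-values", {
  set.seed(401)
  cfg <- sim_config(seed = 77, n_tumor = 60, n_normal = 60, n_genes = 150,
                    n_probes_per_gene = c(2, 2), n_intergenic_probes = 0,
                    frac_dms = 0, frac_probe_na = 0, frac_all_na_probes = 0)
  st <- simulate_study(cfg, "A")$subtypes$A
  p <- lnceqtm:::row_ttest(st$beta_tumor, st$beta_normal)$p_value
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("condition-specific coupling yields the target correlations", {
  cfg <- sim_config(seed = 13, n_tumor = 100, n_normal = 100,
                    coupling_normal = 0.8, coupling_tumor = 0,
                    frac_probe_na = 0, frac_all_na_probes = 0)
  st <- simulate_study(cfg, "A")$subtypes$A
  tr <- st$truth$eqtm
  r_n <- r_t <- numeric(nrow(tr))
  for (j in seq_len(nrow(tr))) {
    r_n[j] <- cor(st$beta_normal[tr$probe_id[j], ],
                  log2(st$expr_normal[tr$gene_id[j], ]))
    r_t[j] <- cor(st$beta_tumor[tr$probe_id[j], ],
                  log2(st$expr_tumor[tr$gene_id[j], ]))
  }
  expect_gt(mean(r_n > 0.6), 0.95)
  expect_gt(mean(abs(r_t) < 0.2), 0.90)
  expect_lt(abs(mean(r_n) - 0.8), 0.05)
})

test_that("coupling for an unknown gene is a consistency error", {
  cfg <- small_config(2)
  ann <- generate_annotation(cfg)
  meth <- generate_methylation(cfg, ann$probes, ann$truth)
  bad_truth <- meth$truth
  bad_truth$eqtm$gene_id[1] <- "NOT_A_GENE"
  expect_error(
    generate_expression(cfg, ann$genes, meth$beta_tumor,
                        meth$beta_normal, bad_truth),
    "unmapped gene")
})

test_that("censoring control: rate 0 observes every event", {
  cfg <- small_config(6, censor_rate = 0)
  st <- simulate_study(cfg, "A")$subtypes$A
  expect_true(all(st$clinical$event == 1L))
  expect_true(all(st$clinical$time > 0))
  cfg2 <- small_config(6, censor_rate = 0.5)
  st2 <- simulate_study(cfg2, "A")$subtypes$A
  expect_equal(sum(st2$clinical$event == 0L), round(0.5 * cfg2$n_tumor))
})

test_that("null hazards give uniform log-rank p over median splits", {
  set.seed(402)
  cfg <- sim_config(seed = 31, n_tumor = 60, n_normal = 10, n_genes = 30,
                    n_prognostic = 0, frac_probe_na = 0,
                    frac_all_na_probes = 0)
  ps <- replicate(60, {
    cfg$seed <- sample.int(1e6, 1)
    st <- simulate_study(cfg, "A")$subtypes$A
    probe <- st$truth$dms$probe_id[1]
    grp <- median_split(st$beta_tumor[probe, ])
    logrank_and_km(grp, st$clinical)$logrank_p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("planted hazard recovers a positive Cox sign in most seeds", {
  set.seed(403)
  signs <- replicate(10, {
    cfg <- sim_config(seed = sample.int(1e6, 1), n_tumor = 200,
                      n_normal = 10, n_genes = 30, n_prognostic = 1,
                      hazard_coefs = 4,
                      frac_probe_na = 0, frac_all_na_probes = 0)
    st <- simulate_study(cfg, "A")$subtypes$A
    probe <- st$truth$prognostic$probe_id[1]
    fit <- fit_cox(st$beta_tumor, probe, st$clinical)
    sign(fit$coefs[[1]])
  })
  expect_gte(mean(signs > 0), 0.95)
})
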