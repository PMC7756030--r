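#' Generate a synthetic gene/probe annotation with planted-signal slots
#'
#' Places non-overlapping lncRNA gene spans on a synthetic chromosome,
#' assigns biotypes per `fraction_lincRNA`, drops CpG probes inside each
#' span plus intergenic probes outside every span, and chooses which
#' probes carry planted differential methylation, eQTM coupling and
#' survival hazard.  Coordinates are 1-based inclusive.
#'
#' @param config a [sim_config()] object.
#' @param subtype_index 1 or 2; subtype B re-plants its DMS set sharing
#'   `frac_shared` of subtype A's.
#' @return list with `genes`, `probes` (both data.frames) and `truth`
#'   (planted-signal tables; see [generate_study()]).
#' @export
generate_annotation <- function(config, subtype_index = 1L) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, "annotation"))
  ng <- config$n_genes
  rng <- config$n_probes_per_gene
  if (length(rng) == 1L) rng <- c(rng, rng)

  gene_len <- sample(2000:20000, ng, replace = TRUE)
  gap <- sample(1000:10000, ng, replace = TRUE)
  start <- cumsum(gap + c(0L, gene_len[-ng]))
  end <- start + gene_len - 1L
  needed <- end[ng] + 10000L
  if (!is.null(config$chrom_length) && config$chrom_length < needed)
    stop("generate_annotation: chromosome of length ", config$chrom_length,
         " cannot hold ", ng, " non-overlapping genes (needs >= ", needed,
         " bp)", call. = FALSE)

  n_linc <- round(config$fraction_lincRNA * ng)
  biotype_raw <- character(ng)
  linc_idx <- sample.int(ng, n_linc)
  biotype_raw[linc_idx] <- "lincRNA"
  others <- c("antisense", "sense_overlapping",
              "transcribed_processed_pseudogene")
  biotype_raw[-linc_idx] <- sample(others, ng - n_linc, replace = TRUE)
  if (n_linc == ng) biotype_raw <- rep("lincRNA", ng)

  genes <- data.frame(
    gene_id = sprintf("SYNG%08d.%d", seq_len(ng),
                      sample(1:9, ng, replace = TRUE)),
    symbol = sprintf("LNC-%04d", seq_len(ng)),
    chrom = "chr1",
    start = start, end = end,
    strand = sample(c("+", "-"), ng, replace = TRUE),
    biotype_raw = biotype_raw,
    biotype_class = classify_biotype(biotype_raw),
    stringsAsFactors = FALSE
  )

  npg <- if (rng[1] == rng[2]) rep(rng[1], ng)
         else sample(rng[1]:rng[2], ng, replace = TRUE)
  in_gene <- do.call(rbind, lapply(seq_len(ng), function(i) {
    pos <- sort(sample(start[i]:end[i], npg[i]))
    data.frame(chrom = "chr1", pos = pos, host_gene = genes$gene_id[i],
               stringsAsFactors = FALSE)
  }))
  inter <- if (config$n_intergenic_probes > 0L) {
    # place intergenic probes in the gaps before each gene
    gap_start <- start - gap + 1L
    gpos <- integer(0)
    while (length(gpos) < config$n_intergenic_probes) {
      gi <- sample.int(ng, config$n_intergenic_probes * 2L, replace = TRUE)
      cand <- gap_start[gi] + sample(0:499, length(gi), replace = TRUE)
      ok <- cand < start[gi]
      gpos <- unique(c(gpos, cand[ok]))
    }
    data.frame(chrom = "chr1",
               pos = sort(gpos[seq_len(config$n_intergenic_probes)]),
               host_gene = NA_character_, stringsAsFactors = FALSE)
  } else NULL
  probes <- rbind(in_gene, inter)
  probes <- probes[order(probes$pos), ]
  probes$probe_id <- sprintf("cg%08d", seq_len(nrow(probes)))
  probes$strand <- "+"
  rownames(probes) <- NULL
  probes <- probes[, c("probe_id", "chrom", "pos", "strand", "host_gene")]

  truth <- plant_signals(config, probes, subtype_index)
  list(genes = genes, probes = probes, truth = truth)
}

# Length-safe sampling from a vector (sample() would expand a length-1
# numeric into 1:n).
sample_vec <- function(x, size = length(x), ...) {
  x[sample.int(length(x), size, ...)]
}

# Choose planted DMS probes, eQTM-coupled pairs (at most one per host
# gene) and prognostic probes.  Subtype 2 shares frac_shared of subtype
# 1's DMS set; planting draws come from a dedicated RNG stream.
plant_signals <- function(config, probes, subtype_index = 1L) {
  set.seed(stream_seed(config$seed, "planting"))
  ingene <- probes$probe_id[!is.na(probes$host_gene)]
  n_dms <- round(config$frac_dms * length(ingene))
  pool <- sample_vec(ingene)  # one shared shuffle for both subtypes
  dms_a <- sort(pool[seq_len(n_dms)])
  if (subtype_index == 1L) {
    dms <- dms_a
  } else {
    n_shared <- round(config$frac_shared * n_dms)
    rest <- setdiff(pool, dms_a)
    dms <- sort(c(sample_vec(dms_a, n_shared),
                  rest[seq_len(n_dms - n_shared)]))
  }
  set.seed(stream_seed(config$seed, "planting", subtype_index))
  direction <- sample(c("up", "down"), length(dms), replace = TRUE)

  host <- probes$host_gene[match(dms, probes$probe_id)]
  first_per_gene <- !duplicated(host)
  eligible <- dms[first_per_gene]
  n_eqtm <- round(config$frac_eqtm * length(dms))
  n_eqtm <- min(n_eqtm, length(eligible))
  eqtm_probes <- sort(sample_vec(eligible, n_eqtm))
  eqtm <- data.frame(
    probe_id = eqtm_probes,
    gene_id = probes$host_gene[match(eqtm_probes, probes$probe_id)],
    rho_normal = rep(config$coupling_normal, n_eqtm),
    rho_tumor = rep(config$coupling_tumor, n_eqtm),
    stringsAsFactors = FALSE
  )

  n_prog <- min(config$n_prognostic, nrow(eqtm))
  prog_probes <- if (n_prog > 0L) sort(sample_vec(eqtm$probe_id, n_prog))
                 else character(0)
  prognostic <- data.frame(
    probe_id = prog_probes,
    hazard_coef = if (n_prog > 0L) config$hazard_coefs[seq_len(n_prog)]
                  else numeric(0),
    stringsAsFactors = FALSE
  )

  list(
    dms = data.frame(probe_id = dms, direction = direction,
                     true_delta = ifelse(direction == "up", 1, -1) *
                       config$dms_effect,
                     gene_id = host, stringsAsFactors = FALSE),
    eqtm = eqtm,
    prognostic = prognostic
  )
}

#' Generate tumor and normal methylation matrices with planted DMSs
#'
#' Null probes draw from a Beta distribution with a probe-specific mean
#' shared by both conditions; planted DMS probes shift the tumor mean by
#' `dms_effect` in the recorded direction, with both group means kept
#' inside (0, 1).  Values are clipped to `[0, 1]`; NAs are injected per
#' `frac_probe_na`, and exactly `round(frac_all_na_probes * n_probes)`
#' non-planted probes are made all-NA in both cohorts.
#'
#' @param config a [sim_config()] object.
#' @param probes probe table from [generate_annotation()].
#' @param truth planted-signal tables from [generate_annotation()].
#' @param subtype_index RNG stream selector.
#' @return list with `beta_tumor`, `beta_normal` (probes x samples) and
#'   `truth` updated with realised per-probe baselines.
#' @export
generate_methylation <- function(config, probes, truth,
                                 subtype_index = 1L) {
  set.seed(stream_seed(config$seed, "methylation", subtype_index))
  np <- nrow(probes)
  nt <- config$n_tumor; nn <- config$n_normal
  eff <- config$dms_effect
  margin <- 0.05
  if (eff + 2 * margin >= 1)
    stop("generate_methylation: dms_effect ", eff,
         " leaves no room for group means inside (0, 1)", call. = FALSE)

  m_normal <- stats::runif(np, margin, 1 - margin)
  m_tumor <- m_normal
  di <- match(truth$dms$probe_id, probes$probe_id)
  up <- truth$dms$direction == "up"
  # redraw planted baselines so mean +/- effect stays inside (0, 1)
  m_normal[di[up]] <- stats::runif(sum(up), margin, 1 - margin - eff)
  m_tumor[di[up]] <- m_normal[di[up]] + eff
  m_normal[di[!up]] <- stats::runif(sum(!up), margin + eff, 1 - margin)
  m_tumor[di[!up]] <- m_normal[di[!up]] - eff

  k <- config$meth_concentration
  draw <- function(means, n) {
    m <- matrix(stats::rbeta(length(means) * n,
                             shape1 = rep(means, n) * k,
                             shape2 = rep(1 - means, n) * k),
                nrow = length(means))
    pmin(pmax(m, 0), 1)
  }
  beta_tumor <- draw(m_tumor, nt)
  beta_normal <- draw(m_normal, nn)
  sample_ids <- function(prefix, n)
    sprintf("S%d_%s%03d", subtype_index, prefix, seq_len(n))
  dimnames(beta_tumor) <- list(probes$probe_id, sample_ids("T", nt))
  dimnames(beta_normal) <- list(probes$probe_id, sample_ids("N", nn))

  if (config$frac_probe_na > 0) {
    for (m in c("beta_tumor", "beta_normal")) {
      mm <- get(m)
      idx <- which(stats::runif(length(mm)) < config$frac_probe_na)
      mm[idx] <- NA_real_
      assign(m, mm)
    }
  }
  n_all_na <- round(config$frac_all_na_probes * np)
  if (n_all_na > 0L) {
    planted <- unique(c(truth$dms$probe_id, truth$eqtm$probe_id))
    free <- setdiff(probes$probe_id, planted)
    if (length(free) < n_all_na)
      stop("generate_methylation: not enough non-planted probes to make ",
           n_all_na, " probes all-NA", call. = FALSE)
    all_na <- sample_vec(free, n_all_na)
    beta_tumor[all_na, ] <- NA_real_
    beta_normal[all_na, ] <- NA_real_
    truth$all_na_probes <- sort(all_na)
  } else {
    truth$all_na_probes <- character(0)
  }
  truth$baseline_mean <- data.frame(probe_id = probes$probe_id,
                                    mean_tumor = m_tumor,
                                    mean_normal = m_normal,
                                    stringsAsFactors = FALSE)
  list(beta_tumor = beta_tumor, beta_normal = beta_normal, truth = truth)
}

#' Generate tumor and normal expression matrices with planted coupling
#'
#' Latent log2 expression is a per-gene baseline plus noise; for planted
#' eQTM pairs the standardized methylation of the paired probe enters
#' linearly with weight `rho` against `sqrt(1 - rho^2)` independent
#' noise, so the population correlation between beta and log2 expression
#' equals the configured per-condition target.  The latent values are
#' exponentiated (base 2) onto a non-negative raw scale.  Zeros are
#' injected per `frac_expression_zero` and exactly
#' `round(frac_all_zero_genes * n_genes)` genes are made all-zero; both
#' kinds of zeros avoid planted-pair genes so planted correlations stay
#' at their targets.
#'
#' @param config a [sim_config()] object.
#' @param genes gene table.
#' @param beta_tumor,beta_normal methylation matrices.
#' @param truth planted-signal tables.
#' @param subtype_index RNG stream selector.
#' @return list with raw-scale `expr_tumor`, `expr_normal` and `truth`
#'   updated with the all-zero gene list.
#' @export
generate_expression <- function(config, genes, beta_tumor, beta_normal,
                                truth, subtype_index = 1L) {
  bad <- setdiff(truth$eqtm$gene_id, genes$gene_id)
  if (length(bad))
    stop("generate_expression: coupling specified for unmapped gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  set.seed(stream_seed(config$seed, "expression", subtype_index))
  ng <- nrow(genes)
  mu <- stats::runif(ng, 2, 8)
  sd_e <- config$noise_sd

  latent <- function(beta, rho_col) {
    n <- ncol(beta)
    z <- matrix(stats::rnorm(ng * n, mean = mu, sd = sd_e), nrow = ng)
    for (j in seq_len(nrow(truth$eqtm))) {
      gi <- match(truth$eqtm$gene_id[j], genes$gene_id)
      rho <- truth$eqtm[[rho_col]][j]
      b <- beta[truth$eqtm$probe_id[j], ]
      bs <- (b - mean(b, na.rm = TRUE)) /
        max(stats::sd(b, na.rm = TRUE), 1e-12)
      bs[is.na(bs)] <- 0  # missing betas contribute the mean
      eps <- stats::rnorm(n)
      z[gi, ] <- mu[gi] + sd_e * (rho * bs + sqrt(1 - rho^2) * eps)
    }
    z
  }
  z_t <- latent(beta_tumor, "rho_tumor")
  z_n <- latent(beta_normal, "rho_normal")
  expr_tumor <- 2^z_t
  expr_normal <- 2^z_n
  dimnames(expr_tumor) <- list(genes$gene_id, colnames(beta_tumor))
  dimnames(expr_normal) <- list(genes$gene_id, colnames(beta_normal))

  planted_genes <- truth$eqtm$gene_id
  free_genes <- setdiff(genes$gene_id, planted_genes)
  n_zero_genes <- round(config$frac_all_zero_genes * ng)
  if (n_zero_genes > length(free_genes))
    stop("generate_expression: not enough non-planted genes to zero out",
         call. = FALSE)
  zero_genes <- if (n_zero_genes > 0L) sample_vec(free_genes, n_zero_genes)
               else character(0)
  expr_tumor[zero_genes, ] <- 0
  expr_normal[zero_genes, ] <- 0
  if (config$frac_expression_zero > 0) {
    droppable <- setdiff(free_genes, zero_genes)
    for (m in c("expr_tumor", "expr_normal")) {
      mm <- get(m)
      sub <- mm[droppable, , drop = FALSE]
      idx <- which(stats::runif(length(sub)) < config$frac_expression_zero)
      sub[idx] <- 0
      mm[droppable, ] <- sub
      assign(m, mm)
    }
  }
  truth$all_zero_genes <- sort(zero_genes)
  list(expr_tumor = expr_tumor, expr_normal = expr_normal, truth = truth)
}

#' Generate clinical follow-up tied to planted prognostic methylation
#'
#' Survival times are exponential with per-patient rate
#' `lambda0 * exp(lp)`, where the linear predictor `lp` is the sum of
#' `hazard_coef * beta` over the planted prognostic probes, centred so
#' the baseline median survival equals `baseline_median_days`.  Exactly
#' `round(censor_rate * n_tumor)` patients are censored at a uniform
#' fraction of their event time.
#'
#' @param config a [sim_config()] object.
#' @param beta_tumor tumor methylation matrix.
#' @param truth planted-signal tables.
#' @param subtype_index RNG stream selector.
#' @return data.frame with `sample_id`, `time` (days), `event`.
#' @export
generate_clinical <- function(config, beta_tumor, truth,
                              subtype_index = 1L) {
  set.seed(stream_seed(config$seed, "clinical", subtype_index))
  samples <- colnames(beta_tumor)
  n <- length(samples)
  lp <- rep(0, n)
  for (j in seq_len(nrow(truth$prognostic))) {
    b <- beta_tumor[truth$prognostic$probe_id[j], ]
    b[is.na(b)] <- mean(b, na.rm = TRUE)
    lp <- lp + truth$prognostic$hazard_coef[j] * b
  }
  lp <- lp - mean(lp)
  lambda0 <- log(2) / config$baseline_median_days
  time <- stats::rexp(n, rate = lambda0 * exp(lp))
  event <- rep(1L, n)
  n_cens <- round(config$censor_rate * n)
  if (n_cens > 0L) {
    ci <- sample.int(n, n_cens)
    time[ci] <- time[ci] * stats::runif(n_cens)
    event[ci] <- 0L
  }
  data.frame(sample_id = samples, time = round(time, 2) + 0.01,
             event = event, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study on disk
#'
#' Writes a shared annotation (GTF + probe manifest) and, per subtype,
#' tumor/normal beta and expression matrices, a clinical table and a
#' planted-truth JSON.  Two-subtype studies share the annotation and
#' `frac_shared` of the planted DMS set, with disjoint sample ids.
#'
#' @param config a [sim_config()] object.
#' @param out_dir output directory (created if needed).
#' @param subtypes character vector of 1 or 2 subtype labels.
#' @return (invisibly) a named list of written file paths plus the
#'   in-memory `study` object as returned by [simulate_study()].
#' @export
generate_study <- function(config, out_dir, subtypes = c("A", "B")) {
  stopifnot(length(subtypes) %in% 1:2)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("generate_study: cannot create output directory ", out_dir,
         call. = FALSE)
  study <- simulate_study(config, subtypes)
  paths <- list(
    gtf = file.path(out_dir, "annotation.gtf"),
    probes = file.path(out_dir, "probes.tsv")
  )
  write_gtf(study$genes, paths$gtf)
  write_tsv(study$probes[, c("probe_id", "chrom", "pos", "strand")],
            paths$probes)
  for (s in subtypes) {
    d <- study$subtypes[[s]]
    p <- list(
      beta_tumor = file.path(out_dir, paste0("beta_tumor_", s, ".tsv")),
      beta_normal = file.path(out_dir, paste0("beta_normal_", s, ".tsv")),
      expr_tumor = file.path(out_dir, paste0("expr_tumor_", s, ".tsv")),
      expr_normal = file.path(out_dir, paste0("expr_normal_", s, ".tsv")),
      clinical = file.path(out_dir, paste0("clinical_", s, ".tsv")),
      truth = file.path(out_dir, paste0("truth_", s, ".json"))
    )
    write_matrix_tsv(d$beta_tumor, p$beta_tumor, "probe_id")
    write_matrix_tsv(d$beta_normal, p$beta_normal, "probe_id")
    write_matrix_tsv(d$expr_tumor, p$expr_tumor, "gene_id")
    write_matrix_tsv(d$expr_normal, p$expr_normal, "gene_id")
    write_tsv(d$clinical, p$clinical)
    jsonlite::write_json(d$truth, p$truth, dataframe = "rows",
                         digits = NA, pretty = TRUE)
    paths[[paste0("subtype_", s)]] <- p
  }
  invisible(c(paths, list(study = study)))
}

#' Simulate a complete study in memory
#'
#' Same generative process as [generate_study()] without touching disk.
#'
#' @param config a [sim_config()] object.
#' @param subtypes 1 or 2 subtype labels.
#' @return list with `genes`, `probes` and per-subtype data
#'   (`beta_tumor`, `beta_normal`, `expr_tumor`, `expr_normal`,
#'   `clinical`, `truth`).
#' @export
simulate_study <- function(config, subtypes = "A") {
  stopifnot(length(subtypes) %in% 1:2)
  ann <- generate_annotation(config)
  out <- list(genes = ann$genes, probes = ann$probes, subtypes = list())
  for (i in seq_along(subtypes)) {
    truth <- if (i == 1L) ann$truth
             else plant_signals(config, ann$probes, subtype_index = 2L)
    meth <- generate_methylation(config, ann$probes, truth,
                                 subtype_index = i)
    expr <- generate_expression(config, ann$genes, meth$beta_tumor,
                                meth$beta_normal, meth$truth,
                                subtype_index = i)
    clinical <- generate_clinical(config, meth$beta_tumor, expr$truth,
                                  subtype_index = i)
    out$subtypes[[subtypes[i]]] <- list(
      beta_tumor = meth$beta_tumor, beta_normal = meth$beta_normal,
      expr_tumor = expr$expr_tumor, expr_normal = expr$expr_normal,
      clinical = clinical, truth = expr$truth
    )
  }
  out
}
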