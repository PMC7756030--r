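#' Simulation configuration for a synthetic lnc-eQTM study
#'
#' Bundles every knob of the synthetic-study generator into a validated
#' object.  A study consists of a shared gene/probe annotation and, per
#' subtype, tumor and normal methylation matrices, expression matrices and
#' tumor clinical follow-up, with planted ground-truth signals at three
#' levels: differentially methylated CpG sites (DMSs), condition-specific
#' methylation-expression coupling (eQTM pairs), and methylation-linked
#' survival hazards.
#'
#' @param seed master integer seed; every file kind derives its own stream
#'   from it, so identical configs give byte-identical output.
#' @param n_tumor,n_normal sample counts per condition.
#' @param n_genes number of lncRNA loci to place.
#' @param fraction_lincRNA fraction of genes given the `lincRNA` biotype;
#'   the rest draw from antisense/sense_overlapping/pseudogene biotypes.
#' @param n_probes_per_gene integer range `c(min, max)` of CpG probes placed
#'   inside each gene span.
#' @param n_intergenic_probes probes placed outside every gene span.
#' @param dms_effect planted difference in mean beta at DMS probes
#'   (direction randomized per probe and recorded).
#' @param frac_dms fraction of in-gene probes planted as DMSs.
#' @param coupling_normal,coupling_tumor target population Pearson
#'   correlation between methylation and log2 expression for planted eQTM
#'   pairs, per condition.  The generator realises them through a linear
#'   coupling of standardized beta into latent log2 expression, so the
#'   population correlation equals the requested value exactly.
#' @param frac_eqtm fraction of planted DMS probes that additionally carry
#'   an eQTM coupling to their host gene (at most one coupled probe per
#'   gene); the remaining DMS probes act as null differential-correlation
#'   pairs.
#' @param noise_sd standard deviation of latent log2 expression around the
#'   per-gene baseline for uncoupled genes.
#' @param meth_concentration concentration of the Beta distribution used
#'   for per-probe methylation draws (mean m gives shape `m * k`,
#'   `(1 - m) * k`); 20 gives a per-probe SD of about 0.11 at m = 0.5,
#'   typical of a variable 450k probe.
#' @param frac_expression_zero fraction of expression entries set to 0
#'   (injected outside planted eQTM genes so planted correlations stay at
#'   their targets).
#' @param frac_all_zero_genes fraction of genes made all-zero, to exercise
#'   the zero-gene filter.
#' @param frac_probe_na fraction of beta entries set NA.
#' @param frac_all_na_probes fraction of probes made all-NA in both
#'   conditions, to exercise the all-NA probe filter.
#' @param n_prognostic number of planted prognostic probes (chosen among
#'   eQTM-coupled DMS probes so they survive into the network stage).
#' @param hazard_coefs log-hazard coefficient per planted prognostic probe
#'   (recycled to `n_prognostic`).  The default of 6 per unit beta comes
#'   from a power analysis: prognostic probes are DMS probes whose tumor
#'   betas sit near the unit-interval boundary (per-probe SD down to
#'   about 0.06 at concentration 20), and a median-split log-rank test
#'   with about 175 events needs a between-group log hazard ratio near
#'   0.55 -- i.e. a coefficient of about 6 -- to reach 90 percent power.
#' @param censor_rate fraction of tumor patients censored.
#' @param frac_shared for two-subtype studies, fraction of subtype A's
#'   planted DMS set re-used in subtype B (common signal).
#' @param chrom_length optional chromosome length in bp; `NULL` sizes the
#'   chromosome automatically.  Supplying a length too short to hold the
#'   requested non-overlapping genes is an error.
#' @param baseline_median_days median survival (days) of a baseline
#'   patient in the exponential survival model.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_tumor = 100L, n_normal = 100L,
                       n_genes = 120L, fraction_lincRNA = 0.5,
                       n_probes_per_gene = c(1L, 4L),
                       n_intergenic_probes = 60L,
                       dms_effect = 0.4, frac_dms = 0.25,
                       coupling_normal = 0.8, coupling_tumor = 0,
                       frac_eqtm = 0.5, noise_sd = 1,
                       meth_concentration = 20,
                       frac_expression_zero = 0.02,
                       frac_all_zero_genes = 0.05,
                       frac_probe_na = 0.02,
                       frac_all_na_probes = 0.02,
                       n_prognostic = 2L, hazard_coefs = 6,
                       censor_rate = 0.3, frac_shared = 0.5,
                       chrom_length = NULL,
                       baseline_median_days = 730) {
  cfg <- list(
    seed = as.integer(seed),
    n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
    n_genes = as.integer(n_genes), fraction_lincRNA = fraction_lincRNA,
    n_probes_per_gene = as.integer(n_probes_per_gene),
    n_intergenic_probes = as.integer(n_intergenic_probes),
    dms_effect = dms_effect, frac_dms = frac_dms,
    coupling_normal = coupling_normal, coupling_tumor = coupling_tumor,
    frac_eqtm = frac_eqtm, noise_sd = noise_sd,
    meth_concentration = meth_concentration,
    frac_expression_zero = frac_expression_zero,
    frac_all_zero_genes = frac_all_zero_genes,
    frac_probe_na = frac_probe_na,
    frac_all_na_probes = frac_all_na_probes,
    n_prognostic = as.integer(n_prognostic),
    hazard_coefs = rep_len(hazard_coefs, max(1L, as.integer(n_prognostic))),
    censor_rate = censor_rate, frac_shared = frac_shared,
    chrom_length = chrom_length,
    baseline_median_days = baseline_median_days
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  fracs <- c("fraction_lincRNA", "frac_dms", "frac_eqtm",
             "frac_expression_zero", "frac_all_zero_genes",
             "frac_probe_na", "frac_all_na_probes", "censor_rate",
             "frac_shared")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("sim_config: `", f, "` must be a single value in [0, 1]",
           call. = FALSE)
  }
  counts <- c("n_tumor", "n_normal", "n_genes")
  for (f in counts) {
    if (cfg[[f]] < 1L)
      stop("sim_config: `", f, "` must be a positive count", call. = FALSE)
  }
  if (cfg$n_intergenic_probes < 0L || cfg$n_prognostic < 0L)
    stop("sim_config: probe and prognostic counts must be non-negative",
         call. = FALSE)
  rng <- cfg$n_probes_per_gene
  if (length(rng) == 1L) rng <- c(rng, rng)
  if (length(rng) != 2L || any(rng < 1L) || rng[1] > rng[2])
    stop("sim_config: `n_probes_per_gene` must be a positive c(min, max)",
         call. = FALSE)
  if (cfg$dms_effect <= 0 || cfg$dms_effect >= 0.9)
    stop("sim_config: `dms_effect` must lie in (0, 0.9) so both group ",
         "means fit inside (0, 1)", call. = FALSE)
  for (f in c("coupling_normal", "coupling_tumor")) {
    if (abs(cfg[[f]]) > 1)
      stop("sim_config: `", f, "` is a target correlation and must lie in ",
           "[-1, 1]", call. = FALSE)
  }
  if (cfg$noise_sd <= 0 || cfg$meth_concentration <= 0 ||
      cfg$baseline_median_days <= 0)
    stop("sim_config: scale parameters must be positive", call. = FALSE)
  invisible(cfg)
}

#' Decision thresholds for the lnc-eQTM pipeline
#'
#' @param fdr_alpha Benjamini-Hochberg FDR cut-off for DMS calling
#'   (strict `<`).
#' @param delta_beta minimum absolute difference in mean beta between
#'   conditions for a DMS (strict `>`).
#' @param delta_pcc minimum absolute difference in Pearson correlation
#'   between conditions for an eQTM edge (strict `>`).
#' @param survival_alpha log-rank significance level for prognostic models
#'   (strict `<`).
#' @param min_pairs minimum complete (both non-NA) observation pairs for a
#'   correlation to be computed.
#' @param var_equal use the pooled-variance Student t-test (`TRUE`,
#'   default) or Welch's unequal-variance variant.
#' @param sign_mode how an edge's sign class is assigned: `"tumor"` (sign
#'   of the tumor-condition correlation, default), `"normal"`, or
#'   `"strongest"` (sign of whichever condition has the larger absolute
#'   correlation).
#'
#' @return an object of class `eqtm_thresholds`.
#' @export
eqtm_thresholds <- function(fdr_alpha = 0.05, delta_beta = 0.3,
                            delta_pcc = 0.3, survival_alpha = 0.05,
                            min_pairs = 10L, var_equal = TRUE,
                            sign_mode = c("tumor", "normal", "strongest")) {
  sign_mode <- match.arg(sign_mode)
  for (f in list(fdr_alpha = fdr_alpha, delta_beta = delta_beta,
                 delta_pcc = delta_pcc, survival_alpha = survival_alpha)) {
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f > 1)
      stop("eqtm_thresholds: thresholds must lie in (0, 1]", call. = FALSE)
  }
  min_pairs <- as.integer(min_pairs)
  if (min_pairs < 3L)
    stop("eqtm_thresholds: `min_pairs` must be at least 3", call. = FALSE)
  structure(list(fdr_alpha = fdr_alpha, delta_beta = delta_beta,
                 delta_pcc = delta_pcc, survival_alpha = survival_alpha,
                 min_pairs = min_pairs, var_equal = var_equal,
                 sign_mode = sign_mode),
            class = "eqtm_thresholds")
}

# Derive a per-kind RNG seed from the master seed.  One stream per file
# kind (and per subtype) means e.g. adding probes does not perturb the
# expression draws.  Kept below 2^31 - 1.
stream_seed <- function(seed, kind, subtype_index = 1L) {
  kinds <- c(annotation = 1L, planting = 2L, methylation = 3L,
             expression = 4L, clinical = 5L)
  k <- kinds[[kind]]
  (as.integer(seed) * 101L + subtype_index * 11L + k) %% .Machine$integer.max
}
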