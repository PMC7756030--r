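#' Skip sentinel for per-model failures
#'
#' Model-level stages (Cox fit, median split, log-rank) return a skip
#' sentinel instead of raising when a single model cannot be completed;
#' the screen logs the reason and moves on.
#'
#' @param reason human-readable reason.
#' @export
skipped_model <- function(reason) {
  structure(list(), class = "lnceqtm_skip", reason = reason)
}

#' @rdname skipped_model
#' @param x object to test.
#' @export
is_skipped <- function(x) inherits(x, "lnceqtm_skip")

#' @rdname skipped_model
#' @export
skip_reason <- function(x) attr(x, "reason")

#' Multivariate Cox fit over a gene's DMS methylation levels
#'
#' Fits a Cox proportional-hazards model of survival on the beta values
#' of the given probes, over the patients shared by the tumor matrix and
#' the clinical table with observed betas on every probe.  Ties use the
#' Efron approximation; up to 100 Newton iterations at tolerance 1e-9.
#'
#' @param beta_tumor tumor beta matrix (probes x samples).
#' @param probe_ids probes entering the model.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @return list with `coefs` (named per-probe coefficients), `fit`, and
#'   `patients` used; or a skip sentinel (test with [is_skipped()],
#'   reason via [skip_reason()]) when the model cannot be fitted (no
#'   patients/events, collinearity, or non-convergence).
#' @export
fit_cox <- function(beta_tumor, probe_ids, clinical) {
  stopifnot(length(probe_ids) >= 1L)
  missing_probes <- setdiff(probe_ids, rownames(beta_tumor))
  if (length(missing_probes))
    stop("fit_cox: probes absent from beta matrix: ",
         paste(missing_probes, collapse = ", "), call. = FALSE)
  patients <- intersect(colnames(beta_tumor), clinical$sample_id)
  X <- t(beta_tumor[probe_ids, patients, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  patients <- patients[ok]
  skip <- skipped_model
  if (length(patients) <= length(probe_ids) + 1L)
    return(skip("too few patients with complete betas"))
  cl <- clinical[match(patients, clinical$sample_id), ]
  if (sum(cl$event) < 1L) return(skip("no observed events"))
  dat <- data.frame(time = cl$time, event = cl$event, X,
                    check.names = FALSE)
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ ., data = dat, ties = "efron",
      control = survival::coxph.control(iter.max = 100, eps = 1e-9))),
    error = function(e) skip(conditionMessage(e)))
  if (is_skipped(fit)) return(fit)
  co <- stats::coef(fit)
  if (anyNA(co)) return(skip("collinear covariates"))
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " ")))
    return(skip("non-convergence"))
  names(co) <- probe_ids
  list(coefs = co, fit = fit, patients = patients)
}

#' Integrated methylation risk score
#'
#' The per-patient linear combination `sum_i cox_i * meth_i` of DMS beta
#' values weighted by the multivariate Cox coefficients.
#'
#' @param cox_coefs named coefficients (names = probe ids).
#' @param beta_tumor tumor beta matrix.
#' @param patients samples to score; defaults to all columns.  Patients
#'   with a missing beta on any scored probe are excluded.
#' @return named numeric vector of risk scores.
#' @export
risk_score <- function(cox_coefs, beta_tumor,
                       patients = colnames(beta_tumor)) {
  probes <- names(cox_coefs)
  stopifnot(!is.null(probes), all(probes %in% rownames(beta_tumor)))
  X <- t(beta_tumor[probes, patients, drop = FALSE])
  ok <- stats::complete.cases(X)
  scores <- drop(X[ok, , drop = FALSE] %*% cox_coefs)
  names(scores) <- patients[ok]
  scores
}

#' Median split of risk scores into high/low groups
#'
#' Scores strictly above the median go to `high`; scores at or below the
#' median go to `low` (ties assigned to the low-risk group,
#' deterministically).
#'
#' @param scores named risk scores for at least 4 patients.
#' @return named character vector ("high"/"low"), or a skip sentinel
#'   (see [is_skipped()]) when all scores are identical (no split
#'   exists).
#' @export
median_split <- function(scores) {
  if (length(scores) < 4L)
    stop("median_split: at least 4 scored patients required",
         call. = FALSE)
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", "low")
  if (length(unique(grp)) < 2L)
    return(skipped_model("degenerate split (constant scores)"))
  names(grp) <- names(scores)
  grp
}

#' Log-rank test and Kaplan-Meier curves for two risk groups
#'
#' @param groups named "high"/"low" labels per patient.
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @return list with `logrank_p` (chi-square p on 1 df), `chisq`, and
#'   `km` (per-group product-limit curve points: time, n.risk, surv).
#'   Returns a skip sentinel (see [is_skipped()]) when neither group
#'   has an observed event.
#' @export
logrank_and_km <- function(groups, clinical) {
  cl <- clinical[match(names(groups), clinical$sample_id), ]
  if (anyNA(cl$sample_id))
    stop("logrank_and_km: grouped patients missing from clinical table",
         call. = FALSE)
  if (sum(cl$event) == 0L)
    return(skipped_model("no observed events in either group"))
  dat <- data.frame(time = cl$time, event = cl$event,
                    group = unname(groups))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = dat)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  km <- data.frame(
    group = rep(sub("^group=", "", names(sf$strata)), sf$strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, stringsAsFactors = FALSE)
  list(logrank_p = p, chisq = sd_$chisq, km = km)
}

#' Screen every network lncRNA for prognostic value
#'
#' For each lncRNA node, its network-adjacent DMS probes form the
#' covariates of a multivariate Cox model; patients are scored with the
#' integrated risk score, median-split, and the two groups compared by
#' log-rank.  Models are flagged significant at raw
#' `logrank_p < survival_alpha` (no cross-model correction, matching the
#' screening design); a BH-adjusted column is emitted alongside for
#' transparency.  Per-model failures are logged, not fatal.
#'
#' @param net an `eqtm_network`.
#' @param beta_tumor tumor beta matrix.
#' @param clinical clinical data.frame.
#' @param thresholds an [eqtm_thresholds()] object.
#' @return list with `models` (data.frame ranked by p: gene, probes,
#'   coefficients, n patients, logrank_p, fdr_q, significant), `fits`
#'   (per-gene detail incl. scores, groups and KM curves) and `skipped`
#'   (gene, reason).
#' @export
screen_prognostic <- function(net, beta_tumor, clinical,
                              thresholds = eqtm_thresholds()) {
  genes <- net$lncRNA_nodes
  rows <- list(); fits <- list(); skipped <- list()
  for (g in genes) {
    probes <- unique(net$edges$probe_id[net$edges$gene_id == g])
    res <- screen_one_gene(g, probes, beta_tumor, clinical)
    if (is.character(res)) {
      skipped[[g]] <- data.frame(gene_id = g, reason = res,
                                 stringsAsFactors = FALSE)
    } else {
      rows[[g]] <- res$row
      fits[[g]] <- res$detail
    }
  }
  models <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), probes = character(),
               coefs = character(), n_probes = integer(),
               n_patients = integer(), logrank_p = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(models)) {
    models$fdr_q <- stats::p.adjust(models$logrank_p, method = "BH")
    models$significant <- models$logrank_p < thresholds$survival_alpha
    models <- models[order(models$logrank_p), ]
    rownames(models) <- NULL
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(skipped) <- NULL
  list(models = models, fits = fits, skipped = skipped)
}

screen_one_gene <- function(gene_id, probes, beta_tumor, clinical) {
  cox <- fit_cox(beta_tumor, probes, clinical)
  if (is_skipped(cox)) return(skip_reason(cox))
  scores <- risk_score(cox$coefs, beta_tumor, cox$patients)
  if (length(scores) < 4L) return("fewer than 4 scored patients")
  grp <- median_split(scores)
  if (is_skipped(grp)) return(skip_reason(grp))
  lr <- logrank_and_km(grp, clinical)
  if (is_skipped(lr)) return(skip_reason(lr))
  list(
    row = data.frame(
      gene_id = gene_id,
      probes = paste(probes, collapse = ","),
      coefs = paste(signif(cox$coefs, 6), collapse = ","),
      n_probes = length(probes),
      n_patients = length(scores),
      logrank_p = lr$logrank_p,
      stringsAsFactors = FALSE),
    detail = list(coefs = cox$coefs, scores = scores, groups = grp,
                  logrank_p = lr$logrank_p, km = lr$km)
  )
}
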