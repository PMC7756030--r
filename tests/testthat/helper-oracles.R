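# Independent oracles used to cross-check the implementation paths.

# O(P*G) double-loop interval intersection, inclusive boundaries.
brute_map <- function(probes, genes) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(genes))) {
      if (probes$chrom[i] == genes$chrom[j] &&
          probes$pos[i] >= genes$start[j] &&
          probes$pos[i] <= genes$end[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = probes$probe_id[i], gene_id = genes$gene_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(probe_id = character(), gene_id = character()))
  out <- do.call(rbind, rows)
  out[order(out$probe_id, out$gene_id), , drop = FALSE]
}

# Benjamini-Hochberg step-up written out literally: find the largest k
# with p_(k) <= k/m * alpha-free q-value transform via cumulative minima.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Pearson correlation straight from the covariance/sd definition.
pcc_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Two-group log-rank chi-square from the observed-vs-expected event
# counts at each distinct event time.
logrank_oracle <- function(time, event, group) {
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == levels(factor(group))[1])
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == levels(factor(group))[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
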