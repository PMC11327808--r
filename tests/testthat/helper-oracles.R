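# Independent brute-force oracles. These re-derive every quantity from
# first principles, by straight-line per-element computation, and are kept
# deliberately separate from the package's vectorised implementations.

# Benjamini-Hochberg step-up, literal definition: for the i-th smallest
# p-value, q = min over j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, ps[i:m] * m / (i:m))
  out <- numeric(m)
  out[o] <- q
  out
}

# FPKM, element by element from the definition.
fpkm_oracle <- function(counts, lengths) {
  out <- counts
  for (s in colnames(counts)) {
    tot <- sum(counts[, s])
    for (g in rownames(counts))
      out[g, s] <- counts[g, s] * 1e9 / (lengths[[g]] * tot)
  }
  out
}

# Hypergeometric upper tail by explicit pmf summation in log space.
phyper_oracle <- function(k, n, K, N) {
  js <- k:min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# Bray-Curtis from the definition.
bray_oracle <- function(u, v) sum(abs(u - v)) / sum(u + v)

# Straight-line re-implementation of the whole screen: per-gene loops,
# stats::t.test for the comparison, bh_oracle for the adjustment.
screen_oracle <- function(fpkm, design, fpkm_min = 5, alpha_p = 0.05,
                          alpha_q = 0.05, mt_min = 0.7) {
  organs <- sort(unique(design$organ))
  k <- length(organs)
  med_pos <- k %/% 2 + 1
  genes <- rownames(fpkm)
  res <- data.frame(gene_id = genes, max_organ = "", median_organ = "",
                    max_mean = NA_real_, total = NA_real_,
                    mt_ratio = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, status = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    means <- vapply(organs, function(o)
      mean(fpkm[g, design$sample_id[design$organ == o]]), numeric(1))
    ord <- order(-means, organs)
    res$max_organ[i] <- organs[ord[1]]
    res$median_organ[i] <- organs[ord[med_pos]]
    res$max_mean[i] <- means[ord[1]]
    res$total[i] <- sum(means)
    res$mt_ratio[i] <- if (res$total[i] > 0)
      res$max_mean[i] / res$total[i] else NA_real_
    if (res$max_mean[i] < fpkm_min) {
      res$status[i] <- "low_expression"
      next
    }
    a <- fpkm[g, design$sample_id[design$organ == res$max_organ[i]]]
    b <- fpkm[g, design$sample_id[design$organ == res$median_organ[i]]]
    res$p_value[i] <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    }
  }
  tested <- res$status != "low_expression"
  res$q_value[tested] <- bh_oracle(res$p_value[tested])
  for (i in which(tested)) {
    res$status[i] <-
      if (res$p_value[i] < alpha_p && res$q_value[i] < alpha_q &&
          res$mt_ratio[i] > mt_min) "selective"
      else if (res$p_value[i] < alpha_p) "interesting"
      else "not_significant"
  }
  res
}
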