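# Organ-selective gene screening: per gene, summarise each organ by its mean
# FPKM, locate the maximum- and median-expressing organs, compare their
# replicate values with a two-sample t-test, adjust for multiple testing,
# and gate the final call on the MT ratio (max-organ mean / summed organ
# means), the method's expression-dominance statistic.

#' Screening configuration
#'
#' @param fpkm_min Abundance floor: a gene whose maximum organ mean FPKM is
#'   strictly below this value is ignored (status `low_expression`).
#'   Default 5.
#' @param alpha_p Significance level for the max-vs-median t-test
#'   (strict `<`). Default 0.05.
#' @param alpha_q FDR level for the adjusted q-value (strict `<`).
#'   Default 0.05.
#' @param mt_min Dominance threshold: a selective gene's MT ratio must
#'   strictly exceed this value. Default 0.7.
#' @param test_flavor `"student"` (pooled variance, the default) or
#'   `"welch"`.
#' @param tails `"two_sided"` (default) or `"one_sided"` (max > median).
#' @param fdr_method `"bh"` (Benjamini-Hochberg, default) or `"storey"`.
#' @param filter_basis `"organ_mean"` (default: the abundance floor applies
#'   to the maximum organ *mean*) or `"sample_max"` (applies to the maximum
#'   single replicate value).
#' @param interesting_requires_q If `TRUE`, the `interesting` status (the
#'   enrichment foreground) additionally requires `q < alpha_q`; the
#'   default `FALSE` gates on the p-value only.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(fpkm_min = 5, alpha_p = 0.05, alpha_q = 0.05,
                          mt_min = 0.7,
                          test_flavor = c("student", "welch"),
                          tails = c("two_sided", "one_sided"),
                          fdr_method = c("bh", "storey"),
                          filter_basis = c("organ_mean", "sample_max"),
                          interesting_requires_q = FALSE) {
  if (!is.numeric(fpkm_min) || fpkm_min < 0)
    stop("`fpkm_min` must be >= 0")
  for (nm in c("alpha_p", "alpha_q")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("`", nm, "` must lie in (0, 1)")
  }
  if (!is.numeric(mt_min) || mt_min <= 0 || mt_min >= 1)
    stop("`mt_min` must lie in (0, 1)")
  structure(list(fpkm_min = fpkm_min, alpha_p = alpha_p, alpha_q = alpha_q,
                 mt_min = mt_min, test_flavor = match.arg(test_flavor),
                 tails = match.arg(tails),
                 fdr_method = match.arg(fdr_method),
                 filter_basis = match.arg(filter_basis),
                 interesting_requires_q = isTRUE(interesting_requires_q)),
            class = "screen_config")
}

#' Per-organ mean expression
#'
#' Averages each gene's FPKM over the replicates of every organ.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param design Study design mapping samples to organs.
#' @return Numeric matrix, genes x organs (organ columns in ascending code
#'   order), of arithmetic replicate means.
#' @export
organ_means <- function(matrix, design) {
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  organs <- sort(unique(design$organ))
  if (any(table(design$organ) < 1L)) stop("organ without samples")
  out <- base::matrix(NA_real_, nrow(matrix), length(organs),
                      dimnames = list(rownames(matrix), organs))
  for (o in organs)
    out[, o] <- rowMeans(matrix[, design$organ == o, drop = FALSE])
  out
}

#' Locate the maximum- and median-expressing organ
#'
#' Given one gene's per-organ means, returns the organ with the largest
#' mean and the organ holding the median of the K means: the
#' `floor(K/2) + 1`-th largest, i.e. the 6th of 11 for the 11-organ design,
#' and the lower of the two central values when K is even. Ties are broken
#' deterministically by ascending organ code; a tie between the max and
#' median *values* is flagged.
#'
#' @param means Named numeric vector of per-organ means (>= 3 organs).
#' @return List with `max_organ`, `median_organ`, and logical `tie`.
#' @export
rank_organs <- function(means) {
  k <- length(means)
  if (k < 3L) stop("rank_organs needs >= 3 organs, got ", k)
  if (is.null(names(means)) || any(!nzchar(names(means))))
    stop("`means` must be named by organ code")
  ord <- order(-means, names(means))
  med_pos <- k %/% 2L + 1L
  list(max_organ = names(means)[ord[1L]],
       median_organ = names(means)[ord[med_pos]],
       tie = means[ord[1L]] == means[ord[med_pos]])
}

#' Two-sample t-test p-value for the max-vs-median comparison
#'
#' Pooled-variance Student t-test by default (df = na + nb - 2); Welch
#' available. When both groups are constant the test statistic is
#' undefined; the contract is p = 1 if the group means are equal and p = 0
#' otherwise, which is the limiting behaviour as the common variance
#' shrinks to zero.
#'
#' @param a,b Numeric vectors of replicate values (each length >= 2).
#' @param test_flavor `"student"` or `"welch"`.
#' @param tails `"two_sided"` or `"one_sided"` (tests mean(a) > mean(b)).
#' @return A p-value.
#' @export
two_sample_pvalue <- function(a, b, test_flavor = c("student", "welch"),
                              tails = c("two_sided", "one_sided")) {
  test_flavor <- match.arg(test_flavor)
  tails <- match.arg(tails)
  if (length(a) < 2L || length(b) < 2L)
    stop("both groups need >= 2 replicates")
  stat <- t_statistic(mean(a), mean(b), stats::var(a), stats::var(b),
                      length(a), length(b), test_flavor)
  p_from_t(stat$t, stat$df, mean(a), mean(b), tails)
}

# Pooled (Student) or Welch t statistic and df from group summaries.
# Vectorised over genes; returns NaN t where the variance term is zero.
t_statistic <- function(ma, mb, va, vb, na, nb, flavor) {
  if (flavor == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = (ma - mb) / se, df = df)
}

# p-values from t, honouring the zero-variance contract. Vectorised.
p_from_t <- function(t, df, ma, mb, tails) {
  p <- if (tails == "two_sided") 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  degen <- !is.finite(t)
  if (any(degen)) p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  pmin(p, 1)
}

#' FDR-adjusted q-values
#'
#' `"bh"` is the Benjamini-Hochberg step-up: q for the i-th smallest
#' p-value is `min_{j >= i} p_(j) * m / j`, capped at 1, mapped back to the
#' input order. `"storey"` scales the BH step-up by an estimate of the null
#' proportion pi0, obtained on the lambda grid 0.05, 0.10, ..., 0.95 as
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)`, smoothed with a
#' df = 3 spline and read off at the largest lambda (falling back to the
#' grid mean when too few p-values support the spline).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"storey"`.
#' @return q-values in the input order.
#' @export
fdr_qvalues <- function(p, method = c("bh", "storey")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey" && length(p)) {
    lambda <- seq(0.05, 0.95, by = 0.05)
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    pi0 <- tryCatch(
      stats::predict(stats::smooth.spline(lambda, pi0_l, df = 3),
                     x = max(lambda))$y,
      error = function(e) mean(pi0_l))
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
    q <- pmin(q * pi0, 1)
  }
  q
}

#' MT ratio: the expression-dominance statistic
#'
#' The mean FPKM of a gene in its highest-expressing organ ("max mean")
#' divided by the sum of its mean FPKM over all organs ("Total"). Values
#' near 1 mean the gene's abundance is concentrated in a single organ; a
#' uniformly expressed gene scores 1/K for K organs.
#'
#' @param max_mean Mean FPKM in the maximum organ.
#' @param total Sum of the per-organ mean FPKMs; must be positive and at
#'   least `max_mean`.
#' @return `max_mean / total`, in (0, 1].
#' @examples
#' mt_ratio(469.5, 473.5)   # 0.992 to 3 decimals
#' mt_ratio(51493.4, 56686.5)  # 0.908
#' @export
mt_ratio <- function(max_mean, total) {
  if (any(total <= 0)) stop("`total` must be positive")
  if (any(max_mean > total)) stop("`max_mean` cannot exceed `total`")
  max_mean / total
}

#' Screen a study for organ-selective genes
#'
#' Runs the full per-gene procedure on an FPKM matrix:
#' \enumerate{
#'   \item average replicates into per-organ means;
#'   \item drop genes whose maximum organ mean is below `fpkm_min`
#'     (status `low_expression`; no test is run);
#'   \item for each remaining gene, compare the replicate FPKMs of the
#'     maximum- and median-expressing organs with a two-sample t-test;
#'   \item adjust the p-values over all tested genes jointly
#'     (`fdr_qvalues`);
#'   \item compute the MT ratio, and call the gene `selective` when
#'     p < `alpha_p`, q < `alpha_q` and MT ratio > `mt_min`;
#'     `interesting` when p < `alpha_p` only.
#' }
#'
#' @param matrix FPKM expression matrix.
#' @param design Study design (>= 3 organs, >= 2 replicates each).
#' @param config A [screen_config()].
#' @return A data.frame with one row per gene: `gene_id`, `max_organ`,
#'   `median_organ`, `max_mean`, `total`, `mt_ratio`, `p_value`, `q_value`,
#'   `status` (factor: low_expression, not_significant, interesting,
#'   selective) and `tie`. Low-expression genes carry NA p and q.
#' @export
screen <- function(matrix, design, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  design <- validate_design(matrix, design)
  means <- organ_means(matrix, design)
  organs <- colnames(means)
  k <- length(organs)
  med_pos <- k %/% 2L + 1L

  # per-gene descending order of organ means, ties by organ code (columns
  # are already in ascending code order, so order() tie-breaks correctly)
  ord <- t(apply(means, 1L, order, decreasing = TRUE))
  idx_max <- ord[, 1L]
  idx_med <- ord[, med_pos]
  n_genes <- nrow(means)
  rows <- seq_len(n_genes)
  max_mean <- means[cbind(rows, idx_max)]
  med_mean <- means[cbind(rows, idx_med)]
  total <- rowSums(means)
  mt <- ifelse(total > 0, max_mean / total, NA_real_)

  tested <- if (config$filter_basis == "organ_mean") {
    max_mean >= config$fpkm_min
  } else {
    apply(matrix, 1L, max) >= config$fpkm_min
  }

  p <- q <- rep(NA_real_, n_genes)
  if (any(tested)) {
    sample_organ <- design$organ[match(colnames(matrix), design$sample_id)]
    gm <- gv <- gn <- base::matrix(NA_real_, n_genes, k,
                                   dimnames = list(NULL, organs))
    for (j in seq_len(k)) {
      sub <- matrix[, sample_organ == organs[j], drop = FALSE]
      gm[, j] <- rowMeans(sub)
      gv[, j] <- apply(sub, 1L, stats::var)
      gn[, j] <- ncol(sub)
    }
    ti <- which(tested)
    st <- t_statistic(gm[cbind(ti, idx_max[ti])], gm[cbind(ti, idx_med[ti])],
                      gv[cbind(ti, idx_max[ti])], gv[cbind(ti, idx_med[ti])],
                      gn[cbind(ti, idx_max[ti])], gn[cbind(ti, idx_med[ti])],
                      config$test_flavor)
    p[ti] <- p_from_t(st$t, st$df,
                      gm[cbind(ti, idx_max[ti])], gm[cbind(ti, idx_med[ti])],
                      config$tails)
    q[ti] <- fdr_qvalues(p[ti], config$fdr_method)
  }

  status <- rep("not_significant", n_genes)
  status[!tested] <- "low_expression"
  is_int <- tested & p < config$alpha_p &
    (!config$interesting_requires_q | q < config$alpha_q)
  status[which(is_int)] <- "interesting"
  is_sel <- tested & p < config$alpha_p & q < config$alpha_q &
    !is.na(mt) & mt > config$mt_min
  status[which(is_sel & is_int)] <- "selective"

  data.frame(
    gene_id = rownames(means),
    max_organ = organs[idx_max],
    median_organ = organs[idx_med],
    max_mean = max_mean,
    total = total,
    mt_ratio = mt,
    p_value = p,
    q_value = q,
    status = factor(status, levels = c("low_expression", "not_significant",
                                       "interesting", "selective")),
    tie = max_mean == med_mean,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-organ interesting-gene lists
#'
#' Partitions the interesting (and selective) genes by their maximum organ;
#' the per-organ lists are the enrichment foregrounds.
#'
#' @param records Screen output from [screen()].
#' @return Named list: organ code -> character vector of gene ids.
#' @export
interesting_sets <- function(records) {
  keep <- records$status %in% c("interesting", "selective")
  split(records$gene_id[keep], records$max_organ[keep])
}
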