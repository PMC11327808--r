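# Synthetic multi-organ expression studies with planted organ-selective
# genes, so every downstream stage can be validated against known truth.

#' Simulation configuration
#'
#' Describes a replicated multi-organ FPKM study. Genes fall into three
#' disjoint classes: *selective* genes whose target organ holds a share
#' `dominance` of the gene's total mean abundance (the remaining share is
#' split uniformly over the other organs), *low-expressed* genes whose
#' per-organ means all sit below the abundance floor, and ordinary genes
#' with equal means in every organ. Replicate values are the true organ
#' mean times multiplicative log-normal noise with unit mean and
#' coefficient of variation `noise_cv` (`sigma^2 = log(1 + cv^2)`), which
#' keeps abundances positive and mimics FPKM dispersion without a count
#' model.
#'
#' @param n_genes Number of genes.
#' @param n_organs Number of organs (default 11, labelled with the rat
#'   study codes Ad..St; other counts get codes O1..Ok, zero-padded past
#'   9 so lexicographic order matches numeric order).
#' @param n_reps Replicates per organ (default 3).
#' @param frac_selective Fraction of genes planted as organ-selective.
#' @param dominance Share d of a selective gene's summed organ means held
#'   by its target organ; must exceed `1/n_organs` (below that,
#'   "selective" is meaningless) and be at most 1.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-gene baseline per-organ mean abundance.
#' @param noise_cv Coefficient of variation of the replicate noise (>= 0).
#' @param frac_low_expressed Fraction of genes forced below the abundance
#'   floor. `frac_selective + frac_low_expressed` must not exceed 1.
#' @param abundance_floor The screening floor the low-expressed class is
#'   pushed under (and expressed classes kept clear of); default 5.
#' @param count_mode If `TRUE`, additionally emit negative-binomial
#'   fragment counts with gene lengths and library sizes, so FPKM
#'   computation can be round-trip tested.
#' @param dispersion Negative-binomial dispersion for count mode
#'   (`variance = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param seed Integer seed; identical configs give bit-identical studies.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_organs = 11L, n_reps = 3L,
                       frac_selective = 0.1, dominance = 0.9,
                       baseline_log_mean = 3, baseline_log_sd = 1,
                       noise_cv = 0.1, frac_low_expressed = 0.1,
                       abundance_floor = 5, count_mode = FALSE,
                       dispersion = 0.05, seed = 1L) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != as.integer(x))
      stop("`", nm, "` must be a positive integer")
  }
  chk_count(n_genes, "n_genes")
  chk_count(n_organs, "n_organs")
  chk_count(n_reps, "n_reps")
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || is.na(x) || x < 0 || x > 1)
      stop("`", nm, "` must lie in [0, 1]")
  }
  chk_frac(frac_selective, "frac_selective")
  chk_frac(frac_low_expressed, "frac_low_expressed")
  if (frac_selective + frac_low_expressed > 1)
    stop("`frac_selective` + `frac_low_expressed` must not exceed 1")
  if (!is.numeric(dominance) || dominance <= 1 / n_organs || dominance > 1)
    stop("`dominance` must lie in (1/n_organs, 1]")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("`noise_cv` must be >= 0")
  if (!is.numeric(abundance_floor) || abundance_floor < 0)
    stop("`abundance_floor` must be >= 0")
  if (!is.numeric(dispersion) || dispersion < 0)
    stop("`dispersion` must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_organs = as.integer(n_organs),
                 n_reps = as.integer(n_reps),
                 frac_selective = frac_selective, dominance = dominance,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, noise_cv = noise_cv,
                 frac_low_expressed = frac_low_expressed,
                 abundance_floor = abundance_floor,
                 count_mode = isTRUE(count_mode), dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

organ_labels <- function(k) {
  if (k == 11L) return(ORGAN_CODES_RAT)
  if (k > 9L) sprintf("O%02d", seq_len(k)) else paste0("O", seq_len(k))
}

#' Generate a synthetic multi-organ study
#'
#' Draws a replicated FPKM matrix plus its study design and per-gene
#' truth from a [sim_config()]. One seeded random stream is consumed in a
#' fixed, documented order — (1) per-gene baseline abundances, (2) class
#' assignment and target organs, (3) the replicate noise matrix, (4)
#' count-mode draws — so identical configs reproduce bit-identical
#' studies.
#'
#' Construction of the true organ means, for baseline per-organ mean b and
#' K organs (total T = K * b):
#' * selective gene: target mean `d * T`, every other organ
#'   `(1 - d) * T / (K - 1)`, so the target's share of the summed means is
#'   exactly `d` before noise;
#' * ordinary gene: all organ means equal b; baselines of expressed genes
#'   are truncated below at 1.2 x `abundance_floor` so the planted classes
#'   stay unambiguous under replicate noise;
#' * low-expressed gene: equal means squashed below the floor
#'   (`floor * b / (1 + b)`).
#'
#' @param config A [sim_config()].
#' @return List with elements `fpkm` (expression matrix), `design` (study
#'   design), `truth` (data.frame: `gene_id`, `is_selective`,
#'   `target_organ`, `dominance_used`, `expected_mt_ratio`,
#'   `is_low_expressed`) and, in count mode, `counts`, `lengths`,
#'   `lib_sizes`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  K <- cf$n_organs
  organs <- organ_labels(K)
  genes <- sprintf("gene_%05d", seq_len(cf$n_genes))
  samples <- paste(rep(organs, each = cf$n_reps),
                   rep(seq_len(cf$n_reps), K), sep = "_")
  design <- study_design(samples, rep(organs, each = cf$n_reps),
                         rep(seq_len(cf$n_reps), K))

  # (1) baselines
  b <- stats::rlnorm(cf$n_genes, cf$baseline_log_mean, cf$baseline_log_sd)
  # (2) class assignment
  n_sel <- round(cf$frac_selective * cf$n_genes)
  n_low <- round(cf$frac_low_expressed * cf$n_genes)
  perm <- sample.int(cf$n_genes)
  idx_sel <- perm[seq_len(n_sel)]
  idx_low <- perm[n_sel + seq_len(n_low)]
  target <- sample.int(K, n_sel, replace = TRUE)

  expressed <- setdiff(seq_len(cf$n_genes), idx_low)
  b[expressed] <- pmax(b[expressed], 1.2 * cf$abundance_floor)
  b[idx_low] <- cf$abundance_floor * b[idx_low] / (1 + b[idx_low])

  M <- matrix(b, cf$n_genes, K)  # true organ means; ordinary genes flat
  if (n_sel) {
    total <- K * b[idx_sel]
    M[idx_sel, ] <- (1 - cf$dominance) * total / (K - 1)
    M[cbind(idx_sel, target)] <- cf$dominance * total
  }

  # (3) replicate noise: unit-mean log-normal, CV = noise_cv
  sigma <- sqrt(log(1 + cf$noise_cv^2))
  z <- matrix(stats::rnorm(cf$n_genes * K * cf$n_reps),
              cf$n_genes, K * cf$n_reps)
  noise <- exp(sigma * z - sigma^2 / 2)
  fpkm <- M[, rep(seq_len(K), each = cf$n_reps)] * noise
  dimnames(fpkm) <- list(genes, samples)
  fpkm <- expression_matrix(fpkm, unit = "fpkm")

  truth <- data.frame(
    gene_id = genes,
    is_selective = FALSE,
    target_organ = NA_character_,
    dominance_used = NA_real_,
    expected_mt_ratio = NA_real_,
    is_low_expressed = FALSE,
    stringsAsFactors = FALSE
  )
  truth$is_selective[idx_sel] <- TRUE
  truth$target_organ[idx_sel] <- organs[target]
  truth$dominance_used[idx_sel] <- cf$dominance
  truth$expected_mt_ratio[idx_sel] <- cf$dominance
  truth$is_low_expressed[idx_low] <- TRUE

  out <- list(fpkm = fpkm, design = design, truth = truth)

  if (cf$count_mode) {
    # (4) lengths, library sizes, then NB fragment counts
    lengths <- pmax(round(stats::rlnorm(cf$n_genes, log(1500), 0.6)), 200)
    names(lengths) <- genes
    lib <- round(stats::runif(length(samples), 0.8, 1.2) * 2e7)
    mu <- fpkm * lengths * lib[col(fpkm)] / 1e9
    counts <- if (cf$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / cf$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    counts <- matrix(as.numeric(counts), nrow(fpkm), ncol(fpkm),
                     dimnames = dimnames(fpkm))
    out$counts <- expression_matrix(counts, unit = "counts")
    out$lengths <- lengths
    out$lib_sizes <- stats::setNames(lib, samples)
  }
  out
}

#' Write a simulated study to disk
#'
#' Emits `matrix.tsv`, `design.tsv` and `truth.tsv` (plus `counts.tsv` and
#' `lengths.tsv` in count mode) under `dir`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression_tsv(study$fpkm, paths[["matrix"]])
  write_design_tsv(study$design, paths[["design"]])
  utils::write.table(study$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(study$counts)) {
    paths[["counts"]] <- file.path(dir, "counts.tsv")
    write_expression_tsv(study$counts, paths[["counts"]])
    paths[["lengths"]] <- file.path(dir, "lengths.tsv")
    utils::write.table(
      data.frame(gene_id = names(study$lengths),
                 length_bp = as.integer(study$lengths)),
      paths[["lengths"]], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
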