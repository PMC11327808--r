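# Small in-code fixtures shared across tests.

# A tiny replicated study built by hand: `k` organs x `reps` replicates,
# values supplied as a genes x organs matrix of true means (replicates get
# the mean plus optional jitter).
toy_study <- function(true_means, reps = 3, jitter = 0, seed = 1) {
  set.seed(seed)
  organs <- colnames(true_means)
  samples <- paste(rep(organs, each = reps), seq_len(reps), sep = "_")
  vals <- true_means[, rep(seq_along(organs), each = reps), drop = FALSE]
  if (jitter > 0)
    vals <- vals + matrix(rnorm(length(vals), sd = jitter), nrow(vals))
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(rownames(true_means), samples)
  list(fpkm = expression_matrix(vals, "fpkm"),
       design = study_design(samples, rep(organs, each = reps),
                             rep(seq_len(reps), length(organs))))
}

random_collection <- function(n_sets, universe, min_size = 5,
                              max_size = 40) {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(min_size:max_size, 1)))
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  attr(sets, "descriptions") <-
    stats::setNames(paste("set", seq_len(n_sets)), names(sets))
  sets
}
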