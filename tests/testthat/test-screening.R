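test_that("organ means average replicates per organ", {
  tm <- matrix(c(1, 10, 4, 20, 7, 30), 2, 3,
               dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  st <- toy_study(tm, reps = 3)
  # replicates identical -> means equal true means
  expect_equal(organ_means(st$fpkm, st$design),
               tm, ignore_attr = TRUE)

  # (1,2,3) averages to 2
  m <- matrix(1:3, 1, 3, dimnames = list("g", c("A_1", "A_2", "A_3")))
  d <- study_design(colnames(m), rep("A", 3), 1:3)
  expect_equal(organ_means(expression_matrix(m * 1.0, "fpkm"), d)[1, "A"], 2)

  # random matrix against brute-force per-group averaging
  set.seed(5)
  st <- toy_study(matrix(rlnorm(50, 2, 1), 10, 5,
                         dimnames = list(paste0("g", 1:10), LETTERS[1:5])),
                  reps = 3, jitter = 1)
  got <- organ_means(st$fpkm, st$design)
  for (o in LETTERS[1:5])
    expect_equal(got[, o],
                 rowMeans(st$fpkm[, st$design$organ == o]))

  bad <- st$design[-1, ]
  expect_error(organ_means(st$fpkm, bad), "absent from design")
})

test_that("max and median organs are located with deterministic tie-breaks", {
  means <- stats::setNames(11:1, paste0("O", sprintf("%02d", 1:11)))
  r <- rank_organs(means)
  expect_identical(r$max_organ, "O01")   # largest
  expect_identical(r$median_organ, "O06")  # 6th of 11
  expect_false(r$tie)

  # all tied: resolved by ascending organ code, flagged
  tied <- stats::setNames(rep(2, 5), c("E", "D", "C", "B", "A"))
  r <- rank_organs(tied)
  expect_identical(r$max_organ, "A")
  expect_identical(r$median_organ, "C")  # 3rd of 5 by code order
  expect_true(r$tie)

  # even K: the lower of the two central values
  r <- rank_organs(c(A = 4, B = 3, C = 2, D = 1))
  expect_identical(r$median_organ, "C")

  expect_error(rank_organs(c(A = 1, B = 2)), ">= 3")

  # 500 random vectors against a brute-force sort oracle
  set.seed(6)
  codes <- c("Ad", "Br", "Co", "Du", "He", "Il", "Ki", "Li", "Lu", "Sp",
             "St")
  for (i in 1:500) {
    v <- stats::setNames(sample(1:6, 11, replace = TRUE), sample(codes))
    r <- rank_organs(v)
    o <- order(-v, names(v))
    expect_identical(r$max_organ, names(v)[o[1]])
    expect_identical(r$median_organ, names(v)[o[6]])
  }
})

test_that("max-vs-median t-test matches the closed form and its contracts", {
  expect_equal(two_sample_pvalue(c(5, 5, 5), c(5, 5, 5)), 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # pooled: sp2 = 1, se = sqrt(2/3), t = -3/se, df = 4
  t_hand <- -3 / sqrt(2 / 3)
  p_hand <- 2 * stats::pt(-abs(t_hand), 4)
  expect_equal(two_sample_pvalue(a, b), p_hand)
  expect_equal(round(t_hand, 3), -3.674)
  expect_lt(abs(p_hand - 0.021), 5e-4)
  expect_equal(two_sample_pvalue(b, a), two_sample_pvalue(a, b))

  # zero-variance contract
  expect_equal(two_sample_pvalue(c(2, 2), c(3, 3)), 0)
  expect_equal(two_sample_pvalue(c(3, 3), c(3, 3)), 1)
  expect_error(two_sample_pvalue(1, c(1, 2)), ">= 2")

  # both flavors agree with stats::t.test on random draws
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(2:5, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(2:5, 1), mean = runif(1, 0, 3))
    expect_equal(two_sample_pvalue(x, y),
                 stats::t.test(x, y, var.equal = TRUE)$p.value)
    expect_equal(two_sample_pvalue(x, y, test_flavor = "welch"),
                 stats::t.test(x, y)$p.value)
  }

  # one-sided: direction max > median
  expect_equal(two_sample_pvalue(b, a, tails = "one_sided"),
               stats::t.test(b, a, var.equal = TRUE,
                             alternative = "greater")$p.value)
})

test_that("BH q-values follow the step-up oracle; Storey shrinks them", {
  expect_equal(fdr_qvalues(0.05), 0.05)
  expect_equal(fdr_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(fdr_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:80, 1))
    q <- fdr_qvalues(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }

  p <- c(runif(300, 0, 0.01), runif(700))  # signal + uniform null
  qs <- fdr_qvalues(p, "storey")
  qb <- fdr_qvalues(p, "bh")
  expect_true(all(qs <= qb + 1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("MT ratio is max mean over total, with hand-checked values", {
  expect_equal(round(mt_ratio(469.5, 473.5), 3), 0.992)
  expect_equal(round(mt_ratio(51493.4, 56686.5), 3), 0.908)
  expect_equal(mt_ratio(100, 100), 1)  # single-organ expression
  expect_error(mt_ratio(1, 0), "positive")
  expect_error(mt_ratio(5, 4), "exceed")
})

test_that("screen applies the filter, test, FDR and MT gates end to end", {
  # planted gene, d = 1, no noise -> selective with MT exactly 1
  tm <- matrix(5.5, 5, 11, dimnames = list(paste0("g", 1:5),
                                           orgsel:::organ_labels(11)))
  tm[1, ] <- 0; tm[1, "Br"] <- 100       # fully dominant
  tm[2, ] <- 4.9                          # under the floor everywhere
  st <- toy_study(tm, reps = 3)
  rec <- screen(st$fpkm, st$design)
  expect_identical(as.character(rec$status[1]), "selective")
  expect_equal(rec$mt_ratio[1], 1)
  expect_identical(rec$max_organ[1], "Br")
  expect_identical(as.character(rec$status[2]), "low_expression")
  expect_true(is.na(rec$p_value[2]))
  # flat genes: tied means, p = 1 under the zero-variance contract
  expect_true(all(rec$tie[3:5]))
  expect_equal(rec$p_value[3:5], rep(1, 3))
})

test_that("screen statuses are monotone in the thresholds and scale invariant", {
  set.seed(9)
  st <- simulate_study(sim_config(n_genes = 400, seed = 77))
  base <- screen(st$fpkm, st$design)

  n_sel <- function(cfg) sum(screen(st$fpkm, st$design, cfg)$status ==
                               "selective")
  n0 <- n_sel(screen_config())
  expect_lte(n_sel(screen_config(mt_min = 0.8)), n0)
  expect_lte(n_sel(screen_config(fpkm_min = 50)), n0)
  expect_lte(n_sel(screen_config(alpha_p = 0.01)), n0)
  expect_lte(n_sel(screen_config(alpha_q = 0.01)), n0)

  # selective subset of interesting subset of tested; counts partition
  tab <- table(base$status)
  expect_equal(sum(tab), nrow(base))
  f <- funnel_counts(base)
  expect_equal(tab[["interesting"]] + tab[["selective"]], f[["n_p"]])
  expect_equal(f[["n_filtered"]] + tab[["low_expression"]], nrow(base))
  expect_lte(f[["n_selective"]], f[["n_q"]])
  expect_lte(f[["n_q"]], f[["n_p"]])

  # multiplying the matrix by a constant changes nothing but the means
  scaled <- screen(expression_matrix(unclass(st$fpkm)[, ] * 7.3, "fpkm"),
                   st$design, screen_config(fpkm_min = 5 * 7.3))
  expect_identical(scaled$status, base$status)
  expect_identical(scaled$max_organ, base$max_organ)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
  expect_equal(scaled$mt_ratio, base$mt_ratio, tolerance = 1e-12)
})

test_that("interesting gene lists partition genes by their max organ", {
  st <- simulate_study(sim_config(n_genes = 300, seed = 5))
  rec <- screen(st$fpkm, st$design)
  sets <- interesting_sets(rec)
  all_ids <- unlist(sets, use.names = FALSE)
  expect_false(anyDuplicated(all_ids) > 0)
  expect_setequal(all_ids,
                  rec$gene_id[rec$status %in% c("interesting", "selective")])
  for (o in names(sets))
    expect_true(all(rec$max_organ[match(sets[[o]], rec$gene_id)] == o))

  empty <- rec[0, ]
  expect_length(interesting_sets(empty), 0)
})
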