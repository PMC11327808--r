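test_that("organ tables sort, truncate and reconcile with the screen", {
  st <- simulate_study(sim_config(n_genes = 600, seed = 41))
  rec <- screen(st$fpkm, st$design)
  organs <- sort(unique(rec$max_organ))

  total_sel <- 0
  for (o in organs) {
    rep_o <- organ_table(rec, o, top_n = 20)
    rows <- rep_o$rows
    expect_lte(nrow(rows), 20)
    expect_true(all(order(rows$q_value, rows$p_value, rows$gene_id) ==
                      seq_len(nrow(rows))))
    expect_equal(rep_o$counts$n_selective,
                 sum(rec$status == "selective" & rec$max_organ == o))
    total_sel <- total_sel + rep_o$counts$n_selective
  }
  expect_equal(total_sel, sum(rec$status == "selective"))

  # ordering invariant under input shuffling
  set.seed(1)
  shuf <- rec[sample(nrow(rec)), ]
  o1 <- organ_table(rec, organs[1])
  o2 <- organ_table(shuf, organs[1])
  expect_identical(o1$rows, o2$rows)

  expect_error(organ_table(rec, "XX"), "unknown organ")
})

test_that("print formatting follows the table conventions", {
  rows <- data.frame(gene_id = "g1", median_organ = "Br",
                     max_mean = 469.4567, total = 473.512,
                     p_value = 1.018e-06, q_value = 3.2e-04,
                     mt_ratio = 0.99155)
  f <- orgsel:::format_organ_rows(rows)
  expect_identical(f$max_mean, "469.5")
  expect_identical(f$total, "473.5")
  expect_identical(f$mt_ratio, "0.992")
  expect_identical(f$p_value, "1.02e-06")
})

test_that("funnel counts recount the screen records exactly", {
  st <- simulate_study(sim_config(n_genes = 500, seed = 51))
  cfg <- screen_config()
  rec <- screen(st$fpkm, st$design, cfg)
  f <- funnel_counts(rec, cfg)
  expect_equal(f[["n_genes"]], 500)
  expect_equal(f[["n_filtered"]], sum(rec$status != "low_expression"))
  expect_equal(f[["n_p"]],
               sum(rec$p_value < cfg$alpha_p, na.rm = TRUE))
  expect_equal(f[["n_q"]],
               sum(rec$p_value < cfg$alpha_p & rec$q_value < cfg$alpha_q,
                   na.rm = TRUE))
  expect_equal(f[["n_selective"]], sum(rec$status == "selective"))
})

test_that("the pipeline writes every artifact, reproducibly", {
  cf <- sim_config(n_genes = 200, n_organs = 6, seed = 61)
  universe <- sprintf("gene_%05d", 1:200)
  set.seed(62)
  coll <- random_collection(8, universe, 10, 50)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_pipeline(sim = cf, collection = coll, out_dir = d1)
  r2 <- run_pipeline(sim = cf, collection = coll, out_dir = d2)

  expect_true(all(file.exists(file.path(d1, c("screen.tsv", "distance.tsv",
                                              "tree.newick",
                                              "run_log.txt")))))
  expect_true(any(grepl("^organ_", list.files(d1))))
  expect_true(any(grepl("^enrich_", list.files(d1))))

  # data artifacts are byte-identical across runs (log carries timestamps)
  for (f in setdiff(list.files(d1, recursive = TRUE), "run_log.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)

  # logged funnel equals an independent recount from the screen TSV
  tsv <- utils::read.delim(file.path(d1, "screen.tsv"))
  expect_equal(r1$funnel[["n_selective"]],
               sum(tsv$status == "selective"))
  expect_equal(r1$funnel[["n_filtered"]],
               sum(tsv$status != "low_expression"))
  log <- readLines(file.path(d1, "run_log.txt"))
  expect_true(any(grepl(paste0("n_selective=",
                               r1$funnel[["n_selective"]]), log)))
})

test_that("an empty selective set still yields valid empty tables", {
  # flat study: nothing passes the screen
  tm <- matrix(50, 5, 4, dimnames = list(paste0("g", 1:5), LETTERS[1:4]))
  st <- toy_study(tm, reps = 3, jitter = 0.5)
  rec <- screen(st$fpkm, st$design)
  expect_equal(sum(rec$status == "selective"), 0)
  rep_a <- organ_table(rec, rec$max_organ[1])
  expect_equal(nrow(rep_a$rows), 0)
  expect_output(print(rep_a), "no selective genes")
})
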