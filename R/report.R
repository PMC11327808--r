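# Per-organ report assembly and end-to-end pipeline orchestration.

#' Per-organ selective-gene table
#'
#' Collects the selective genes assigned to one organ, sorted by ascending
#' q-value, then p-value, then gene id, truncated to `top_n` rows, together
#' with the organ's status counts.
#'
#' @param records Screen output from [screen()].
#' @param organ Organ code; must be the max organ of at least one record.
#' @param top_n Maximum number of rows (default 20).
#' @return List of class `organ_report`: `organ`, `rows` (data.frame with
#'   gene_id, median_organ, max_mean, total, p_value, q_value, mt_ratio)
#'   and `counts` (n_selective, n_interesting, n_low_expression).
#' @export
organ_table <- function(records, organ, top_n = 20L) {
  if (!organ %in% records$max_organ)
    stop("unknown organ: ", organ)
  sel <- records[records$status == "selective" &
                   records$max_organ == organ, , drop = FALSE]
  sel <- sel[order(sel$q_value, sel$p_value, sel$gene_id), , drop = FALSE]
  sel <- utils::head(sel, top_n)
  here <- records$max_organ == organ
  structure(list(
    organ = organ,
    rows = data.frame(gene_id = sel$gene_id,
                      median_organ = sel$median_organ,
                      max_mean = sel$max_mean, total = sel$total,
                      p_value = sel$p_value, q_value = sel$q_value,
                      mt_ratio = sel$mt_ratio,
                      stringsAsFactors = FALSE, row.names = NULL),
    counts = list(
      n_selective = sum(here & records$status == "selective"),
      n_interesting = sum(here & records$status %in%
                            c("interesting", "selective")),
      n_low_expression = sum(here & records$status == "low_expression"))),
    class = "organ_report")
}

# Print-style formatting: means/totals to 1 decimal, MT ratio to 3
# decimals, p/q in scientific notation with 3 significant digits.
format_organ_rows <- function(rows) {
  data.frame(gene_id = rows$gene_id,
             median_organ = rows$median_organ,
             max_mean = sprintf("%.1f", rows$max_mean),
             total = sprintf("%.1f", rows$total),
             p_value = sprintf("%.2e", rows$p_value),
             q_value = sprintf("%.2e", rows$q_value),
             mt_ratio = sprintf("%.3f", rows$mt_ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.organ_report <- function(x, ...) {
  cat("Organ", x$organ, "-", x$counts$n_selective, "selective,",
      x$counts$n_interesting, "interesting,",
      x$counts$n_low_expression, "low-expression genes\n")
  if (nrow(x$rows)) print(format_organ_rows(x$rows)) else
    cat("(no selective genes)\n")
  invisible(x)
}

#' Filter-funnel counts of a screen
#'
#' The stagewise gene counts of the screening funnel: all genes, genes
#' passing the abundance filter, of those the genes with p below
#' `alpha_p`, of those additionally q below `alpha_q`, and finally the
#' selective genes (MT ratio gate applied).
#'
#' @param records Screen output from [screen()].
#' @param config The [screen_config()] used.
#' @return Named integer vector: `n_genes`, `n_filtered`, `n_p`, `n_q`,
#'   `n_selective`.
#' @export
funnel_counts <- function(records, config = screen_config()) {
  tested <- records$status != "low_expression"
  p_ok <- tested & !is.na(records$p_value) &
    records$p_value < config$alpha_p
  q_ok <- p_ok & !is.na(records$q_value) &
    records$q_value < config$alpha_q
  c(n_genes = nrow(records),
    n_filtered = sum(tested),
    n_p = sum(p_ok),
    n_q = sum(q_ok),
    n_selective = sum(records$status == "selective"))
}

#' Run the full pipeline on a simulated or supplied study
#'
#' Orchestrates simulate (optional) -> screen -> organ clustering ->
#' per-organ tables -> enrichment (optional) and writes every artifact to
#' `out_dir`: `screen.tsv`, `organ_<code>.tsv` per organ,
#' `distance.tsv`, `tree.newick`, `enrich_<code>.tsv` when a collection is
#' given, the simulated study files, and a line-oriented `run_log.txt`
#' recording configuration, versions and the filter-funnel counts.
#'
#' @param sim A [sim_config()] to simulate from, or `NULL` when `study`
#'   is supplied.
#' @param study A list with `fpkm` and `design` (as from
#'   [simulate_study()]); ignored when `sim` is given.
#' @param config A [screen_config()].
#' @param collection Optional gene-set collection for per-organ
#'   over-representation analysis.
#' @param out_dir Output directory.
#' @param top_n Rows per organ table.
#' @param linkage Clustering linkage (see [hcluster()]).
#' @return Invisibly, a list with `records`, `funnel`, `dist`, `tree`,
#'   `reports`, `enrichments` and `paths`.
#' @export
run_pipeline <- function(sim = NULL, study = NULL,
                         config = screen_config(), collection = NULL,
                         out_dir, top_n = 20L, linkage = "average") {
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines,
                    paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ",
                           paste0(...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say("orgsel ", as.character(utils::packageVersion("orgsel")),
      " on R ", getRversion())

  if (!is.null(sim)) {
    say("simulate: n_genes=", sim$n_genes, " n_organs=", sim$n_organs,
        " n_reps=", sim$n_reps, " dominance=", sim$dominance,
        " noise_cv=", sim$noise_cv, " seed=", sim$seed)
    study <- stage("simulate", simulate_study(sim))
    stage("simulate", write_study(study, file.path(out_dir, "study")))
  }
  if (is.null(study)) stop("supply either `sim` or `study`")

  say("screen: fpkm_min=", config$fpkm_min, " alpha_p=", config$alpha_p,
      " alpha_q=", config$alpha_q, " mt_min=", config$mt_min,
      " test=", config$test_flavor, " fdr=", config$fdr_method)
  records <- stage("screen", screen(study$fpkm, study$design, config))
  screen_path <- file.path(out_dir, "screen.tsv")
  utils::write.table(records, screen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  funnel <- funnel_counts(records, config)
  say("funnel: ", paste(names(funnel), funnel, sep = "=", collapse = " "))

  means <- stage("cluster", organ_means(study$fpkm, study$design))
  dmat <- stage("cluster", distance_matrix(means))
  utils::write.table(data.frame(organ = rownames(dmat), dmat,
                                check.names = FALSE),
                     file.path(out_dir, "distance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tree <- stage("cluster", hcluster(dmat, linkage))
  writeLines(to_newick(tree), file.path(out_dir, "tree.newick"))

  organs <- sort(unique(records$max_organ))
  reports <- lapply(organs, function(o)
    stage("report", organ_table(records, o, top_n)))
  names(reports) <- organs
  for (o in organs)
    utils::write.table(format_organ_rows(reports[[o]]$rows),
                       file.path(out_dir, paste0("organ_", o, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  say("report: ", length(organs), " organ tables, top_n=", top_n)

  enrichments <- NULL
  if (!is.null(collection)) {
    fg <- interesting_sets(records)
    background <- records$gene_id[records$status != "low_expression"]
    enrichments <- lapply(names(fg), function(o)
      stage("enrich", enrich(fg[[o]], collection, background)))
    names(enrichments) <- names(fg)
    for (o in names(enrichments)) {
      e <- enrichments[[o]]
      out <- data.frame(set_id = e$set_id,
                        significant = paste0(e$k, "/", e$n),
                        annotated = paste0(e$K, "/", e$N),
                        p_value = sprintf("%.2e", e$p_value),
                        q_value = sprintf("%.2e", e$q_value),
                        stringsAsFactors = FALSE)
      utils::write.table(out,
                         file.path(out_dir, paste0("enrich_", o, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    say("enrich: ", length(enrichments), " organ foregrounds against ",
        length(collection), " sets")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(records = records, funnel = funnel, dist = dmat,
                 tree = tree, reports = reports,
                 enrichments = enrichments, out_dir = out_dir))
}
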