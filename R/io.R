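# Expression matrices, study designs and gene-set collections: constructors,
# validation, TSV/GMT readers and writers, and FPKM computation.

ORGAN_CODES_RAT <- c("Ad", "Br", "Co", "Du", "He", "Il", "Ki", "Li", "Lu",
                     "Sp", "St")

#' Construct an expression matrix
#'
#' An expression matrix is a numeric gene x sample matrix with unique row
#' (gene) and column (sample) names, no negative values, and a unit tag
#' recording whether the values are raw fragment counts or FPKM.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty dimnames.
#' @param unit `"fpkm"` or `"counts"`.
#' @return The validated matrix with a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "counts")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values")
  if (any(values < 0))
    stop("expression matrix contains negative values")
  attr(values, "unit") <- unit
  values
}

#' @rdname expression_matrix
#' @param x Object to query.
#' @export
expression_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "fpkm" else u
}

#' Construct a study design
#'
#' Maps each sample to an organ code and a replicate index. Screening needs
#' at least 3 organs (so a median organ exists) and at least 2 replicates per
#' organ (so a two-sample t-test is defined).
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param organ Character vector of organ codes, parallel to `sample_id`.
#' @param replicate Positive integer replicate index within organ.
#' @return A data.frame with columns `sample_id`, `organ`, `replicate`.
#' @export
study_design <- function(sample_id, organ, replicate) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in design")
  if (any(!nzchar(organ)))
    stop("empty organ code in design")
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate indices must be positive integers")
  data.frame(sample_id = as.character(sample_id),
             organ = as.character(organ),
             replicate = replicate,
             stringsAsFactors = FALSE)
}

# Check matrix/design consistency and the minimum group sizes screening needs.
validate_design <- function(matrix, design, min_reps = 2L, min_organs = 3L) {
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing))
    stop("samples absent from design: ", paste(missing, collapse = ", "))
  design <- design[design$sample_id %in% colnames(matrix), , drop = FALSE]
  n_per <- table(design$organ)
  if (length(n_per) < min_organs)
    stop("design has ", length(n_per), " organ(s); at least ", min_organs,
         " required")
  few <- names(n_per)[n_per < min_reps]
  if (length(few))
    stop("organs with fewer than ", min_reps, " replicates: ",
         paste(few, collapse = ", "))
  design
}

#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of transcript per million sequenced
#' fragments) normalises raw fragment counts for transcript length and
#' sequencing depth:
#' \deqn{FPKM_{gs} = \frac{c_{gs} \times 10^9}{L_g \times T_s}}
#' where \eqn{c_{gs}} is the fragment count for gene g in sample s,
#' \eqn{L_g} the transcript length in base pairs, and \eqn{T_s} the sample's
#' total fragment count. The library size \eqn{T_s} is taken as the column
#' sum of the supplied count matrix, so the operation is self-contained;
#' pre-scale the counts if a different denominator (e.g. all mapped reads)
#' is wanted.
#'
#' @param counts Expression matrix with unit `"counts"`.
#' @param lengths Named numeric vector of transcript lengths in base pairs;
#'   must cover every gene in `counts`.
#' @return Expression matrix of the same shape with unit `"fpkm"`.
#' @examples
#' counts <- expression_matrix(
#'   matrix(c(10, 1e6 - 10), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
#'   unit = "counts")
#' compute_fpkm(counts, c(g1 = 1000, g2 = 1000))["g1", "s1"]  # 10
#' @export
compute_fpkm <- function(counts, lengths) {
  if (expression_unit(counts) != "counts")
    stop("`counts` must carry unit \"counts\"")
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("no transcript length for gene(s): ", paste(miss, collapse = ", "))
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("transcript lengths must be positive and finite")
  totals <- colSums(counts)
  zero <- colnames(counts)[totals <= 0]
  if (length(zero))
    stop("sample(s) with zero total fragments: ",
         paste(zero, collapse = ", "))
  fpkm <- sweep(counts * 1e9 / len, 2L, totals, "/")
  expression_matrix(fpkm, unit = "fpkm")
}

# ---- TSV round trips ----------------------------------------------------
# Dialect: UTF-8, tab-separated, no quoting, first header cell "gene_id".
# Values are written as %.17g so write -> read is bit-exact for doubles.

#' Read and write expression matrices as TSV
#'
#' @param path File path. First column is the gene id, remaining columns are
#'   samples; the first header cell is `gene_id` on write and ignored on
#'   read. Parse errors (ragged rows, non-numeric cells, duplicate ids)
#'   report the offending line number.
#' @param unit Unit tag to attach on read.
#' @export
read_expression_tsv <- function(path, unit = c("fpkm", "counts")) {
  unit <- match.arg(unit)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  p <- length(header)
  if (p < 2L) stop("line 1: header needs a gene id column and >= 1 sample")
  samples <- header[-1L]
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != p)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": expected ", p, " fields, found ",
         widths[bad[1L]])
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  raw <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  vals <- suppressWarnings(as.numeric(raw))
  nonnum <- which(is.na(vals) & raw != "NA")
  if (length(nonnum)) {
    row <- (nonnum[1L] - 1L) %/% (p - 1L) + 2L
    stop("line ", row, ": non-numeric value \"", raw[nonnum[1L]], "\"")
  }
  dup <- which(duplicated(gene_ids))
  if (length(dup))
    stop("line ", dup[1L] + 1L, ": duplicate gene id \"",
         gene_ids[dup[1L]], "\"")
  m <- matrix(vals, nrow = length(gene_ids), ncol = p - 1L, byrow = TRUE,
              dimnames = list(gene_ids, samples))
  expression_matrix(m, unit = unit)
}

#' @rdname read_expression_tsv
#' @param matrix Expression matrix to write.
#' @export
write_expression_tsv <- function(matrix, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read and write study designs as TSV
#'
#' Columns: `sample_id`, `organ`, `replicate`.
#' @param path File path.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file lacks column(s): ", paste(miss, collapse = ", "))
  study_design(d$sample_id, d$organ, d$replicate)
}

#' @rdname read_design_tsv
#' @param design Study design data.frame.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- GMT gene sets ------------------------------------------------------

#' Read and write gene-set collections in GMT format
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are collapsed; a line with
#' no members is rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (members by set id), with the
#'   set descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("line ", bad[1L],
         ": GMT line needs set id, description and >= 1 member")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("line ", which(duplicated(ids))[1L], ": duplicate set id \"",
         ids[duplicated(ids)][1L], "\"")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1L), 2L), ids)
  sets
}

#' @rdname read_gmt
#' @param collection Named list of member vectors, as returned by
#'   [read_gmt()].
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc))
    desc <- stats::setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(id)
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
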