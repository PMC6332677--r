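#' Validate a gene-by-sample expression matrix
#'
#' Expression matrices are plain numeric matrices with gene identifiers as
#' row names and sample identifiers as column names.  Values may be on any
#' monotone scale (linear, log2, ...): the package never rescales them,
#' because every downstream statistic depends only on within-sample
#' orderings.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @param min_genes minimum number of gene rows required (default 2).
#' @param allow_missing if `TRUE`, genes containing any non-finite value are
#'   dropped (with a message); the default rejects non-finite values, since
#'   ordering counts have no natural missing-value semantics.
#' @return the validated (possibly row-filtered) matrix, invisibly usable as
#'   input to every other function in the package.
#' @export
as_expression_matrix <- function(m, min_genes = 2L, allow_missing = FALSE) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must carry gene row names and sample column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(is.finite(m))) {
    if (!allow_missing) {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                   rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
    }
    keep <- rowSums(!is.finite(m)) == 0L
    message("dropping ", sum(!keep), " gene(s) with non-finite values")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < min_genes)
    stop("expression matrix needs at least ", min_genes, " genes")
  if (ncol(m) < 1L)
    stop("expression matrix needs at least one sample")
  m
}

# readLines with transparent gzip support
read_text_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  readLines(con)
}

#' Read an expression matrix from a tab-separated file
#'
#' Two layouts are supported.  `"plain_tsv"` is a header row
#' `gene<TAB>sample1<TAB>...` followed by one gene per row.
#' `"series_matrix"` is the GEO series-matrix dialect: metadata lines
#' beginning with `!` are ignored, and if the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers are
#' present only the table between them is parsed.  Quoted identifiers are
#' unquoted.
#'
#' @param path path to the file (plain or gzipped).
#' @param layout `"plain_tsv"` or `"series_matrix"`.
#' @param allow_missing see [as_expression_matrix()].
#' @return a validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, layout = c("plain_tsv", "series_matrix"),
                            allow_missing = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- read_text_lines(path)
  if (layout == "series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) == 1L && length(end) == 1L && end > beg)
      lines <- lines[(beg + 1L):(end - 1L)]
    lines <- lines[!startsWith(lines, "!")]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("no table body found in ", path)
  dt <- data.table::fread(text = lines, sep = "\t", header = TRUE,
                          quote = "\"", data.table = FALSE)
  if (ncol(dt) < 2L) stop("expected at least one sample column in ", path)
  samp <- colnames(dt)[-1L]
  if (anyDuplicated(samp))     # before subsetting, which uniquifies names
    stop("duplicate sample identifiers: ",
         paste(unique(samp[duplicated(samp)]), collapse = ", "))
  ids <- as.character(dt[[1L]])
  vals <- dt[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   vals[[j]][bad], bad, colnames(vals)[j], path))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  as_expression_matrix(m, allow_missing = allow_missing)
}

#' Write an expression matrix as plain TSV
#'
#' @param m expression matrix.
#' @param path output path; the header names the gene column `gene`.
#' @param gene_col name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, gene_col = "gene") {
  m <- as_expression_matrix(m, min_genes = 1L)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- gene_col
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene level
#'
#' Probes are mapped to genes through an annotation table.  Probes without a
#' mapping, with an empty/NA gene identifier, or mapped ambiguously to more
#' than one gene are dropped.  When several probes hit one gene,
#' `rule = "max_mean"` keeps the single probe with the largest mean across
#' samples (this preserves within-sample orderings, unlike averaging rows on
#' a log scale, and is therefore the default), while `rule = "mean"`
#' averages the probe rows.
#'
#' @param m expression matrix keyed by probe identifier.
#' @param annotation data frame with columns `probe_id` and `gene_id` (extra
#'   columns ignored); many-to-one and one-to-many rows are permitted.
#' @param rule `"max_mean"` or `"mean"`.
#' @return an expression matrix keyed by gene, rows sorted by gene id.
#' @export
collapse_probes <- function(m, annotation, rule = c("max_mean", "mean")) {
  rule <- match.arg(rule)
  m <- as_expression_matrix(m, min_genes = 1L)
  if (!all(c("probe_id", "gene_id") %in% names(annotation)))
    stop("annotation needs columns 'probe_id' and 'gene_id'")
  ann <- data.frame(probe_id = as.character(annotation$probe_id),
                    gene_id  = as.character(annotation$gene_id),
                    stringsAsFactors = FALSE)
  ann <- unique(ann[!is.na(ann$gene_id) & nzchar(ann$gene_id), ])
  # a probe pointing at >1 distinct gene is ambiguous and dropped
  ambig <- unique(ann$probe_id[duplicated(ann$probe_id)])
  ann <- ann[!ann$probe_id %in% ambig, ]
  ann <- ann[ann$probe_id %in% rownames(m), ]
  if (nrow(ann) == 0L)
    stop("no probe in the matrix maps to a gene in the annotation")
  genes <- sort(unique(ann$gene_id))
  probe_mean <- rowMeans(m)
  out <- matrix(NA_real_, length(genes), ncol(m),
                dimnames = list(genes, colnames(m)))
  for (g in genes) {
    probes <- sort(ann$probe_id[ann$gene_id == g])
    if (length(probes) == 1L || rule == "max_mean") {
      # ties on the mean broken by probe id order for determinism
      best <- probes[which.max(probe_mean[probes])]
      out[g, ] <- m[best, ]
    } else {
      out[g, ] <- colMeans(m[probes, , drop = FALSE])
    }
  }
  as_expression_matrix(out, min_genes = 1L)
}

#' Restrict several expression matrices to their common gene universe
#'
#' Cross-dataset pair comparisons are only meaningful on a shared gene set;
#' this is an explicit pipeline step, never applied implicitly.
#'
#' @param ms list of two or more expression matrices.
#' @return list of matrices, each restricted to the sorted common genes in
#'   identical row order.
#' @export
intersect_gene_universe <- function(ms) {
  if (!is.list(ms) || length(ms) < 2L)
    stop("need a list of at least two expression matrices")
  ms <- lapply(ms, as_expression_matrix, min_genes = 1L)
  common <- sort(Reduce(intersect, lapply(ms, rownames)))
  if (length(common) < 2L)
    stop("common gene universe has ", length(common),
         " gene(s); at least 2 are needed to form pairs")
  lapply(ms, function(m) m[common, , drop = FALSE])
}
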