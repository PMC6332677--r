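#' Construct a directed gene-pair set
#'
#' A directed pair (`gene_high`, `gene_low`) states that `gene_high` exceeds
#' `gene_low` within a sample; a set of such pairs is the output of
#' [detect_stable_pairs()] and the currency of all cross-dataset
#' comparisons.  At most one direction of an unordered pair may be present.
#'
#' @param gene_high,gene_low character vectors of equal length.
#' @param support optional per-pair support fraction (share of samples
#'   showing the stated direction).
#' @param threshold,n_samples optional provenance attributes recording the
#'   stability threshold and sample count used to build the set.
#' @return a data frame of class `reo_pairs` with columns `gene_high`,
#'   `gene_low` and optionally `support`.
#' @export
reo_pairs <- function(gene_high, gene_low, support = NULL,
                      threshold = NULL, n_samples = NULL) {
  gene_high <- as.character(gene_high)
  gene_low <- as.character(gene_low)
  if (length(gene_high) != length(gene_low))
    stop("gene_high and gene_low must have equal length")
  if (any(gene_high == gene_low))
    stop("a gene cannot be paired with itself")
  df <- data.frame(gene_high = gene_high, gene_low = gene_low,
                   stringsAsFactors = FALSE)
  if (!is.null(support)) df$support <- as.numeric(support)
  if (anyDuplicated(pair_key(df)))
    stop("duplicate unordered pair present (possibly in both directions)")
  attr(df, "threshold") <- threshold
  attr(df, "n_samples") <- n_samples
  class(df) <- c("reo_pairs", "data.frame")
  df
}

# canonical unordered key for a pair table
pair_key <- function(pairs) {
  paste(pmin(pairs$gene_high, pairs$gene_low),
        pmax(pairs$gene_high, pairs$gene_low), sep = "\r")
}

# directed key: distinguishes (a,b) from (b,a)
directed_key <- function(pairs) {
  paste(pairs$gene_high, pairs$gene_low, sep = "\r")
}

#' @export
print.reo_pairs <- function(x, ...) {
  cat("Directed REO pair set: ", nrow(x), " pair(s)\n", sep = "")
  if (!is.null(attr(x, "threshold")))
    cat("  stability threshold: >", attr(x, "threshold"),
        " of ", attr(x, "n_samples"), " sample(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... ", nrow(x) - 10L, " more\n", sep = "")
  invisible(x)
}

#' Read / write a directed pair set as TSV
#'
#' The format is tab-separated with columns `gene_high`, `gene_low` and an
#' optional `support` column; gzipped files are handled by extension.
#'
#' @param path file path.
#' @return `read_pairs` returns a [reo_pairs()] table; `write_pairs` its
#'   `path`, invisibly.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(text = read_text_lines(path), sep = "\t",
                          header = TRUE, data.table = FALSE)
  if (!all(c("gene_high", "gene_low") %in% names(dt)))
    stop("pair file needs columns 'gene_high' and 'gene_low': ", path)
  reo_pairs(dt$gene_high, dt$gene_low,
            support = if ("support" %in% names(dt)) dt$support)
}

#' @param pairs a [reo_pairs()] table.
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  data.table::fwrite(as.data.frame(pairs), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct a voting signature
#'
#' A signature is an ordered list of directed pairs stored in the class-1
#' direction (`gene_high` above `gene_low` in class-1 samples), plus the two
#' class labels the vote decides between.
#'
#' @param pairs a [reo_pairs()] table or data frame with `gene_high` /
#'   `gene_low` columns; order is meaningful.
#' @param class1,class2 labels assigned on a winning / losing majority.
#' @return an object of class `reo_signature`.
#' @export
reo_signature <- function(pairs, class1 = "class1", class2 = "class2") {
  pairs <- reo_pairs(pairs$gene_high, pairs$gene_low)
  if (nrow(pairs) == 0L) stop("a signature needs at least one pair")
  structure(list(pairs = pairs, class1 = as.character(class1),
                 class2 = as.character(class2)),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat("REO voting signature: ", nrow(x$pairs), " pair(s), ",
      x$class1, " vs ", x$class2, "\n", sep = "")
  cat("  (gene_high > gene_low in ", x$class1, ")\n", sep = "")
  print(as.data.frame(x$pairs))
  invisible(x)
}

#' Read / write a signature as annotated TSV
#'
#' Signatures serialise as a pair TSV preceded by comment lines
#' `#class1=<label>` and `#class2=<label>`.
#'
#' @param path file path.
#' @return `read_signature` returns a [reo_signature()]; `write_signature`
#'   its `path`, invisibly.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- read_text_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_label <- function(key) {
    hit <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(hit) != 1L) stop("signature file lacks a '#", key, "=' line")
    sub(paste0("^#", key, "="), "", hit)
  }
  body <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = body, sep = "\t", header = TRUE,
                          data.table = FALSE)
  reo_signature(dt, class1 = get_label("class1"), class2 = get_label("class2"))
}

#' @param sig a [reo_signature()].
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#class1=", sig$class1),
               paste0("#class2=", sig$class2)), con)
  utils::write.table(as.data.frame(sig$pairs)[, c("gene_high", "gene_low")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
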