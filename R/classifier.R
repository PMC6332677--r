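#' Classify one sample by majority vote over a signature
#'
#' Each signature pair with both genes present casts a class-1 vote when the
#' sample's value for `gene_high` strictly exceeds that for `gene_low` (a
#' tie or reversal is not a class-1 vote).  The sample is assigned the
#' class-1 label iff strictly more than half of the evaluated pairs voted
#' class 1; with an even evaluated count, an exact half goes to class 2.
#' Pairs with a missing gene are skipped and counted, shrinking the
#' denominator — unless `strict = TRUE`, in which case any missing gene is
#' an error.
#'
#' @param sample named numeric vector, or a one-column expression matrix.
#' @param sig a [reo_signature()].
#' @param strict refuse to classify when any signature gene is absent.
#' @return one-row data frame: `sample_id`, `votes_class1`, `n_evaluated`,
#'   `n_missing`, `predicted`.
#' @export
classify_sample <- function(sample, sig, strict = FALSE) {
  sid <- "sample"
  if (is.matrix(sample)) {
    if (ncol(sample) != 1L) stop("supply a single sample column")
    sid <- colnames(sample) %||% sid
    sample <- stats::setNames(sample[, 1L], rownames(sample))
  }
  if (is.null(names(sample))) stop("sample values must be named by gene")
  pairs <- sig$pairs
  present <- pairs$gene_high %in% names(sample) &
    pairs$gene_low %in% names(sample)
  missing_genes <- setdiff(unique(c(pairs$gene_high[!present],
                                    pairs$gene_low[!present])),
                           names(sample))
  if (strict && any(!present))
    stop("signature gene(s) absent from sample '", sid, "': ",
         paste(missing_genes, collapse = ", "))
  n_eval <- sum(present)
  if (n_eval == 0L)
    stop("no signature pair evaluable in sample '", sid,
         "'; missing gene(s): ", paste(missing_genes, collapse = ", "))
  votes <- sum(sample[pairs$gene_high[present]] >
                 sample[pairs$gene_low[present]])
  data.frame(sample_id = sid,
             votes_class1 = as.integer(votes),
             n_evaluated = n_eval,
             n_missing = nrow(pairs) - n_eval,
             predicted = if (votes > n_eval / 2) sig$class1 else sig$class2,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify every sample of an expression matrix
#'
#' Applies [classify_sample()] to each column; there is no cross-sample
#' coupling of any kind.  When true labels are supplied, per-class and
#' pooled accuracies (percent) are attached.
#'
#' @param m expression matrix.
#' @param sig a [reo_signature()].
#' @param labels optional character vector of true class labels, one per
#'   sample (values matching `sig$class1` / `sig$class2`; others ignored in
#'   the accuracy summary).
#' @param strict see [classify_sample()].
#' @return data frame of class `reo_classification`, one row per sample;
#'   with labels, an `accuracy` attribute holding `pooled`, `class1` and
#'   `class2` percentages.
#' @export
classify_matrix <- function(m, sig, labels = NULL, strict = FALSE) {
  m <- as_expression_matrix(m)
  res <- do.call(rbind, lapply(colnames(m), function(sid)
    classify_sample(m[, sid, drop = FALSE], sig, strict = strict)))
  class(res) <- c("reo_classification", "data.frame")
  if (!is.null(labels)) {
    if (length(labels) != ncol(m))
      stop("labels must have one entry per sample")
    labels <- as.character(labels)
    in1 <- labels == sig$class1; in2 <- labels == sig$class2
    acc <- c(pooled = 100 * mean(res$predicted[in1 | in2] == labels[in1 | in2]),
             class1 = 100 * mean(res$predicted[in1] == sig$class1),
             class2 = 100 * mean(res$predicted[in2] == sig$class2))
    attr(res, "accuracy") <- acc
  }
  res
}

#' @export
print.reo_classification <- function(x, ...) {
  print(as.data.frame(x))
  acc <- attr(x, "accuracy")
  if (!is.null(acc))
    cat(sprintf("accuracy: pooled %.2f%% | class1 %.2f%% | class2 %.2f%%\n",
                acc["pooled"], acc["class1"], acc["class2"]))
  invisible(x)
}

#' The published five-pair colorectal-versus-lung signature
#'
#' The fixed signature selected on six training cohorts of primary
#' colorectal (CRC) and lung cancer: five gene pairs, each with SLC34A2 as
#' the lower-expressed gene, the first gene being higher in CRC samples.
#' SLC34A2 is strongly expressed in lung tissue, which is why a single lung
#' marker anchors every pair.
#'
#' @param class1,class2 labels to attach (defaults "CRC" / "lung").
#' @return a [reo_signature()] with pairs (GUCY2C, SLC34A2),
#'   (CDH17, SLC34A2), (FABP1, SLC34A2), (KRT20, SLC34A2),
#'   (USH1C, SLC34A2).
#' @export
published_signature <- function(class1 = "CRC", class2 = "lung") {
  reo_signature(data.frame(
    gene_high = c("GUCY2C", "CDH17", "FABP1", "KRT20", "USH1C"),
    gene_low = rep("SLC34A2", 5L),
    stringsAsFactors = FALSE
  ), class1 = class1, class2 = class2)
}
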