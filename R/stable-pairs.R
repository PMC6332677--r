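#' Detect gene pairs with stable within-sample orderings
#'
#' An ordered pair (A, B) is stable when A's expression strictly exceeds B's
#' in more than `threshold` of the samples (strict on both counts: ties
#' count as "not higher", and support exactly equal to the threshold fails,
#' so 19/20 = 0.95 is not stable at threshold 0.95).  At most one direction
#' of an unordered pair can satisfy this for `threshold > 0.5`.
#'
#' For G genes there are G(G-1)/2 unordered pairs, so the scan runs over
#' gene blocks and never materialises more than `block_size^2` counters at
#' once; results are identical to the naive all-pairs loop.
#'
#' @param m expression matrix (genes x samples), any monotone scale.
#' @param threshold required support fraction, in (0.5, 1]; default 0.95.
#' @param block_size genes per block; tune downward to cap memory for very
#'   large gene universes.
#' @return a [reo_pairs()] table with per-pair `support`, carrying the
#'   threshold and sample count as attributes.
#' @export
detect_stable_pairs <- function(m, threshold = 0.95, block_size = 1024L) {
  m <- as_expression_matrix(m)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold > 1)
    stop("threshold must lie in (0.5, 1]")
  if (block_size < 1L) stop("block_size must be positive")
  G <- nrow(m); S <- ncol(m); genes <- rownames(m)
  blocks <- split(seq_len(G), ceiling(seq_len(G) / block_size))
  hi <- li <- integer(0); sup <- numeric(0)
  need <- threshold * S   # strictly more than this many samples
  for (bi in seq_along(blocks)) {
    ii <- blocks[[bi]]
    for (bj in bi:length(blocks)) {
      jj <- blocks[[bj]]
      cnt <- .pair_order_counts(m[ii, , drop = FALSE], m[jj, , drop = FALSE])
      n_gt <- cnt$gt
      n_lt <- cnt$lt
      elig <- if (bi == bj) outer(ii, jj, `<`) else matrix(TRUE, length(ii), length(jj))
      w <- which(elig & n_gt > need)
      if (length(w)) {
        hi <- c(hi, ii[row(elig)[w]]); li <- c(li, jj[col(elig)[w]])
        sup <- c(sup, n_gt[w] / S)
      }
      w <- which(elig & n_lt > need)
      if (length(w)) {
        hi <- c(hi, jj[col(elig)[w]]); li <- c(li, ii[row(elig)[w]])
        sup <- c(sup, n_lt[w] / S)
      }
    }
  }
  # block traversal order is deterministic; no re-sort needed
  reo_pairs(genes[hi], genes[li], support = sup,
            threshold = threshold, n_samples = S)
}

#' Intersect stable-pair sets into a characteristic set
#'
#' The characteristic stable pairs of a tumour class are the ordered pairs
#' present with the same direction in every one of the class's datasets;
#' direction conflicts remove a pair entirely.
#'
#' @param sets list of two or more [reo_pairs()] tables.
#' @return a [reo_pairs()] table (no support column), sorted by gene ids.
#' @export
characteristic_pairs <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("need a list of at least two pair sets")
  keys <- lapply(sets, directed_key)
  common <- Reduce(intersect, keys)
  first <- sets[[1L]][keys[[1L]] %in% common, c("gene_high", "gene_low")]
  first <- first[order(first$gene_high, first$gene_low), , drop = FALSE]
  reo_pairs(first$gene_high, first$gene_low)
}
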