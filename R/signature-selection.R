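#' Pairs whose stable ordering reverses between two classes
#'
#' Returns the pairs stable as (a, b) in the class-1 characteristic set and
#' stable as (b, a) in the class-2 set, stored in the class-1 direction.
#' Swapping the two arguments returns the same unordered pairs with
#' directions flipped.
#'
#' @param char1,char2 non-empty [reo_pairs()] tables (characteristic sets of
#'   the two classes).
#' @return a [reo_pairs()] table in class-1 direction, sorted by gene ids;
#'   may be empty.
#' @export
find_reversed_pairs <- function(char1, char2) {
  if (nrow(char1) == 0L || nrow(char2) == 0L)
    stop("both characteristic sets must be non-empty")
  flipped2 <- paste(char2$gene_low, char2$gene_high, sep = "\r")
  hit <- directed_key(char1) %in% flipped2
  out <- char1[hit, c("gene_high", "gene_low"), drop = FALSE]
  out <- out[order(out$gene_high, out$gene_low), , drop = FALSE]
  reo_pairs(out$gene_high, out$gene_low)
}

#' Within-sample expression ranks
#'
#' Ranks each column from 1 (lowest expression) to G (highest), ties
#' receiving the average rank.  All rank-difference statistics depend only
#' on these values, which is what makes them scale-free.
#'
#' @param m expression matrix.
#' @return matrix of the same shape and dimnames holding per-column ranks.
#' @export
within_sample_ranks <- function(m) {
  m <- as_expression_matrix(m)
  r <- apply(m, 2L, rank)           # ties.method = "average"
  dimnames(r) <- dimnames(m)
  r
}

#' Average within-sample rank difference of a gene pair
#'
#' For pair (i, j) and rank matrices of the two training classes, the score
#' is the mean over all N1 + N2 training samples of |R_i - R_j|, the
#' absolute within-sample rank difference.  Large values mean the two genes
#' sit far apart in every profile, so their ordering is robust.
#'
#' @param pair character vector of two gene ids `c(i, j)`.
#' @param ranks1,ranks2 rank matrices from [within_sample_ranks()] for the
#'   class-1 and class-2 training samples.
#' @return the average rank difference (a non-negative scalar).
#' @export
delta_avg_rank <- function(pair, ranks1, ranks2) {
  pair <- as.character(pair)
  if (length(pair) != 2L) stop("pair must name exactly two genes")
  for (rk in list(ranks1, ranks2))
    if (!all(pair %in% rownames(rk)))
      stop("gene(s) missing from a rank matrix: ",
           paste(setdiff(pair, rownames(rk)), collapse = ", "))
  d1 <- abs(ranks1[pair[1L], ] - ranks1[pair[2L], ])
  d2 <- abs(ranks2[pair[1L], ] - ranks2[pair[2L], ])
  (sum(d1) + sum(d2)) / (ncol(ranks1) + ncol(ranks2))
}

# vectorised delta_avg_rank over the rows of a pair table
delta_avg_rank_table <- function(pairs, ranks1, ranks2) {
  d1 <- abs(ranks1[pairs$gene_high, , drop = FALSE] -
              ranks1[pairs$gene_low, , drop = FALSE])
  d2 <- abs(ranks2[pairs$gene_high, , drop = FALSE] -
              ranks2[pairs$gene_low, , drop = FALSE])
  (rowSums(d1) + rowSums(d2)) / (ncol(ranks1) + ncol(ranks2))
}

#' Gene appearance frequencies in a reversed-pair set
#'
#' @param reversed [reo_pairs()] table.
#' @return named integer vector: for each gene, the number of reversed pairs
#'   it appears in (either side).
#' @export
gene_frequencies <- function(reversed) {
  tab <- table(c(reversed$gene_high, reversed$gene_low))
  stats::setNames(as.integer(tab), names(tab))
}

#' Build the ordered candidate pair list
#'
#' Genes are sorted by their appearance frequency in the reversed-pair set,
#' descending (frequency ties broken lexicographically on gene id).  Walking
#' down that gene list, each gene contributes its reversed pair with the
#' largest average rank difference (ties: the partner with the larger
#' frequency, then the lexicographically smaller partner); a pair already
#' contributed by an earlier gene is skipped, so the list has no duplicates.
#' A gene's best partner need not itself be a high-frequency gene.
#'
#' @param reversed [reo_pairs()] table in class-1 direction.
#' @param freq named vector of gene appearance frequencies; computed with
#'   [gene_frequencies()] when omitted.
#' @param delta per-pair average rank differences aligned with the rows of
#'   `reversed` (see [delta_avg_rank()]), or a rank-matrix pair via
#'   `ranks1`/`ranks2`.
#' @param ranks1,ranks2 rank matrices used to compute `delta` when it is not
#'   supplied directly.
#' @return a [reo_pairs()] table ordered by candidate priority, with a
#'   `delta_avg_rank` column.
#' @export
build_candidate_list <- function(reversed, freq = NULL, delta = NULL,
                                 ranks1 = NULL, ranks2 = NULL) {
  if (nrow(reversed) == 0L) stop("reversed pair set is empty")
  if (is.null(freq)) freq <- gene_frequencies(reversed)
  if (is.null(delta)) {
    if (is.null(ranks1) || is.null(ranks2))
      stop("supply either delta or both rank matrices")
    delta <- delta_avg_rank_table(reversed, ranks1, ranks2)
  }
  if (length(delta) != nrow(reversed))
    stop("delta must align with the rows of the reversed set")
  genes <- names(freq)[order(-freq, names(freq))]
  dkey <- directed_key(reversed)
  chosen <- character(0)
  out <- integer(0)
  for (g in genes) {
    rows <- which(reversed$gene_high == g | reversed$gene_low == g)
    if (!length(rows)) next
    partner <- ifelse(reversed$gene_high[rows] == g,
                      reversed$gene_low[rows], reversed$gene_high[rows])
    pf <- freq[partner]
    pf[is.na(pf)] <- 0L
    ranked <- rows[order(-delta[rows], -pf, partner)]
    # best remaining pair: one already contributed by an earlier gene is
    # skipped so the gene introduces a new pair (or none are left)
    ranked <- ranked[!dkey[ranked] %in% chosen]
    if (!length(ranked)) next
    chosen <- c(chosen, dkey[ranked[1L]])
    out <- c(out, ranked[1L])
  }
  cand <- reo_pairs(reversed$gene_high[out], reversed$gene_low[out])
  cand$delta_avg_rank <- delta[out]
  cand
}

#' Scan odd signature sizes by training accuracy
#'
#' Takes the first n candidate pairs for each odd n (1, 3, 5, ...), applies
#' the majority-vote classifier to the pooled training samples of both
#' classes, and records the percent correctly classified.  The chosen size
#' is the smallest odd n whose accuracy equals the maximum over the scan —
#' the start of the accuracy plateau.
#'
#' @param candidates ordered [reo_pairs()] table from
#'   [build_candidate_list()].
#' @param train1,train2 expression matrices of the class-1 and class-2
#'   training samples.
#' @param max_n largest odd size scanned (default 43); must be odd and no
#'   larger than the candidate list.
#' @param class1,class2 labels used in the returned accuracies.
#' @return an object of class `reo_size_scan`: list with `scan` (data frame
#'   of `n_pairs`, pooled `accuracy`, and per-class accuracies, in percent)
#'   and `chosen_n`.
#' @export
scan_odd_sizes <- function(candidates, train1, train2, max_n = 43L,
                           class1 = "class1", class2 = "class2") {
  if (nrow(candidates) < 1L) stop("candidate list is empty")
  if (max_n %% 2L == 0L) stop("max_n must be odd")
  if (max_n > nrow(candidates))
    stop("max_n (", max_n, ") exceeds the candidate list (",
         nrow(candidates), " pairs)")
  train1 <- as_expression_matrix(train1)
  train2 <- as_expression_matrix(train2)
  sizes <- seq(1L, max_n, by = 2L)
  rows <- lapply(sizes, function(n) {
    sig <- reo_signature(candidates[seq_len(n), , drop = FALSE],
                         class1 = class1, class2 = class2)
    pred1 <- classify_matrix(train1, sig)$predicted
    pred2 <- classify_matrix(train2, sig)$predicted
    acc1 <- 100 * mean(pred1 == class1)
    acc2 <- 100 * mean(pred2 == class2)
    pooled <- 100 * (sum(pred1 == class1) + sum(pred2 == class2)) /
      (length(pred1) + length(pred2))
    data.frame(n_pairs = n, accuracy = pooled,
               accuracy_class1 = acc1, accuracy_class2 = acc2)
  })
  scan <- do.call(rbind, rows)
  chosen <- scan$n_pairs[which(scan$accuracy == max(scan$accuracy))[1L]]
  structure(list(scan = scan, chosen_n = chosen,
                 class1 = class1, class2 = class2),
            class = "reo_size_scan")
}

#' @export
print.reo_size_scan <- function(x, ...) {
  cat("Signature size scan (", x$class1, " vs ", x$class2, "): chosen n = ",
      x$chosen_n, "\n", sep = "")
  print(x$scan, row.names = FALSE)
  invisible(x)
}

#' End-to-end signature selection from training expression
#'
#' Convenience wrapper running the full selection pipeline: stable-pair
#' detection per training dataset, per-class characteristic sets, reversed
#' pairs, candidate ranking on the intersected gene universe, and the odd
#' size scan.  With a single dataset per class the characteristic set is
#' that dataset's stable set.
#'
#' @param class1_mats,class2_mats lists of expression matrices (training
#'   datasets of the two classes).
#' @param threshold stability threshold passed to [detect_stable_pairs()].
#' @param max_n largest odd signature size scanned; clamped to the odd
#'   length of the candidate list.
#' @param class1,class2 class labels.
#' @return list with `signature` (a [reo_signature()] of the chosen size),
#'   `scan`, `candidates`, `reversed`, and `frequencies`.
#' @export
select_signature <- function(class1_mats, class2_mats, threshold = 0.95,
                             max_n = 43L, class1 = "class1",
                             class2 = "class2") {
  if (!is.list(class1_mats)) class1_mats <- list(class1_mats)
  if (!is.list(class2_mats)) class2_mats <- list(class2_mats)
  harm <- intersect_gene_universe(c(class1_mats, class2_mats))
  class1_mats <- harm[seq_along(class1_mats)]
  class2_mats <- harm[-seq_along(class1_mats)]
  char_of <- function(mats) {
    sets <- lapply(mats, detect_stable_pairs, threshold = threshold)
    if (length(sets) == 1L) sets[[1L]] else characteristic_pairs(sets)
  }
  reversed <- find_reversed_pairs(char_of(class1_mats), char_of(class2_mats))
  if (nrow(reversed) == 0L)
    stop("no reversed pairs between the two classes at threshold ", threshold)
  pool1 <- do.call(cbind, class1_mats)
  pool2 <- do.call(cbind, class2_mats)
  ranks1 <- within_sample_ranks(pool1)
  ranks2 <- within_sample_ranks(pool2)
  freq <- gene_frequencies(reversed)
  cand <- build_candidate_list(reversed, freq = freq,
                               ranks1 = ranks1, ranks2 = ranks2)
  n_cap <- nrow(cand) - (1L - nrow(cand) %% 2L)   # largest odd <= length
  scan <- scan_odd_sizes(cand, pool1, pool2, max_n = min(max_n, n_cap),
                         class1 = class1, class2 = class2)
  sig <- reo_signature(cand[seq_len(scan$chosen_n), , drop = FALSE],
                       class1 = class1, class2 = class2)
  list(signature = sig, scan = scan, candidates = cand,
       reversed = reversed, frequencies = freq)
}
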