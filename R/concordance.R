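#' Upper-tail cumulative binomial probability
#'
#' Probability of observing at least `s` direction-concordant pairs out of
#' `k` overlapping pairs when each pair agrees by chance with probability
#' `p_e`: `P(X >= s)` for `X ~ Binomial(k, p_e)`, i.e.
#' `1 - sum_{i=0}^{s-1} C(k,i) p_e^i (1-p_e)^(k-i)`.  Computed through the
#' regularized incomplete beta function, so it stays accurate for pair
#' counts in the hundreds of millions; `log_p = TRUE` returns the natural
#' log for tails far below double precision.
#'
#' @param s observed concordant count, `0 <= s <= k` (at `s = 0` the sum is
#'   empty and the tail is exactly 1).
#' @param k number of overlapping pairs (trials).
#' @param p_e chance agreement probability, in (0, 1); default 0.5.
#' @param log_p return the natural logarithm of the tail.
#' @return the tail probability (or its log).
#' @export
binomial_tail <- function(s, k, p_e = 0.5, log_p = FALSE) {
  if (length(s) != 1L || length(k) != 1L || is.na(s) || is.na(k) ||
      s != round(s) || k != round(k) || k < 0 || s < 0 || s > k)
    stop("need integers 0 <= s <= k")
  if (length(p_e) != 1L || is.na(p_e) || p_e <= 0 || p_e >= 1)
    stop("p_e must lie strictly between 0 and 1")
  if (s == 0) return(if (log_p) 0 else 1)
  stats::pbinom(s - 1, k, p_e, lower.tail = FALSE, log.p = log_p)
}

#' Concordance between two stable-pair sets
#'
#' Counts the unordered pairs present in both sets (`k`, in either
#' direction) and those whose directions agree (`s`); the concordance score
#' is `s/k * 100` and its chance probability comes from [binomial_tail()].
#' The statistic is symmetric in its two arguments.
#'
#' @param a,b non-empty [reo_pairs()] tables.
#' @param p_e chance agreement probability per overlapping pair.
#' @return an object of class `reo_concordance`: list with `k`, `s`,
#'   `score` (percent; `NA` and `undefined = TRUE` when `k = 0`),
#'   `p_value`, `log_p` (natural log of the tail) and `p_e`.
#' @export
concordance_score <- function(a, b, p_e = 0.5) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both pair sets must be non-empty")
  ka <- pair_key(a); kb <- pair_key(b)
  # direction flag relative to the canonical (alphabetical) orientation
  da <- a$gene_high < a$gene_low
  db <- b$gene_high < b$gene_low
  common <- intersect(ka, kb)
  k <- length(common)
  if (k == 0L) {
    res <- list(k = 0L, s = 0L, score = NA_real_, p_value = 1,
                log_p = 0, p_e = p_e, undefined = TRUE)
  } else {
    s <- sum(da[match(common, ka)] == db[match(common, kb)])
    res <- list(k = k, s = as.integer(s), score = 100 * s / k,
                p_value = binomial_tail(s, k, p_e),
                log_p = binomial_tail(s, k, p_e, log_p = TRUE),
                p_e = p_e, undefined = FALSE)
  }
  structure(res, class = "reo_concordance")
}

#' @export
print.reo_concordance <- function(x, ...) {
  if (x$undefined) {
    cat("REO concordance: no overlapping pairs (k = 0); score not applicable\n")
    return(invisible(x))
  }
  p_show <- if (x$p_value < 2.2e-16) "< 2.2e-16" else format(x$p_value)
  cat(sprintf("REO concordance: s = %d of k = %d pairs agree (%.2f%%), P %s (P_e = %g)\n",
              x$s, x$k, x$score, p_show, x$p_e))
  invisible(x)
}

#' Concordance of one sample with a reference direction set
#'
#' Fraction (percent) of the reference pairs whose stated ordering is
#' realised in the sample: a pair (high, low) counts as concordant only when
#' the sample's value for `high` strictly exceeds that for `low` (ties are
#' discordant).  Pairs with either gene absent from the sample are excluded
#' from the denominator and reported via the `n_missing` attribute.
#'
#' @param sample named numeric vector, or a one-column expression matrix.
#' @param reference [reo_pairs()] table giving the reference directions.
#' @return percent concordance, with attributes `n_evaluated`,
#'   `n_concordant` and `n_missing`.
#' @export
per_sample_concordance <- function(sample, reference) {
  if (is.matrix(sample)) {
    if (ncol(sample) != 1L) stop("supply a single sample column")
    sample <- stats::setNames(sample[, 1L], rownames(sample))
  }
  if (is.null(names(sample))) stop("sample values must be named by gene")
  present <- reference$gene_high %in% names(sample) &
    reference$gene_low %in% names(sample)
  n_eval <- sum(present)
  if (n_eval == 0L)
    stop("no reference pair has both genes present in the sample")
  conc <- sum(sample[reference$gene_high[present]] >
                sample[reference$gene_low[present]])
  structure(100 * conc / n_eval, n_evaluated = n_eval,
            n_concordant = as.integer(conc),
            n_missing = as.integer(nrow(reference) - n_eval))
}

#' Per-sample concordance table for a whole matrix
#'
#' Applies [per_sample_concordance()] to every column and returns one row
#' per sample — the tabular form of a per-metastasis concordance figure.
#'
#' @param m expression matrix.
#' @param reference [reo_pairs()] table.
#' @return data frame with `sample_id`, `concordance` (percent),
#'   `n_evaluated`, `n_missing`.
#' @export
sample_concordance_table <- function(m, reference) {
  m <- as_expression_matrix(m)
  rows <- lapply(colnames(m), function(sid) {
    x <- per_sample_concordance(stats::setNames(m[, sid], rownames(m)), reference)
    data.frame(sample_id = sid, concordance = as.numeric(x),
               n_evaluated = attr(x, "n_evaluated"),
               n_missing = attr(x, "n_missing"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
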