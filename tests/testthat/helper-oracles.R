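# Independent brute-force oracles: deliberately naive double loops and
# enumerations, kept free of any code path they are used to check.

rand_expr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# all-pairs double loop over unordered pairs
oracle_stable_pairs <- function(m, threshold = 0.95) {
  genes <- rownames(m); S <- ncol(m)
  hi <- lo <- character(0); sup <- numeric(0)
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      n_gt <- sum(m[i, ] > m[j, ])
      n_lt <- sum(m[j, ] > m[i, ])
      if (n_gt / S > threshold) {
        hi <- c(hi, genes[i]); lo <- c(lo, genes[j]); sup <- c(sup, n_gt / S)
      } else if (n_lt / S > threshold) {
        hi <- c(hi, genes[j]); lo <- c(lo, genes[i]); sup <- c(sup, n_lt / S)
      }
    }
  }
  data.frame(gene_high = hi, gene_low = lo, support = sup,
             stringsAsFactors = FALSE)
}

oracle_characteristic <- function(sets) {
  first <- sets[[1L]]
  keep <- logical(nrow(first))
  for (r in seq_len(nrow(first))) {
    keep[r] <- all(vapply(sets[-1L], function(s)
      any(s$gene_high == first$gene_high[r] &
            s$gene_low == first$gene_low[r]), logical(1L)))
  }
  first[keep, c("gene_high", "gene_low"), drop = FALSE]
}

oracle_concordance <- function(a, b) {
  k <- 0L; s <- 0L
  for (r in seq_len(nrow(a))) {
    same <- any(b$gene_high == a$gene_high[r] & b$gene_low == a$gene_low[r])
    rev <- any(b$gene_high == a$gene_low[r] & b$gene_low == a$gene_high[r])
    if (same || rev) {
      k <- k + 1L
      if (same) s <- s + 1L
    }
  }
  list(k = k, s = s, score = if (k > 0) 100 * s / k else NA_real_)
}

oracle_sample_concordance <- function(x, ref) {
  n_eval <- 0L; conc <- 0L
  for (r in seq_len(nrow(ref))) {
    h <- ref$gene_high[r]; l <- ref$gene_low[r]
    if (h %in% names(x) && l %in% names(x)) {
      n_eval <- n_eval + 1L
      if (x[[h]] > x[[l]]) conc <- conc + 1L
    }
  }
  100 * conc / n_eval
}

# Binomial(k, pe) upper tail by repeated Pascal convolution of the pmf
oracle_binom_tail_conv <- function(s, k, pe) {
  pmf <- 1
  for (i in seq_len(k)) pmf <- c(pmf * (1 - pe), 0) + c(0, pmf * pe)
  sum(pmf[(s + 1L):(k + 1L)])
}

# literal enumeration over all 2^k outcomes (small k only)
oracle_binom_tail_enum <- function(s, k, pe) {
  total <- 0
  for (o in 0:(2^k - 1L)) {
    bits <- sum(bitwAnd(bitwShiftR(o, 0:(k - 1L)), 1L))
    if (bits >= s) total <- total + pe^bits * (1 - pe)^(k - bits)
  }
  total
}

oracle_ranks <- function(m) {
  r <- m
  for (s in seq_len(ncol(m))) {
    x <- m[, s]
    # average rank: mean position of each tied block in the sorted column
    sorted <- sort(x)
    rk <- numeric(length(x))
    for (g in seq_along(x))
      rk[g] <- mean(which(sorted == x[g]))
    r[, s] <- rk
  }
  r
}

oracle_delta_avg_rank <- function(pair, ranks1, ranks2) {
  tot <- 0
  for (n in seq_len(ncol(ranks1)))
    tot <- tot + abs(ranks1[pair[1L], n] - ranks1[pair[2L], n])
  for (m_ in seq_len(ncol(ranks2)))
    tot <- tot + abs(ranks2[pair[1L], m_] - ranks2[pair[2L], m_])
  tot / (ncol(ranks1) + ncol(ranks2))
}

oracle_classify <- function(m, sig) {
  pred <- character(ncol(m)); votes <- integer(ncol(m))
  for (s in seq_len(ncol(m))) {
    v <- 0L; n_eval <- 0L
    for (r in seq_len(nrow(sig$pairs))) {
      h <- sig$pairs$gene_high[r]; l <- sig$pairs$gene_low[r]
      if (h %in% rownames(m) && l %in% rownames(m)) {
        n_eval <- n_eval + 1L
        if (m[h, s] > m[l, s]) v <- v + 1L
      }
    }
    votes[s] <- v
    pred[s] <- if (v > n_eval / 2) sig$class1 else sig$class2
  }
  list(predicted = pred, votes = votes)
}

# directed pair tables as comparable key sets
directed_keys <- function(pairs) paste(pairs$gene_high, pairs$gene_low)

expect_same_pairs <- function(a, b) {
  expect_setequal(directed_keys(a), directed_keys(b))
}
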