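test_that("reversed pairs are those stable in opposite directions", {
  c1 <- reo_pairs(c("a", "p"), c("b", "q"))
  c2 <- reo_pairs(c("b", "p"), c("a", "q"))
  rev <- find_reversed_pairs(c1, c2)
  expect_same_pairs(rev, data.frame(gene_high = "a", gene_low = "b"))
  # identical sets share no reversal
  expect_identical(nrow(find_reversed_pairs(c1, c1)), 0L)
  # class swap returns the same unordered pairs with flipped direction
  back <- find_reversed_pairs(c2, c1)
  expect_identical(back$gene_high, rev$gene_low)
  expect_identical(back$gene_low, rev$gene_high)
})

test_that("within-sample ranks match a sort-based oracle and average ties", {
  m <- matrix(c(2, 5, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(within_sample_ranks(m)[, 1], c(a = 1, b = 3, c = 2))
  tied <- matrix(c(1, 1, 9), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(within_sample_ranks(tied)[, 1], c(a = 1.5, b = 1.5, c = 3))
  r <- rand_expr(10, 5, seed = 21)
  expect_equal(within_sample_ranks(r), oracle_ranks(r))
})

test_that("the average rank difference follows its defining arithmetic", {
  ranks1 <- matrix(c(1, 3, 2, 5), nrow = 2,
                   dimnames = list(c("i", "j"), c("n1", "n2")))
  ranks2 <- matrix(c(4, 1), nrow = 2, dimnames = list(c("i", "j"), "m1"))
  expect_equal(delta_avg_rank(c("i", "j"), ranks1, ranks2), 8 / 3)
  # constant rank separation c in every sample gives exactly c
  const1 <- matrix(c(7, 2, 9, 4, 6, 1), nrow = 2,
                   dimnames = list(c("i", "j"), paste0("n", 1:3)))
  const2 <- const1[, 1:2]
  expect_equal(delta_avg_rank(c("i", "j"), const1, const2), 5)
  expect_error(delta_avg_rank(c("i", "zz"), ranks1, ranks2), "zz")
  # agreement with the explicit loop oracle on random ranks
  m1 <- within_sample_ranks(rand_expr(8, 6, seed = 31))
  m2 <- within_sample_ranks(rand_expr(8, 4, seed = 32))
  expect_equal(delta_avg_rank(c("g002", "g007"), m1, m2),
               oracle_delta_avg_rank(c("g002", "g007"), m1, m2))
})

test_that("rank statistics are invariant to per-sample increasing transforms", {
  m <- rand_expr(12, 7, seed = 8)
  warped <- apply_monotone_distortion(m, "rank_preserving_spline", seed = 2)
  expect_equal(within_sample_ranks(warped), within_sample_ranks(m))
})

test_that("candidate list follows frequency order with max-delta pairs, no duplicates", {
  rev <- reo_pairs(c("x", "x", "y"), c("h1", "h2", "h3"))
  freq <- c(x = 3, y = 2, z = 1)
  cand <- build_candidate_list(rev, freq = freq, delta = c(5, 9, 4))
  expect_identical(cand$gene_high[1:2], c("x", "y"))
  expect_identical(cand$gene_low[1:2], c("h2", "h3"))
  expect_identical(cand$delta_avg_rank[1:2], c(9, 4))

  # a single reversed pair yields exactly that pair
  single <- build_candidate_list(reo_pairs("a", "b"), delta = 3)
  expect_identical(nrow(single), 1L)

  # a pair already contributed by an earlier gene is skipped, and a gene
  # whose best pair was consumed contributes its next-best remaining pair
  rev2 <- reo_pairs(c("a", "a", "b"), c("b", "c", "d"))
  freq2 <- gene_frequencies(rev2)
  expect_equal(freq2[["a"]], 2L); expect_equal(freq2[["b"]], 2L)
  cand2 <- build_candidate_list(rev2, freq = freq2, delta = c(10, 1, 5))
  expect_identical(directed_keys(cand2), c("a b", "b d", "a c"))
})

test_that("frequency and delta ties break lexicographically for determinism", {
  rev <- reo_pairs(c("b", "a"), c("q", "p"))
  cand <- build_candidate_list(rev, delta = c(2, 2))
  # all genes have frequency 1: gene 'a' wins the tie, then 'b'
  expect_identical(cand$gene_high, c("a", "b"))
})

test_that("planted pairs with dominant rank gaps top the candidate list", {
  # two planted pairs straddle the extremes of the rank scale; background
  # reversals have tiny rank gaps
  set.seed(77)
  G <- 30
  genes <- sprintf("g%03d", 1:G)
  base <- seq(10, 12, length.out = G)
  names(base) <- genes
  mk <- function(mu, n, prefix) {
    m <- matrix(rep(mu, n), ncol = n,
                dimnames = list(genes, paste0(prefix, 1:n)))
    m + matrix(rnorm(G * n, 0, 1e-3), G, n)
  }
  mu1 <- base; mu2 <- base
  mu1["g001"] <- 20; mu1["g002"] <- 0; mu2["g001"] <- 0; mu2["g002"] <- 20
  mu1["g003"] <- 25; mu1["g004"] <- -5; mu2["g003"] <- -5; mu2["g004"] <- 25
  # one background reversal with adjacent means
  mu1["g010"] <- 11; mu1["g011"] <- 10.99
  mu2["g010"] <- 10.99; mu2["g011"] <- 11
  m1 <- mk(mu1, 10, "a"); m2 <- mk(mu2, 10, "b")
  rev <- find_reversed_pairs(detect_stable_pairs(m1), detect_stable_pairs(m2))
  cand <- build_candidate_list(rev,
                               ranks1 = within_sample_ranks(m1),
                               ranks2 = within_sample_ranks(m2))
  top_genes <- unique(c(cand$gene_high[1:2], cand$gene_low[1:2]))
  expect_setequal(top_genes, c("g001", "g002", "g003", "g004"))
})

test_that("the odd-size scan matches a vote-counting oracle and picks the plateau start", {
  sim <- generate_two_class(sim_config(n_genes = 80, n_class1 = 20,
                                       n_class2 = 20, n_reversed = 7,
                                       noise_sd = 0.8, rank_gap = 0.4,
                                       stability = 0.8, seed = 12))
  sel_rev <- find_reversed_pairs(
    detect_stable_pairs(sim$class1, threshold = 0.7),
    detect_stable_pairs(sim$class2, threshold = 0.7))
  cand <- build_candidate_list(sel_rev,
                               ranks1 = within_sample_ranks(sim$class1),
                               ranks2 = within_sample_ranks(sim$class2))
  max_n <- nrow(cand) - (1 - nrow(cand) %% 2)
  scan <- scan_odd_sizes(cand, sim$class1, sim$class2, max_n = max_n,
                         class1 = "one", class2 = "two")
  expect_true(all(scan$scan$n_pairs %% 2 == 1))
  expect_equal(max(scan$scan$accuracy[scan$scan$n_pairs == scan$chosen_n]),
               max(scan$scan$accuracy))
  expect_identical(min(scan$scan$n_pairs[scan$scan$accuracy ==
                                           max(scan$scan$accuracy)]),
                   scan$chosen_n)
  for (r in seq_len(nrow(scan$scan))) {
    n <- scan$scan$n_pairs[r]
    sig <- reo_signature(cand[seq_len(n), ], class1 = "one", class2 = "two")
    o1 <- oracle_classify(sim$class1, sig)
    o2 <- oracle_classify(sim$class2, sig)
    acc <- 100 * (sum(o1$predicted == "one") + sum(o2$predicted == "two")) /
      (length(o1$predicted) + length(o2$predicted))
    expect_equal(scan$scan$accuracy[r], acc)
  }
})

test_that("perfectly separable data reach 100% with a single pair", {
  sim <- generate_two_class(sim_config(n_genes = 50, n_class1 = 10,
                                       n_class2 = 10, n_reversed = 3,
                                       noise_sd = 0, seed = 5))
  sel <- select_signature(sim$class1, sim$class2)
  expect_identical(sel$scan$chosen_n, 1L)
  expect_equal(sel$scan$scan$accuracy[1], 100)
  expect_same_pairs(sel$reversed, sim$planted)
})

test_that("the scan validates its arguments", {
  cand <- reo_pairs(c("a", "c"), c("b", "d"))
  m <- rand_expr(4, 3, seed = 1)
  rownames(m) <- c("a", "b", "c", "d")
  expect_error(scan_odd_sizes(cand, m, m, max_n = 2), "odd")
  expect_error(scan_odd_sizes(cand, m, m, max_n = 5), "exceeds")
  expect_error(scan_odd_sizes(cand[0, ], m, m, max_n = 1), "empty")
})
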