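#' Configuration for the two-class REO simulator
#'
#' The generator emulates the statistical structure the pipeline is built
#' for: two tumour classes whose within-sample orderings are stable for
#' most gene pairs, a planted set of pairs whose ordering reverses between
#' the classes, per-entry Gaussian noise on a log-like scale, an additive
#' per-dataset batch offset, and metastasis-like samples that follow the
#' class-1 ordering with a tunable admixture of class-2-like flips.
#'
#' Stability is controlled through the normal CDF: with per-entry noise
#' standard deviation `noise_sd`, a mean offset of `d = qnorm(stability) *
#' noise_sd / sqrt(2)` on each gene of a planted pair makes the planted
#' ordering hold in a `stability` fraction of samples in expectation
#' (`P(high > low) = pnorm(2 d / (sqrt(2) noise_sd))`).  `rank_gap` is a
#' floor on that offset (in expression units), guaranteeing a large
#' within-sample rank separation for planted pairs regardless of noise.
#'
#' @param n_genes number of genes (default 500).
#' @param n_class1,n_class2 samples per class (default 50 each).
#' @param n_metastasis metastasis-like samples (default 20).
#' @param n_reversed planted reversed pairs (default 5); uses
#'   `2 * n_reversed` distinct genes.
#' @param stability target within-class ordering stability fraction for
#'   planted pairs, in (0.5, 1] (default 0.97).
#' @param rank_gap minimum per-gene mean offset for planted pairs, in
#'   expression (log2-like) units (default 1).
#' @param noise_sd per-entry Gaussian noise SD (default 0.4).
#' @param batch_shift additive offset applied to the class-2 dataset as a
#'   whole (default 0); metastasis samples get `-batch_shift`.
#' @param metastasis_admixture fraction of planted pairs flipped toward the
#'   class-2 direction in each metastasis sample, in \[0, 1\] (default 0.2).
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of the full configuration.
#' @return a list of class `reo_sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_class1 = 50L, n_class2 = 50L,
                       n_metastasis = 20L, n_reversed = 5L,
                       stability = 0.97, rank_gap = 1, noise_sd = 0.4,
                       batch_shift = 0, metastasis_admixture = 0.2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_class1 = as.integer(n_class1),
              n_class2 = as.integer(n_class2),
              n_metastasis = as.integer(n_metastasis),
              n_reversed = as.integer(n_reversed), stability = stability,
              rank_gap = rank_gap, noise_sd = noise_sd,
              batch_shift = batch_shift,
              metastasis_admixture = metastasis_admixture,
              seed = as.integer(seed))
  if (2L * cfg$n_reversed > cfg$n_genes)
    stop("need n_genes >= 2 * n_reversed")
  if (cfg$stability <= 0.5 || cfg$stability > 1)
    stop("stability must lie in (0.5, 1]")
  if (cfg$metastasis_admixture < 0 || cfg$metastasis_admixture > 1)
    stop("metastasis_admixture must lie in [0, 1]")
  if (cfg$noise_sd < 0 || cfg$rank_gap < 0)
    stop("noise_sd and rank_gap must be non-negative")
  if (min(cfg$n_genes, cfg$n_class1, cfg$n_class2, cfg$n_reversed) < 1L)
    stop("counts must be at least 1")
  class(cfg) <- "reo_sim_config"
  cfg
}

# Deterministic gene universe + class mean vectors; shared by both
# generators so metastasis samples live on the same genes and baselines.
#
# Planted marker pairs are placed in a dedicated stratum above the
# background mean range (like dominant tissue markers, which sit at the top
# of the expression distribution).  Each pair gets its own centre, spaced
# 2*offset + 0.1 apart, with the pair's two genes at centre +/- offset and
# the classes swapping the signs.  Because no background gene's mean ever
# falls between the two swapped means (the stratum starts 3.5 noise SDs
# above the background), the planted pairs are the only orderings that
# reverse between classes; background orderings are shared.
sim_model <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  bg_range <- c(4, 12)                     # log2-like baseline means
  mu <- stats::runif(cfg$n_genes, bg_range[1L], bg_range[2L])
  names(mu) <- genes
  planted_idx <- sample(cfg$n_genes, 2L * cfg$n_reversed)
  hi <- planted_idx[seq_len(cfg$n_reversed)]
  lo <- planted_idx[cfg$n_reversed + seq_len(cfg$n_reversed)]
  calib <- if (cfg$noise_sd > 0)
    stats::qnorm(min(cfg$stability, 1 - 1e-12)) * cfg$noise_sd / sqrt(2)
  else 0
  offset <- max(cfg$rank_gap, calib)
  sep <- 3.5 * cfg$noise_sd                # keeps background out of reach
  centre <- bg_range[2L] + offset + sep + 0.1 +
    (2 * offset + 0.1) * (seq_len(cfg$n_reversed) - 1L)
  mu1 <- mu; mu2 <- mu
  mu1[hi] <- centre + offset; mu1[lo] <- centre - offset
  mu2[hi] <- centre - offset; mu2[lo] <- centre + offset
  planted <- reo_pairs(genes[hi], genes[lo])
  list(genes = genes, mu1 = mu1, mu2 = mu2, planted = planted,
       offset = offset)
}

sim_draw <- function(mu, n, noise_sd, prefix) {
  G <- length(mu)
  x <- matrix(mu, G, n) +
    matrix(stats::rnorm(G * n, 0, noise_sd), G, n)
  dimnames(x) <- list(names(mu), sprintf("%s_%02d", prefix, seq_len(n)))
  x
}

#' Generate a two-class dataset with planted reversed pairs
#'
#' Draws class-1 and class-2 expression matrices from the seeded model of
#' [sim_config()]: background genes share their means across classes, the
#' planted pair genes have their mean offsets swapped between classes, so
#' each planted pair is stable in opposite directions in the two classes.
#'
#' @param cfg a [sim_config()].
#' @return list with `class1` and `class2` expression matrices and
#'   `planted`, the planted pairs as a [reo_pairs()] table in class-1
#'   direction.
#' @export
generate_two_class <- function(cfg = sim_config()) {
  mod <- sim_model(cfg)
  x1 <- sim_draw(mod$mu1, cfg$n_class1, cfg$noise_sd, "c1")
  x2 <- sim_draw(mod$mu2, cfg$n_class2, cfg$noise_sd, "c2") + cfg$batch_shift
  list(class1 = x1, class2 = x2, planted = mod$planted)
}

#' Generate metastasis-like samples
#'
#' Samples are drawn from the class-1 model (a metastasis retains the
#' orderings of its tissue of origin), then in each sample a fixed fraction
#' `metastasis_admixture` of the planted pairs — rounded to a whole count,
#' chosen at random per sample — has its two genes' values swapped, flipping
#' those orderings to the class-2 direction.  Swapping values (rather than
#' perturbing magnitudes) guarantees a clean reversal.
#'
#' @param cfg a [sim_config()].
#' @param planted [reo_pairs()] table of planted pairs (class-1 direction);
#'   defaults to the pairs of `cfg`'s own model.
#' @return an expression matrix with `cfg$n_metastasis` columns.
#' @export
generate_metastasis <- function(cfg = sim_config(), planted = NULL) {
  mod <- sim_model(cfg)
  if (is.null(planted)) planted <- mod$planted
  if (nrow(planted) == 0L) stop("planted pair set is empty")
  # separate stream so metastasis noise never replays the class-1 draws
  set.seed(cfg$seed + 1L)
  x <- sim_draw(mod$mu1, cfg$n_metastasis, cfg$noise_sd, "met") -
    cfg$batch_shift
  n_flip <- round(cfg$metastasis_admixture * nrow(planted))
  if (n_flip > 0L) {
    for (s in seq_len(ncol(x))) {
      flip <- sample(nrow(planted), n_flip)
      h <- planted$gene_high[flip]; l <- planted$gene_low[flip]
      tmp <- x[h, s]; x[h, s] <- x[l, s]; x[l, s] <- tmp
    }
  }
  x
}

#' Apply a strictly increasing per-sample distortion
#'
#' Transforms every sample column with a strictly increasing map, leaving
#' all within-sample orderings — and therefore every statistic in this
#' package — unchanged.  Kinds: `"exp"` exponentiates (base 2);
#' `"affine_positive"` applies `slope * x + offset` with `slope > 0`, drawn
#' per sample from the seed when not supplied; `"rank_preserving_spline"`
#' applies a seeded random strictly increasing piecewise-linear map per
#' sample.
#'
#' @param m expression matrix.
#' @param kind distortion kind.
#' @param seed seed for the randomized kinds.
#' @param slope,offset fixed affine coefficients (optional; `slope` must be
#'   positive).
#' @return the distorted matrix, same shape and dimnames.
#' @export
apply_monotone_distortion <- function(m,
                                      kind = c("exp", "affine_positive",
                                               "rank_preserving_spline"),
                                      seed = 1L, slope = NULL, offset = NULL) {
  kind <- match.arg(kind)
  m <- as_expression_matrix(m)
  set.seed(seed)
  out <- m
  for (s in seq_len(ncol(m))) {
    x <- m[, s]
    out[, s] <- switch(kind,
      exp = 2^x,
      affine_positive = {
        a <- slope %||% stats::runif(1, 0.5, 3)
        b <- offset %||% stats::runif(1, -5, 5)
        if (a <= 0) stop("affine slope must be strictly positive")
        a * x + b
      },
      rank_preserving_spline = {
        k <- 8L
        rng <- range(x)
        if (diff(rng) == 0) rng <- rng + c(-1, 1)   # degenerate flat column
        knots_x <- seq(rng[1L], rng[2L], length.out = k)
        knots_y <- cumsum(stats::runif(k, 0.1, 2))
        stats::approx(knots_x, knots_y, xout = x)$y
      })
  }
  out
}
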