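#' Scenario configuration
#'
#' Bundles the generative parameters of one simulation scenario.  Defaults
#' follow the reference study design: 150,000 individuals in both the base
#' (discovery) and target (evaluation) samples, 10 replicates, and a
#' genome-wide significance threshold of 5e-8 for variant selection.
#'
#' @param n_snp Number of causal variants.
#' @param h2 Narrow-sense heritability captured by the causal variants, in
#'   \[0, 1).  Residual phenotypic noise has variance `1 - h2` so the trait
#'   variance is ~1 in every ancestry.
#' @param p_het Proportion of causal variants with ancestry-heterogeneous
#'   effects: each such variant has a non-null effect in exactly one
#'   ancestry and zero elsewhere; the remaining variants share one effect
#'   across all ancestries.
#' @param p_eur Proportion of European-ancestry individuals in the sample;
#'   the four non-EUR ancestries split the remainder equally.
#' @param n_base,n_target Total base and target sample sizes.
#' @param n_replicates Number of simulation replicates.
#' @param seed Master seed; per-cell seeds are derived deterministically.
#' @param lognormal_mu,lognormal_sigma Parameters (natural-log scale) of the
#'   log-normal distribution of effect-size magnitudes.  The per-ancestry
#'   heritability rescaling makes `lognormal_mu` immaterial to variance
#'   explained; `lognormal_sigma` controls the spread of per-variant
#'   contributions.
#' @param pgs_p_threshold Association p-value below which a variant enters a
#'   score (strict inequality).
#' @param n_axes Number of axes of genetic variation used by the
#'   meta-regression.
#' @param het_ancestry Optional fixed carrier ancestry for all heterogeneous
#'   variants; `NULL` (default) assigns each one an ancestry uniformly at
#'   random.
#' @param axes_method `"mds"` (classical metric scaling of mean squared
#'   allele-frequency differences, the construction used by trans-ancestry
#'   meta-regression software) or `"pca"` (principal components of the
#'   subpopulation frequency matrix).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_snp = 500, h2 = 0.5, p_het = 0, p_eur = 0.5,
                            n_base = 150000, n_target = 150000,
                            n_replicates = 10, seed = 42,
                            lognormal_mu = -3, lognormal_sigma = 1,
                            pgs_p_threshold = 5e-8, n_axes = 3,
                            het_ancestry = NULL,
                            axes_method = c("mds", "pca")) {
  axes_method <- match.arg(axes_method)
  cfg <- list(n_snp = as.integer(n_snp), h2 = h2, p_het = p_het,
              p_eur = p_eur, n_base = as.integer(n_base),
              n_target = as.integer(n_target),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed),
              lognormal_mu = lognormal_mu,
              lognormal_sigma = lognormal_sigma,
              pgs_p_threshold = pgs_p_threshold,
              n_axes = as.integer(n_axes),
              het_ancestry = het_ancestry,
              axes_method = axes_method)
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
  chk(cfg$n_snp >= 1, "n_snp must be >= 1")
  chk(cfg$h2 >= 0 && cfg$h2 < 1, "h2 must be in [0, 1)")
  chk(cfg$p_het >= 0 && cfg$p_het <= 1, "p_het must be in [0, 1]")
  chk(cfg$p_eur >= 0 && cfg$p_eur <= 1, "p_eur must be in [0, 1]")
  chk(cfg$n_base >= 1 && cfg$n_target >= 1,
      "n_base and n_target must be >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  chk(cfg$lognormal_sigma > 0, "lognormal_sigma must be > 0")
  chk(cfg$pgs_p_threshold > 0 && cfg$pgs_p_threshold <= 1,
      "pgs_p_threshold must be in (0, 1]")
  chk(cfg$n_axes >= 0, "n_axes must be >= 0")
  invisible(cfg)
}

# Deterministic split of `total` over `k` units: floor, then hand the
# leftover out one-by-one in order.
floor_distribute <- function(total, k) {
  base <- total %/% k
  r <- total - base * k
  base + c(rep(1L, r), rep(0L, k - r))
}

#' Allocate sample sizes over subpopulations
#'
#' `round(p_eur * n_total)` individuals go to the European ancestry, split
#' equally over its subpopulations; the remainder is split equally over the
#' non-EUR ancestries and then over each ancestry's subpopulations.  All
#' splits use floor-then-distribute in the panel's fixed subpopulation
#' order, so totals are exact.
#'
#' @param p_eur Proportion of European-ancestry individuals.
#' @param n_total Total sample size.
#' @param panel A `freq_panel` whose ancestry map defines the groups; must
#'   contain a `EUR` ancestry.
#' @return Named integer vector, one count per subpopulation (panel column
#'   order); sums to `n_total`.
#' @export
allocate_sample_sizes <- function(p_eur, n_total, panel) {
  anc <- panel_ancestries(panel)
  if (!"EUR" %in% anc)
    stop("panel has no EUR ancestry; cannot apply a European-ancestry ",
         "proportion")
  n_total <- as.integer(n_total)
  n_eur <- as.integer(round(p_eur * n_total))
  non_eur <- setdiff(anc, "EUR")
  anc_totals <- stats::setNames(integer(length(anc)), anc)
  anc_totals["EUR"] <- n_eur
  if (length(non_eur))
    anc_totals[non_eur] <- floor_distribute(n_total - n_eur,
                                            length(non_eur))
  out <- stats::setNames(integer(length(panel$subpops)), panel$subpops)
  for (a in anc) {
    sp <- panel$subpops[panel$ancestry_map == a]
    out[sp] <- floor_distribute(anc_totals[[a]], length(sp))
  }
  stopifnot(sum(out) == n_total)
  out
}

#' Draw per-variant, per-ancestry true effect sizes
#'
#' Effect magnitudes are i.i.d. log-normal with parameters
#' `lognormal_mu`/`lognormal_sigma`, with random signs.  A uniformly random
#' subset of `round(p_het * n_snp)` variants is marked heterogeneous: each
#' carries its effect in exactly one ancestry (uniform at random, or the
#' fixed `het_ancestry`) and zero elsewhere; homogeneous variants share the
#' same signed magnitude across all ancestries.  Each ancestry column is
#' then rescaled by `sqrt(h2 / sum_j 2 p_ja (1 - p_ja) beta_ja^2)`, where
#' `p_ja` is the variant's mean frequency over the ancestry's
#' subpopulations, so the expected genetic variance equals `h2` exactly in
#' every ancestry.
#'
#' @param panel A `freq_panel` already restricted to the causal variants.
#' @param config A [scenario_config()].
#' @return An object of class `effect_matrix`: list with `beta` (variants x
#'   ancestries matrix), `het_mask` (logical), `het_ancestry` (character,
#'   `NA` for homogeneous variants), and `ancestry_freqs`.
#' @export
draw_effect_sizes <- function(panel, config) {
  v <- n_variants(panel)
  anc <- panel_ancestries(panel)
  mag <- stats::rlnorm(v, config$lognormal_mu, config$lognormal_sigma)
  b <- mag * sample(c(-1, 1), v, replace = TRUE)
  n_het <- round(config$p_het * v)
  het_idx <- if (n_het > 0) sample.int(v, n_het) else integer(0)
  het_mask <- logical(v)
  het_mask[het_idx] <- TRUE
  het_anc <- rep(NA_character_, v)
  if (n_het > 0) {
    het_anc[het_idx] <- if (is.null(config$het_ancestry))
      sample(anc, n_het, replace = TRUE) else config$het_ancestry
  }
  beta <- matrix(b, nrow = v, ncol = length(anc),
                 dimnames = list(panel$variants, anc))
  for (i in het_idx) {
    keep <- het_anc[i]
    beta[i, ] <- 0
    beta[i, keep] <- b[i]
  }
  af <- ancestry_freqs(panel)
  var_a <- colSums(2 * af * (1 - af) * beta^2)
  if (config$h2 > 0) {
    dead <- names(var_a)[var_a == 0]
    if (length(dead))
      stop("no genetic variance assigned to ancestry ",
           paste(dead, collapse = ", "),
           "; every ancestry needs at least one non-null variant")
    beta <- sweep(beta, 2, sqrt(config$h2 / var_a), "*")
  } else {
    beta[] <- 0
  }
  structure(list(beta = beta, het_mask = het_mask, het_ancestry = het_anc,
                 ancestry_freqs = af),
            class = "effect_matrix")
}

#' Simulate genotypes for one subpopulation
#'
#' Independent allele counts under Hardy-Weinberg equilibrium: entry (i, j)
#' is Binomial(2, p_j) where `p_j` is the subpopulation's effect-allele
#' frequency of variant j.
#'
#' @param freqs Numeric vector of per-variant frequencies in \[0, 1\].
#' @param n Number of individuals.
#' @return Integer matrix, `n` x `length(freqs)`, values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(freqs, n) {
  stopifnot(all(freqs >= 0 & freqs <= 1), n >= 0)
  m <- length(freqs)
  g <- matrix(stats::rbinom(as.double(n) * m, 2L, rep(freqs, each = n)),
              nrow = n, ncol = m)
  colnames(g) <- names(freqs)
  g
}

#' Simulate phenotypes from genotypes
#'
#' `y_i = sum_j (g_ij - 2 p_j) beta_j + e_i` with `e_i ~ N(0, 1 - h2)`.
#' Genotypes are centred at twice the ancestry-level mean frequency so the
#' genetic value has mean ~0 in every subpopulation without using
#' subpopulation labels.
#'
#' @param genotypes Allele-count matrix (individuals x variants).
#' @param beta_anc Per-variant effects for the block's ancestry.
#' @param freq_anc Per-variant ancestry-level mean frequencies used for
#'   centring.
#' @param h2 Heritability; residual noise variance is `1 - h2`.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotypes <- function(genotypes, beta_anc, freq_anc, h2) {
  if (h2 >= 1) stop("h2 must be < 1 (residual variance 1 - h2 must be > 0)")
  n <- nrow(genotypes)
  gv <- as.vector(genotypes %*% beta_anc) - sum(2 * freq_anc * beta_anc)
  gv + stats::rnorm(n, 0, sqrt(1 - h2))
}

#' Simulate a base/target cohort pair
#'
#' Draws one shared set of true effects, then simulates genotypes and
#' phenotypes independently for a base (discovery) and a target (evaluation)
#' cohort from the same subpopulation frequencies and sample-size
#' allocation.  Fully reproducible from `(config$seed, replicate)`.
#'
#' @param panel A `freq_panel` (the full variant pool; `config$n_snp` causal
#'   variants are sampled from it).
#' @param config A [scenario_config()].
#' @param replicate Replicate index (>= 1), part of the seed derivation.
#' @return List with `base` and `target` cohorts (each a list of
#'   per-subpopulation blocks with `genotypes`, `phenotype`, `subpop`,
#'   `ancestry`, `n`), the shared `truth` (`effect_matrix`), and the causal
#'   `panel` subset.
#' @export
simulate_cohort_pair <- function(panel, config, replicate = 1) {
  set.seed(cell_seed(config$seed, config$p_het, config$p_eur, replicate))
  causal <- sample_variants(panel, config$n_snp)
  truth <- draw_effect_sizes(causal, config)
  alloc_b <- allocate_sample_sizes(config$p_eur, config$n_base, causal)
  alloc_t <- allocate_sample_sizes(config$p_eur, config$n_target, causal)
  sim_cohort <- function(alloc) {
    blocks <- lapply(causal$subpops, function(sp) {
      n <- alloc[[sp]]
      a <- causal$ancestry_map[[sp]]
      g <- simulate_genotypes(causal$freqs[, sp], n)
      y <- if (n > 0)
        simulate_phenotypes(g, truth$beta[, a], truth$ancestry_freqs[, a],
                            config$h2)
      else numeric(0)
      list(genotypes = g, phenotype = y, subpop = sp, ancestry = a, n = n)
    })
    stats::setNames(blocks, causal$subpops)
  }
  list(base = sim_cohort(alloc_b), target = sim_cohort(alloc_t),
       truth = truth, panel = causal)
}

#' Derive a deterministic per-cell seed
#'
#' Mixes the master seed with the cell coordinates (heterogeneity and
#' European proportions) and the replicate index so that adding grid points
#' never perturbs existing cells.  The result is a valid 32-bit seed.
#'
#' @param master Master integer seed.
#' @param p_het,p_eur Cell coordinates.
#' @param replicate Replicate index.
#' @return Integer seed in \[0, 2^31 - 2\].
#' @export
cell_seed <- function(master, p_het, p_eur, replicate) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- as.double(master) %% m
  for (v in c(round(p_het * 1e6), round(p_eur * 1e6), replicate)) {
    # multiplicative mixing stays exact in doubles (< 2^53)
    x <- (x * 69069 + as.double(v) + 1) %% m
    x <- (x * 3876547) %% m
  }
  as.integer(x)
}
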