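#' Select variants by association p-value
#'
#' Genome-wide-significance selection: keeps variants whose association
#' p-value is strictly below the threshold.  For the single-effect methods
#' (AS, FETA, RETA) the test is the effect z-test; for the meta-regression
#' it is the joint Wald test over all coefficients.
#'
#' @param p Named (or ordered) vector of per-variant association p-values;
#'   `NA` entries (undefined meta results) are never selected.
#' @param threshold Significance cutoff (default 5e-8).
#' @return Integer indices of the selected variants.
#' @export
select_variants <- function(p, threshold = 5e-8) {
  which(!is.na(p) & p < threshold)
}

#' Build a polygenic-score model from meta-analysis output
#'
#' Constructs one of the four score types from aligned per-study summary
#' statistics:
#' \describe{
#'   \item{AS}{per target ancestry, the fixed-effects combination of that
#'     ancestry's own studies; selection and weights are ancestry-specific.}
#'   \item{FETA}{inverse-variance fixed-effects effect, shared by every
#'     target subpopulation.}
#'   \item{RETA}{DerSimonian-Laird random-effects effect, shared.}
#'   \item{TAMR}{the meta-regression prediction evaluated at each target
#'     subpopulation's coordinates on the axes of genetic variation;
#'     weights are subpopulation-specific.}
#' }
#'
#' @param stats_list List of `gwas_sumstats` (one per base study), aligned
#'   on the same variants.
#' @param method One of `"AS"`, `"FETA"`, `"RETA"`, `"TAMR"`.
#' @param panel The causal-variant `freq_panel` (supplies target
#'   subpopulations and their ancestries).
#' @param axes An `axes_of_variation` (required for TAMR).
#' @param threshold Selection p-value threshold.
#' @return Object of class `pgs_model`: list with `method`, `threshold`,
#'   and `per_subpop`, a named list mapping each target subpopulation to a
#'   data.frame `variant`, `weight` (possibly zero rows).
#' @export
build_pgs_model <- function(stats_list, method = c("AS", "FETA", "RETA",
                                                   "TAMR"),
                            panel, axes = NULL, threshold = 5e-8) {
  method <- match.arg(method)
  m <- sumstats_matrices(stats_list)
  subpops <- panel$subpops
  anc_of <- panel$ancestry_map
  per_subpop <- stats::setNames(vector("list", length(subpops)), subpops)
  if (method %in% c("FETA", "RETA")) {
    res <- if (method == "FETA") fixed_effects_meta(m$beta, m$se)
           else random_effects_meta(m$beta, m$se)
    sel <- select_variants(res$p, threshold)
    wdf <- data.frame(variant = m$variants[sel], weight = res$beta[sel],
                      stringsAsFactors = FALSE)
    for (sp in subpops) per_subpop[[sp]] <- wdf
  } else if (method == "AS") {
    for (a in panel_ancestries(panel)) {
      sps <- subpops[anc_of == a]
      have <- any(m$ancestries == a)
      wdf <- if (have) {
        res <- ancestry_specific_meta(stats_list, a)
        sel <- select_variants(res$p, threshold)
        data.frame(variant = m$variants[sel], weight = res$beta[sel],
                   stringsAsFactors = FALSE)
      } else data.frame(variant = character(0), weight = numeric(0))
      for (sp in sps) per_subpop[[sp]] <- wdf
    }
  } else {
    if (is.null(axes)) stop("TAMR requires axes of genetic variation")
    fit <- mr_mega_fit(m$beta, m$se, axes)
    sel <- select_variants(fit$table$p_assoc, threshold)
    for (sp in subpops) {
      if (!sp %in% rownames(axes$coords)) {
        # no coordinates (subpopulation absent from the base sample):
        # no ancestry-aware prediction is possible there
        per_subpop[[sp]] <- data.frame(variant = character(0),
                                       weight = numeric(0))
        next
      }
      w <- predict_study_effect(fit$alpha[sel, , drop = FALSE],
                                axes$coords[sp, ])
      per_subpop[[sp]] <- data.frame(variant = m$variants[sel],
                                     weight = as.numeric(w),
                                     stringsAsFactors = FALSE)
    }
  }
  structure(list(method = method, threshold = threshold,
                 per_subpop = per_subpop),
            class = "pgs_model")
}

#' @export
print.pgs_model <- function(x, ...) {
  ns <- vapply(x$per_subpop, nrow, 0L)
  cat("<pgs_model> ", x$method, ", p < ", format(x$threshold), "; ",
      min(ns), "-", max(ns), " variants per target subpopulation\n",
      sep = "")
  invisible(x)
}

#' Score individuals with a polygenic-score model
#'
#' `score_i = sum_j w_j g_ij` over the model's selected variants, using the
#' weight vector of the individual's subpopulation.  Raw allele counts are
#' used; centring is unnecessary because variance explained is
#' translation-invariant.
#'
#' @param genotypes Allele-count matrix with columns named by variant.
#' @param model A `pgs_model`.
#' @param subpop Subpopulation label of the individuals.
#' @return Numeric score vector (all zeros for an empty model).
#' @export
score_individuals <- function(genotypes, model, subpop) {
  wdf <- model$per_subpop[[subpop]]
  if (is.null(wdf))
    stop("model has no weights for subpopulation '", subpop, "'")
  if (nrow(wdf) == 0) return(rep(0, nrow(genotypes)))
  miss <- setdiff(wdf$variant, colnames(genotypes))
  if (length(miss))
    stop("genotype matrix lacks model variant(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  as.vector(genotypes[, wdf$variant, drop = FALSE] %*% wdf$weight)
}

#' Variance explained, direct (individual-level) model
#'
#' Squared Pearson correlation between the score and the phenotype,
#' equivalently the R-squared of the univariate regression of phenotype on
#' score.  A constant score (e.g. an empty model) explains nothing and
#' returns 0.
#'
#' @param scores Numeric score vector.
#' @param phenotypes Numeric phenotype vector of equal length.
#' @return R-squared in \[0, 1\].
#' @export
evaluate_direct <- function(scores, phenotypes) {
  if (length(scores) != length(phenotypes))
    stop("scores and phenotypes differ in length")
  if (length(scores) < 3) stop("need at least 3 individuals")
  if (stats::sd(scores) == 0 || stats::sd(phenotypes) == 0) return(0)
  stats::cor(scores, phenotypes)^2
}

#' Variance explained, indirect (summary-statistic) model
#'
#' Approximates the direct R-squared from target-sample GWAS summary
#' statistics without individual-level data, under independent variants and
#' unit phenotypic variance:
#' `cov(PGS, y) = sum_j w_j 2 p_j (1 - p_j) b_j` and
#' `var(PGS) = sum_j w_j^2 2 p_j (1 - p_j)`, where `b_j` is the target
#' study's marginal effect estimate and `p_j` the variant frequency, giving
#' `r2 = cov^2 / var(PGS)` clipped to \[0, 1\].
#'
#' @param model A `pgs_model`.
#' @param target_stats `gwas_sumstats` of the target subpopulation covering
#'   all model variants.
#' @param freqs Named per-variant effect-allele frequencies for the target
#'   subpopulation (defaults to the `eaf` column of `target_stats`).
#' @param subpop Target subpopulation label (defaults to the study label of
#'   `target_stats`).
#' @return Approximate R-squared in \[0, 1\]; 0 for an empty model.
#' @export
evaluate_indirect <- function(model, target_stats, freqs = NULL,
                              subpop = attr(target_stats, "study")) {
  wdf <- model$per_subpop[[subpop]]
  if (is.null(wdf))
    stop("model has no weights for subpopulation '", subpop, "'")
  if (nrow(wdf) == 0) return(0)
  idx <- match(wdf$variant, target_stats$variant)
  if (anyNA(idx))
    stop("target summary statistics lack ", sum(is.na(idx)),
         " model variant(s)")
  b <- target_stats$beta[idx]
  p <- if (is.null(freqs)) target_stats$eaf[idx]
       else unname(freqs[wdf$variant])
  het <- 2 * p * (1 - p)
  covv <- sum(wdf$weight * het * b)
  varv <- sum(wdf$weight^2 * het)
  if (varv <= 0) return(0)
  min(max(covv^2 / varv, 0), 1)
}

#' Aggregate per-subpopulation results to ancestry summaries
#'
#' For each method and ancestry: the per-replicate ancestry value is the
#' arithmetic mean of the ancestry's subpopulation R-squared values; the
#' reported point is the mean over replicates and the error is the standard
#' error of that mean (SD over replicates / sqrt(replicates), 0 with a flag
#' for a single replicate).
#'
#' @param results Data.frame with columns `method`, `ancestry`, `subpop`,
#'   `replicate`, and one or more `r2_*` value columns (as produced by
#'   [run_grid()]); extra grouping columns (`p_het`, `p_eur`, ...) are
#'   carried through.
#' @param value Name of the value column to summarise (default
#'   `"r2_direct"`).
#' @return Data.frame with one row per grouping x method x ancestry:
#'   `mean_r2`, `sem_r2`, `n_replicates`, `sem_defined`.
#' @export
aggregate_results <- function(results, value = "r2_direct") {
  stopifnot(value %in% names(results))
  extra <- intersect(c("p_het", "p_eur", "trait", "scenario"),
                     names(results))
  keys <- c(extra, "method", "ancestry")
  # per-replicate ancestry mean over subpopulations
  agg1 <- stats::aggregate(results[[value]],
                           results[c(keys, "replicate")], mean)
  names(agg1)[ncol(agg1)] <- "anc_r2"
  out <- do.call(rbind, lapply(split(agg1, agg1[keys], drop = TRUE),
    function(d) {
      n <- nrow(d)
      sem <- if (n > 1) stats::sd(d$anc_r2) / sqrt(n) else 0
      cbind(d[1, keys, drop = FALSE],
            data.frame(mean_r2 = mean(d$anc_r2), sem_r2 = sem,
                       n_replicates = n, sem_defined = n > 1))
    }))
  rownames(out) <- NULL
  out[order(out$method, out$ancestry), , drop = FALSE]
}
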