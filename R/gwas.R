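#' Per-subpopulation single-variant association analysis
#'
#' For every variant, ordinary least squares of the phenotype on the allele
#' count with an intercept.  The implementation is vectorised over variants
#' (closed-form simple-regression sums), which is exact OLS.  Two-sided
#' p-values come from the t distribution with `n - 2` degrees of freedom.
#' Monomorphic variants are reported with `beta = 0`, `se = Inf`, `p = 1`
#' so that downstream inverse-variance weights become zero while keeping
#' variant alignment across studies.
#'
#' @param genotypes Allele-count matrix, individuals x variants.
#' @param phenotype Numeric phenotype vector.
#' @param variants Variant identifiers (defaults to genotype column names).
#' @param effect_alleles Per-variant effect alleles (default `"A"`).
#' @param study Study (subpopulation) label.
#' @param ancestry Ancestry label of the study.
#' @return A `gwas_sumstats` data.frame with columns `variant`, `ea`,
#'   `eaf`, `beta`, `se`, `p`, `n` and attributes `study` and `ancestry`.
#' @export
run_gwas <- function(genotypes, phenotype,
                     variants = colnames(genotypes),
                     effect_alleles = rep("A", ncol(genotypes)),
                     study = "study", ancestry = NA_character_) {
  n <- nrow(genotypes)
  if (n < 10) stop("study '", study, "' has fewer than 10 individuals")
  if (length(phenotype) != n)
    stop("phenotype length does not match the genotype matrix")
  if (stats::sd(phenotype) == 0)
    stop("constant phenotype in study '", study, "'")
  if (is.null(variants)) variants <- paste0("v", seq_len(ncol(genotypes)))
  gm <- colMeans(genotypes)
  ym <- mean(phenotype)
  sxx <- colSums(genotypes^2) - n * gm^2
  sxy <- as.vector(crossprod(genotypes, phenotype)) - n * gm * ym
  syy <- sum((phenotype - ym)^2)
  mono <- sxx <= 0
  sxx_safe <- ifelse(mono, 1, sxx)
  beta <- sxy / sxx_safe
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx_safe)
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[mono] <- 0
  se[mono] <- Inf
  p[mono] <- 1
  out <- data.frame(variant = variants, ea = effect_alleles,
                    eaf = gm / 2, beta = beta, se = se, p = p, n = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "study") <- study
  attr(out, "ancestry") <- ancestry
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

#' Write GWAS summary statistics to TSV
#'
#' One file per study with columns `VARIANT  EA  NEA  EAF  BETA  SE  P  N`,
#' the standard summary-statistic exchange layout.  `NEA` is written as
#' `"B"` placeholder when no non-effect allele is tracked.
#'
#' @param stats A `gwas_sumstats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  df <- data.frame(VARIANT = stats$variant, EA = stats$ea, NEA = "B",
                   EAF = stats$eaf, BETA = stats$beta, SE = stats$se,
                   P = stats$p, N = stats$n)
  for (col in c("EAF", "BETA", "SE", "P"))
    df[[col]] <- formatC(df[[col]], digits = 12, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Validates the schema and the invariants (`se > 0`, `p` in (0, 1\]).  A
#' p-value of exactly 0 (underflow in the producing software) is accepted
#' and stored as the smallest positive double, with a message.
#'
#' @param path Path to a summary-statistics TSV.
#' @param study,ancestry Labels attached to the result.
#' @return A `gwas_sumstats` data.frame.
#' @export
read_sumstats <- function(path, study = basename(path),
                          ancestry = NA_character_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("VARIANT", "EA", "EAF", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary-statistics file is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(sapply(df[c("EAF", "BETA", "SE", "P", "N")], is.numeric)))
    stop("non-numeric cells in a numeric summary-statistics column")
  if (any(df$P == 0)) {
    message("read_sumstats: ", sum(df$P == 0),
            " p-value(s) of 0 stored as the smallest positive double")
    df$P[df$P == 0] <- .Machine$double.xmin
  }
  if (any(df$P < 0 | df$P > 1)) stop("p-values outside (0, 1]")
  if (any(df$SE <= 0)) stop("non-positive standard error(s)")
  out <- data.frame(variant = df$VARIANT, ea = df$EA, eaf = df$EAF,
                    beta = df$BETA, se = df$SE, p = df$P, n = df$N,
                    stringsAsFactors = FALSE)
  attr(out, "study") <- study
  attr(out, "ancestry") <- ancestry
  class(out) <- c("gwas_sumstats", "data.frame")
  out
}

# Collect a list of per-study sumstats into aligned matrices
# (variants x studies).  All studies must cover the same variants in the
# same order.
sumstats_matrices <- function(stats_list) {
  stopifnot(length(stats_list) >= 1)
  v <- stats_list[[1]]$variant
  for (s in stats_list)
    if (!identical(s$variant, v))
      stop("summary-statistics studies are not aligned on the same variants")
  grab <- function(col) {
    m <- sapply(stats_list, function(s) s[[col]])
    matrix(m, nrow = length(v),
           dimnames = list(v, vapply(stats_list, attr, "", "study")))
  }
  list(beta = grab("beta"), se = grab("se"), eaf = grab("eaf"),
       n = grab("n"), variants = v,
       studies = vapply(stats_list, attr, "", "study"),
       ancestries = vapply(stats_list, attr, "", "ancestry"))
}
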