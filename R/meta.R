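#' Inverse-variance fixed-effects meta-analysis
#'
#' Per variant: weights `w_k = 1/se_k^2`, combined effect `sum(w b)/sum(w)`,
#' standard error `1/sqrt(sum(w))`, two-sided normal p-value, and Cochran's
#' heterogeneity statistic `Q = sum(w (b - b_FE)^2)`.  Studies with
#' infinite standard error (monomorphic variants) get zero weight.
#' Vectorised over variants: `betas` and `ses` may be matrices (variants x
#' studies) or vectors (one variant).
#'
#' @param betas Per-study effect estimates.
#' @param ses Per-study standard errors (> 0, possibly `Inf`).
#' @return Data.frame with columns `variant` (when row names are present),
#'   `beta`, `se`, `p`, `q`, `k` (number of contributing studies).  Variants
#'   with no finite-SE study have `NA` effect and are flagged in `defined`.
#' @export
fixed_effects_meta <- function(betas, ses) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  stopifnot(identical(dim(betas), dim(ses)), all(ses > 0, na.rm = TRUE))
  w <- 1 / ses^2
  w[!is.finite(w)] <- 0
  b0 <- betas
  b0[w == 0] <- 0
  sw <- rowSums(w)
  k <- rowSums(w > 0)
  defined <- sw > 0
  sw_safe <- ifelse(defined, sw, 1)
  beta <- rowSums(w * b0) / sw_safe
  se <- 1 / sqrt(sw_safe)
  q <- rowSums(w * (b0 - beta)^2)
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[!defined] <- NA_real_
  se[!defined] <- NA_real_
  p[!defined] <- NA_real_
  q[!defined] <- NA_real_
  data.frame(variant = rownames(betas) %||% seq_len(nrow(betas)),
             beta = beta, se = se, p = p, q = q, k = k,
             defined = defined, row.names = NULL,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` from the
#' fixed-effects `Q`, followed by inverse-variance combination with
#' re-weights `1/(se^2 + tau2)`.  With `tau2 = 0` the result equals the
#' fixed-effects analysis.
#'
#' @inheritParams fixed_effects_meta
#' @return Data.frame with `beta`, `se`, `p`, `q`, `tau2`, `k`, `defined`.
#' @export
random_effects_meta <- function(betas, ses) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  fe <- fixed_effects_meta(betas, ses)
  w <- 1 / ses^2
  w[!is.finite(w)] <- 0
  b0 <- betas
  b0[w == 0] <- 0
  sw <- rowSums(w)
  k <- fe$k
  if (any(k < 2 & sw > 0))
    warning("random-effects meta-analysis with a single study; tau2 set ",
            "to 0 for those variants")
  cc <- sw - rowSums(w^2) / ifelse(sw > 0, sw, 1)
  tau2 <- pmax(0, (fe$q - (k - 1)) / ifelse(cc > 0, cc, 1))
  tau2[k < 2] <- 0
  wst <- 1 / (ses^2 + rep(tau2, ncol(ses)))
  wst[w == 0] <- 0
  swst <- rowSums(wst)
  defined <- swst > 0
  sw_safe <- ifelse(defined, swst, 1)
  beta <- rowSums(wst * b0) / sw_safe
  se <- 1 / sqrt(sw_safe)
  p <- 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  beta[!defined] <- NA_real_
  se[!defined] <- NA_real_
  p[!defined] <- NA_real_
  data.frame(variant = fe$variant, beta = beta, se = se, p = p,
             q = fe$q, tau2 = tau2, k = k, defined = defined,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ancestry-specific meta-analysis
#'
#' Fixed-effects combination restricted to the studies (subpopulations) of
#' one ancestry: the summary behind the ancestry-specific (AS) score.
#'
#' @param stats_list List of `gwas_sumstats`, one per study, aligned on the
#'   same variants.
#' @param ancestry Ancestry label to restrict to.
#' @return As [fixed_effects_meta()].
#' @export
ancestry_specific_meta <- function(stats_list, ancestry) {
  anc <- vapply(stats_list, attr, "", "ancestry")
  keep <- which(anc == ancestry)
  if (!length(keep))
    stop("no study of ancestry '", ancestry, "' in the input")
  m <- sumstats_matrices(stats_list[keep])
  fixed_effects_meta(m$beta, m$se)
}

#' Derive axes of genetic variation from a frequency panel
#'
#' The pairwise distance between two studies is the mean over variants of
#' the squared difference of their effect-allele frequencies.  Classical
#' metric multidimensional scaling of this matrix (double-centring and
#' eigendecomposition, via [stats::cmdscale()]) yields per-study
#' coordinates on the top axes, ordered by eigenvalue; each axis's sign is
#' fixed so its largest-magnitude loading is positive.  These coordinates
#' summarise ancestry-scale allele-frequency structure and serve as
#' covariates in the trans-ancestry meta-regression.  `method = "pca"`
#' instead uses principal components of the centred study x variant
#' frequency matrix.
#'
#' @param panel A `freq_panel`.
#' @param studies Ordered study (subpopulation) labels; must be panel
#'   columns.  Defaults to all panel subpopulations.
#' @param n_axes Number of axes `T`; must satisfy `T <= K - 2` for `K`
#'   studies so the meta-regression keeps residual degrees of freedom.
#' @param method `"mds"` (default) or `"pca"`.
#' @return Object of class `axes_of_variation`: list with `coords` (K x T
#'   matrix, rows named by study), `eig` (eigenvalues), `dist` (the K x K
#'   distance matrix), `method`.
#' @export
derive_axes <- function(panel, studies = panel$subpops, n_axes = 3,
                        method = c("mds", "pca")) {
  method <- match.arg(method)
  k <- length(studies)
  if (n_axes > k - 2)
    stop("n_axes (", n_axes, ") must be <= number of studies - 2 (",
         k - 2, ")")
  if (n_variants(panel) < 2) stop("need at least 2 variants to derive axes")
  miss <- setdiff(studies, panel$subpops)
  if (length(miss))
    stop("study label(s) not in the panel: ", paste(miss, collapse = ", "))
  fr <- panel$freqs[, studies, drop = FALSE]
  d2 <- as.matrix(stats::dist(t(fr))^2) / n_variants(panel)
  if (method == "mds") {
    # cmdscale squares its input; pass sqrt so the double-centred matrix
    # is built from the mean squared frequency differences themselves
    mds <- stats::cmdscale(stats::as.dist(sqrt(d2)), k = n_axes,
                           eig = TRUE)
    coords <- mds$points
    eig <- mds$eig
  } else {
    pc <- stats::prcomp(t(fr), center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(n_axes), drop = FALSE]
    eig <- pc$sdev^2
  }
  if (is.null(dim(coords)) || ncol(coords) < n_axes)
    stop("could not extract ", n_axes, " axes (degenerate distances)")
  for (t in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, t]))
    if (coords[i, t] < 0) coords[, t] <- -coords[, t]
  }
  dimnames(coords) <- list(studies, paste0("AXIS", seq_len(n_axes)))
  structure(list(coords = coords, eig = eig, dist = d2, method = method),
            class = "axes_of_variation")
}

#' @export
print.axes_of_variation <- function(x, ...) {
  cat("<axes_of_variation> ", nrow(x$coords), " studies x ",
      ncol(x$coords), " axes (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Trans-ancestry meta-regression of study effects on ancestry axes
#'
#' Per variant, weighted least squares of the per-study effect estimates on
#' an intercept plus the `T` axes of genetic variation, with
#' inverse-variance weights.  Reported per variant:
#' \itemize{
#'   \item coefficients `alpha_0 ... alpha_T`;
#'   \item the association Wald chi-square testing all `T + 1` coefficients
#'     jointly (df `T + 1`), driving variant selection;
#'   \item the ancestry-correlated heterogeneity chi-square testing
#'     `alpha_1 ... alpha_T` (df `T`);
#'   \item the residual heterogeneity chi-square, the weighted residual sum
#'     of squares (df `K - T - 1`).
#' }
#' The ancestry-correlated and residual components partition the
#' intercept-only weighted residual sum of squares (Cochran's Q).
#'
#' @param betas,ses Matrices (variants x studies) of per-study effects and
#'   standard errors, columns ordered as `axes$coords` rows.
#' @param axes An [derive_axes()] result for the same studies.
#' @return Object of class `tamr_fit`: list with `table` (data.frame of
#'   per-variant statistics and p-values) and `alpha` (variants x (T+1)
#'   coefficient matrix).
#' @export
mr_mega_fit <- function(betas, ses, axes) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (is.null(dim(ses))) ses <- matrix(ses, nrow = 1)
  k <- ncol(betas)
  stopifnot(identical(dim(betas), dim(ses)), nrow(axes$coords) == k)
  tt <- ncol(axes$coords)
  x <- cbind(`(Intercept)` = 1, axes$coords)
  v <- nrow(betas)
  alpha <- matrix(NA_real_, v, tt + 1,
                  dimnames = list(rownames(betas),
                                  paste0("ALPHA_", 0:tt)))
  chisq_assoc <- chisq_anc <- chisq_res <- rep(NA_real_, v)
  ok <- logical(v)
  w_all <- 1 / ses^2
  w_all[!is.finite(w_all)] <- 0
  for (j in seq_len(v)) {
    use <- w_all[j, ] > 0
    if (sum(use) < tt + 2) next
    xw <- x[use, , drop = FALSE]
    w <- w_all[j, use]
    a <- crossprod(xw, w * xw)
    b <- crossprod(xw, w * betas[j, use])
    ch <- tryCatch(chol(a), error = function(e) NULL)
    if (is.null(ch)) next
    coef <- backsolve(ch, forwardsolve(t(ch), b))
    alpha[j, ] <- coef
    # with known error variances cov(alpha) = A^-1, so the joint Wald
    # statistic is alpha' A alpha
    chisq_assoc[j] <- drop(crossprod(coef, a %*% coef))
    res <- betas[j, use] - drop(xw %*% coef)
    chisq_res[j] <- sum(w * res^2)
    if (tt > 0) {
      covm <- chol2inv(ch)
      a1 <- coef[-1]
      chisq_anc[j] <- drop(crossprod(a1, solve(covm[-1, -1, drop = FALSE],
                                               a1)))
    } else chisq_anc[j] <- 0
    ok[j] <- TRUE
  }
  keff <- rowSums(w_all > 0)
  tab <- data.frame(
    variant = rownames(betas) %||% seq_len(v),
    chisq_assoc = chisq_assoc, df_assoc = tt + 1,
    p_assoc = pmin(pmax(stats::pchisq(chisq_assoc, tt + 1,
                                      lower.tail = FALSE),
                        .Machine$double.xmin), 1),
    chisq_anc_het = chisq_anc, df_anc_het = tt,
    p_anc_het = stats::pchisq(chisq_anc, pmax(tt, 1), lower.tail = FALSE),
    chisq_res_het = chisq_res, df_res_het = keff - tt - 1,
    p_res_het = stats::pchisq(chisq_res, pmax(keff - tt - 1, 1),
                              lower.tail = FALSE),
    defined = ok, row.names = NULL, stringsAsFactors = FALSE)
  if (tt == 0) tab$p_anc_het <- NA_real_
  structure(list(table = tab, alpha = alpha, axes = axes),
            class = "tamr_fit")
}

#' Predict a study-specific effect from a meta-regression fit
#'
#' Evaluates the fitted regression `alpha_0 + sum_t alpha_t coord_t` at one
#' study's position on the axes of genetic variation: the ancestry-aware
#' per-variant weight used by the meta-regression score.
#'
#' @param alpha Coefficient vector `alpha_0 ... alpha_T` for one variant, or
#'   the full variants x (T+1) matrix from a `tamr_fit`.
#' @param coords Length-`T` coordinate vector for the study.
#' @return Predicted effect (scalar, or vector over variants).
#' @export
predict_study_effect <- function(alpha, coords) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  if (ncol(alpha) != length(coords) + 1)
    stop("coordinate dimension (", length(coords),
         ") does not match the fit (", ncol(alpha) - 1, " axes)")
  drop(alpha %*% c(1, coords))
}
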