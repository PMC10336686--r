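test_that("fixed-effects meta-analysis matches the closed form", {
  # single study is an identity
  one <- fixed_effects_meta(0.1, 0.05)
  expect_equal(one$beta, 0.1)
  expect_equal(one$se, 0.05)

  # hand-evaluated inverse-variance combination:
  # w = (100, 100), beta = 0.2, se = 1/sqrt(200), Q = 100*0.01*2 = 2
  fe <- fixed_effects_meta(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(fe$beta, 0.2, tolerance = 1e-12)
  expect_equal(fe$se, 1 / sqrt(200), tolerance = 1e-12)
  expect_equal(fe$q, 2, tolerance = 1e-12)

  # homogeneous limit
  hom <- fixed_effects_meta(rep(0.07, 5), rep(0.02, 5))
  expect_equal(hom$beta, 0.07)
  expect_equal(hom$q, 0, tolerance = 1e-20)

  # infinite-SE studies are ignored; all-infinite is flagged undefined
  mix <- fixed_effects_meta(matrix(c(0.1, 99), 1), matrix(c(0.05, Inf), 1))
  expect_equal(mix$beta, 0.1)
  expect_equal(mix$k, 1)
  none <- fixed_effects_meta(matrix(c(1, 2), 1), matrix(c(Inf, Inf), 1))
  expect_false(none$defined)
  expect_true(is.na(none$beta))

  # combined SE never exceeds any contributing study SE
  set.seed(31)
  b <- matrix(rnorm(200), 50)
  s <- matrix(runif(200, 0.05, 0.5), 50)
  fe2 <- fixed_effects_meta(b, s)
  expect_true(all(fe2$se <= apply(s, 1, min) + 1e-15))
})

test_that("DerSimonian-Laird random effects match hand arithmetic", {
  # Q = 8, C = 200 - 20000/200 = 100, tau2 = 7/100, beta unchanged by
  # symmetry
  re <- random_effects_meta(c(0.0, 0.4), c(0.1, 0.1))
  expect_equal(re$q, 8, tolerance = 1e-12)
  expect_equal(re$tau2, 0.07, tolerance = 1e-12)
  expect_equal(re$beta, 0.2, tolerance = 1e-12)
  expect_equal(re$se, sqrt(1 / (2 / (0.01 + 0.07))), tolerance = 1e-12)

  # no heterogeneity: tau2 truncates to 0 and the result equals FE
  ident <- random_effects_meta(rep(0.1, 4), rep(0.05, 4))
  fe <- fixed_effects_meta(rep(0.1, 4), rep(0.05, 4))
  expect_equal(ident$tau2, 0)
  expect_equal(ident$beta, fe$beta)
  expect_equal(ident$se, fe$se)

  # Q < K-1 also truncates
  set.seed(32)
  b <- c(0.10, 0.101, 0.099)
  tr <- random_effects_meta(b, rep(0.1, 3))
  expect_equal(tr$tau2, 0)
  expect_equal(tr$beta, fixed_effects_meta(b, rep(0.1, 3))$beta)

  # RE standard error is never below the FE standard error
  bm <- matrix(rnorm(200), 50)
  sm <- matrix(runif(200, 0.05, 0.5), 50)
  expect_true(all(random_effects_meta(bm, sm)$se >=
                  fixed_effects_meta(bm, sm)$se - 1e-15))

  # metafor as an independent oracle for the DL estimator
  set.seed(33)
  yi <- rnorm(8, 0.2, 0.1)
  sei <- runif(8, 0.05, 0.2)
  ours <- random_effects_meta(yi, sei)
  ref <- metafor::rma(yi = yi, sei = sei, method = "DL")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("fixed-effects p-values are uniform under the null", {
  set.seed(34)
  n_var <- 5000
  k <- 8
  se <- matrix(runif(n_var * k, 0.05, 0.2), n_var)
  b <- matrix(rnorm(n_var * k, 0, se), n_var)
  fe <- fixed_effects_meta(b, se)
  expect_gt(stats::ks.test(fe$p, "punif")$p.value, 0.01)
})

test_that("axes of variation separate ancestries", {
  pan <- shared_panel()
  axes <- derive_axes(pan, n_axes = 3)
  expect_equal(dim(axes$coords), c(20, 3))
  # distance matrix is symmetric with a zero diagonal
  expect_equal(axes$dist, t(axes$dist))
  expect_true(all(diag(axes$dist) == 0))
  # sign fix: the largest-magnitude loading on each axis is positive
  for (t in 1:3)
    expect_gt(axes$coords[which.max(abs(axes$coords[, t])), t], 0)
  # studies cluster by ancestry on the axes
  amap <- pan$ancestry_map
  d <- as.matrix(stats::dist(axes$coords))
  same <- outer(amap, amap, "==") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[(!outer(amap, amap, "==")) &
                                  upper.tri(d)]))

  # identical frequency vectors collapse onto the same coordinates
  amap2 <- default_ancestry_map()
  fr <- matrix(runif(40 * 20, 0.1, 0.9), 40,
               dimnames = list(NULL, names(amap2)))
  fr[, "LWK"] <- fr[, "GWD"]
  twin <- freq_panel(paste0("v", 1:40), rep("A", 40), fr, amap2)
  ax2 <- derive_axes(twin, n_axes = 3)
  expect_equal(ax2$coords["GWD", ], ax2$coords["LWK", ], tolerance = 1e-8)

  # dimension guard: T must leave residual degrees of freedom
  expect_error(derive_axes(pan, n_axes = 19), "n_axes")
  # the PCA construction also separates ancestries
  axp <- derive_axes(pan, n_axes = 3, method = "pca")
  dp <- as.matrix(stats::dist(axp$coords))
  expect_lt(mean(dp[same]), mean(dp[(!outer(amap, amap, "==")) &
                                    upper.tri(dp)]))
})

test_that("meta-regression matches a weighted least-squares oracle", {
  pan <- shared_panel()
  axes <- derive_axes(pan, n_axes = 3)
  set.seed(35)
  n_var <- 40
  k <- 20
  se <- matrix(runif(n_var * k, 0.02, 0.2), n_var,
               dimnames = list(paste0("v", 1:n_var), pan$subpops))
  b <- matrix(rnorm(n_var * k, 0.1, 0.15), n_var,
              dimnames = dimnames(se))
  fit <- mr_mega_fit(b, se, axes)
  # brute-force oracle: weighted lm per variant
  for (j in c(1, 7, 23)) {
    o <- stats::lm(b[j, ] ~ axes$coords, weights = 1 / se[j, ]^2)
    expect_equal(unname(fit$alpha[j, ]), unname(stats::coef(o)),
                 tolerance = 1e-8)
    expect_equal(fit$table$chisq_res_het[j],
                 sum(stats::resid(o)^2 / se[j, ]^2), tolerance = 1e-8)
  }
  # partition identity: ancestry-correlated + residual heterogeneity
  # equal the intercept-only weighted residual sum of squares (Cochran Q)
  fe <- fixed_effects_meta(b, se)
  expect_equal(fit$table$chisq_anc_het + fit$table$chisq_res_het, fe$q,
               tolerance = 1e-8)
  expect_true(all(fit$table$chisq_assoc >= 0))
  expect_true(all(fit$table$chisq_anc_het >= -1e-12))

  # T = 0 reduces to the fixed-effects analysis
  ax0 <- axes
  ax0$coords <- axes$coords[, integer(0), drop = FALSE]
  fit0 <- mr_mega_fit(b, se, ax0)
  expect_equal(unname(fit0$alpha[, 1]), fe$beta, tolerance = 1e-10)
  expect_equal(stats::pchisq(fit0$table$chisq_assoc, 1,
                             lower.tail = FALSE),
               fe$p, tolerance = 1e-10)

  # an exactly linear effect surface is recovered with zero residual
  b_lin <- matrix(rep(0.1 + 0.2 * axes$coords[, 1], each = n_var), n_var,
                  dimnames = dimnames(se))
  se_eq <- matrix(0.05, n_var, k, dimnames = dimnames(se))
  fit_lin <- mr_mega_fit(b_lin, se_eq, axes)
  expect_equal(unname(fit_lin$alpha[1, 1:2]), c(0.1, 0.2),
               tolerance = 1e-8)
  expect_lt(max(fit_lin$table$chisq_res_het), 1e-8)
  # interpolation of the perfect fit returns each study's own effect
  pred <- predict_study_effect(fit_lin$alpha[1, ], axes$coords["GWD", ])
  expect_equal(pred, b_lin[1, "GWD"], tolerance = 1e-8)
})

test_that("study-effect prediction is affine in the coordinates", {
  alpha <- c(0.3, -0.1, 0.2, 0.05)
  c1 <- c(1, 2, 3)
  c2 <- c(-0.5, 0.1, 0)
  expect_equal(predict_study_effect(alpha, c1) +
               predict_study_effect(alpha, c2) -
               predict_study_effect(alpha, c(0, 0, 0)),
               predict_study_effect(alpha, c1 + c2), tolerance = 1e-12)
  expect_error(predict_study_effect(alpha, c(1, 2)), "dimension")
})

test_that("ancestry-specific meta-analysis isolates its ancestry", {
  pan <- shared_panel()
  sub <- sample_variants(pan, 30, seed = 36)
  set.seed(36)
  mk <- function(sp, anc, beta) {
    st <- data.frame(variant = sub$variants, ea = "A", eaf = 0.5,
                     beta = beta, se = 0.05, p = 0.5, n = 1000)
    attr(st, "study") <- sp
    attr(st, "ancestry") <- anc
    class(st) <- c("gwas_sumstats", "data.frame")
    st
  }
  afr <- names(pan$ancestry_map)[pan$ancestry_map == "AFR"]
  eur <- names(pan$ancestry_map)[pan$ancestry_map == "EUR"]
  stats_list <- c(lapply(afr, mk, anc = "AFR", beta = 0.1),
                  lapply(eur, mk, anc = "EUR", beta = 0.9))
  as_afr <- ancestry_specific_meta(stats_list, "AFR")
  # four equal studies: same beta, half the standard error of one study
  expect_equal(as_afr$beta, rep(0.1, 30))
  expect_equal(as_afr$se, rep(0.025, 30))
  # perturbing non-AFR studies leaves the AFR result unchanged
  stats_list2 <- c(stats_list[1:4], lapply(eur, mk, anc = "EUR",
                                           beta = -5))
  expect_equal(ancestry_specific_meta(stats_list2, "AFR")$beta,
               as_afr$beta)
  # single study is a passthrough
  one <- ancestry_specific_meta(stats_list[1], "AFR")
  expect_equal(one$beta, rep(0.1, 30))
  expect_equal(one$se, rep(0.05, 30))
  expect_error(ancestry_specific_meta(stats_list, "OCE"), "OCE")
})
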