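test_that("variant selection applies a strict threshold", {
  p <- c(5e-8, 1e-9, 1e-9, 1e-9, rep(1e-7, 6))
  expect_equal(select_variants(p, 5e-8), 2:4)   # boundary value excluded
  expect_length(select_variants(rep(1, 5), 5e-8), 0)
  expect_length(select_variants(c(NA, 1e-10), 5e-8), 1)
})

test_that("score models carry the right weights per method", {
  pan <- sample_variants(shared_panel(), 80, seed = 41)
  cfg <- tiny_config(n_snp = 80, p_het = 0.3, n_base = 4000)
  set.seed(cell_seed(cfg$seed, cfg$p_het, cfg$p_eur, 1))
  eff <- draw_effect_sizes(pan, cfg)
  alloc <- allocate_sample_sizes(0.5, 4000, pan)
  stats_list <- lapply(pan$subpops, function(sp) {
    a <- pan$ancestry_map[[sp]]
    g <- simulate_genotypes(pan$freqs[, sp], alloc[[sp]])
    y <- simulate_phenotypes(g, eff$beta[, a], eff$ancestry_freqs[, a],
                             cfg$h2)
    run_gwas(g, y, variants = pan$variants, study = sp, ancestry = a)
  })
  axes <- derive_axes(pan, n_axes = 3)
  # use a permissive threshold so every method selects something at this n
  thr <- 1e-4
  m_feta <- build_pgs_model(stats_list, "FETA", pan, threshold = thr)
  m_reta <- build_pgs_model(stats_list, "RETA", pan, threshold = thr)
  m_as <- build_pgs_model(stats_list, "AS", pan, threshold = thr)
  m_tamr <- build_pgs_model(stats_list, "TAMR", pan, axes = axes,
                            threshold = thr)
  # FETA/RETA weights identical for every target subpopulation
  expect_identical(m_feta$per_subpop$GWD, m_feta$per_subpop$FIN)
  expect_identical(m_reta$per_subpop$CDX, m_reta$per_subpop$PUR)
  expect_gt(nrow(m_feta$per_subpop$GWD), 0)
  # AS weights shared within an ancestry, independent across
  expect_identical(m_as$per_subpop$GWD, m_as$per_subpop$YRI)
  # TAMR weights differ between AFR and EUR targets when axes matter
  sel_t <- m_tamr$per_subpop$GWD$variant
  if (length(sel_t))
    expect_false(isTRUE(all.equal(m_tamr$per_subpop$GWD$weight,
                                  m_tamr$per_subpop$FIN$weight)))
  expect_error(build_pgs_model(stats_list, "TAMR", pan), "axes")

  # scoring: empty model scores 0 and evaluates to R2 = 0
  empty <- build_pgs_model(stats_list, "FETA", pan, threshold = 1e-300)
  g <- simulate_genotypes(pan$freqs[, "GWD"], 50)
  colnames(g) <- pan$variants
  expect_equal(score_individuals(g, empty, "GWD"), rep(0, 50))
  y <- rnorm(50)
  expect_equal(evaluate_direct(score_individuals(g, empty, "GWD"), y), 0)
  expect_equal(evaluate_indirect(empty, stats_list[[1]], subpop = "GWD"),
               0)

  # single variant with weight 1 scores the allele count; doubling the
  # weights leaves R2 unchanged
  one <- m_feta
  one$per_subpop <- lapply(one$per_subpop, function(...)
    data.frame(variant = pan$variants[1], weight = 1))
  expect_equal(score_individuals(g, one, "GWD"), unname(g[, 1]))
  s1 <- score_individuals(g, m_feta, "GWD")
  two <- m_feta
  two$per_subpop$GWD$weight <- 2 * two$per_subpop$GWD$weight
  s2 <- score_individuals(g, two, "GWD")
  expect_equal(s2, 2 * s1)
  yy <- rnorm(50) + 0.1 * s1
  expect_equal(evaluate_direct(s1, yy), evaluate_direct(s2, yy),
               tolerance = 1e-12)
})

test_that("direct evaluation is the squared Pearson correlation", {
  set.seed(42)
  y <- rnorm(1000)
  expect_equal(evaluate_direct(y, y), 1)
  expect_equal(evaluate_direct(-y, y), 1)
  s <- rnorm(1000)
  expect_equal(evaluate_direct(s, y), cor(s, y)^2, tolerance = 1e-12)
  expect_lt(evaluate_direct(s, y), 0.02)  # independent: R2 ~ 1/n
  expect_error(evaluate_direct(s, y[-1]), "length")
  expect_error(evaluate_direct(1:2, 1:2), "3")
})

test_that("indirect evaluation matches its closed form and the direct
           estimate at scale", {
  # single variant with w = b and matching frequency: r2 = b^2 2p(1-p)
  st <- data.frame(variant = "v1", ea = "A", eaf = 0.3, beta = 0.2,
                   se = 0.01, p = 1e-10, n = 1000)
  attr(st, "study") <- "GWD"
  class(st) <- c("gwas_sumstats", "data.frame")
  model <- structure(list(method = "FETA", threshold = 5e-8,
                          per_subpop = list(GWD = data.frame(
                            variant = "v1", weight = 0.2))),
                     class = "pgs_model")
  expect_equal(evaluate_indirect(model, st, subpop = "GWD"),
               0.2^2 * 2 * 0.3 * 0.7, tolerance = 1e-12)
  expect_error(evaluate_indirect(model, transform(st, variant = "zz"),
                                 subpop = "GWD"), "lack")

  # on a simulated scenario the two estimators agree per subpopulation
  pan <- shared_panel()
  cfg <- tiny_config(n_snp = 120, p_het = 0, n_base = 20000,
                     n_target = 20000, seed = 77)
  res <- run_scenario_cell(pan, cfg, replicate = 1,
                           methods = c("FETA", "TAMR"))
  sel <- res$n_snps > 5 & res$r2_direct > 0.02
  expect_gt(sum(sel), 5)
  rel <- abs(res$r2_indirect[sel] - res$r2_direct[sel]) /
    res$r2_direct[sel]
  expect_lt(stats::median(rel), 0.2)
})

test_that("aggregation averages subpopulations then replicates", {
  base <- expand.grid(method = "FETA", ancestry = "AFR",
                      subpop = c("GWD", "LWK", "MSL", "YRI"),
                      replicate = 1, stringsAsFactors = FALSE)
  base$p_het <- 0; base$p_eur <- 0.5
  base$r2_direct <- c(0.1, 0.2, 0.3, 0.4)
  agg <- aggregate_results(base)
  expect_equal(agg$mean_r2, 0.25)
  expect_equal(agg$sem_r2, 0)
  expect_false(agg$sem_defined)

  # replicate means (0.2, 0.3): mean 0.25, SEM = sd/sqrt(2) = 0.05
  two <- rbind(transform(base, r2_direct = 0.2, replicate = 1),
               transform(base, r2_direct = 0.3, replicate = 2))
  agg2 <- aggregate_results(two)
  expect_equal(agg2$mean_r2, 0.25)
  expect_equal(agg2$sem_r2, 0.05, tolerance = 1e-12)
  expect_true(agg2$sem_defined)

  # identical replicates: SEM exactly 0
  ten <- do.call(rbind, lapply(1:10, function(r)
    transform(base, replicate = r)))
  expect_equal(aggregate_results(ten)$sem_r2, 0)
})
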