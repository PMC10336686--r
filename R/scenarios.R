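#' Run one simulation cell (single replicate)
#'
#' Executes the full pipeline for one (p_het, p_eur, replicate) cell:
#' sample causal variants, draw true effects, simulate the base cohort
#' block-by-block and run per-subpopulation GWAS, combine the summary
#' statistics with the four meta-analysis methods, build the four scores,
#' then simulate the target cohort and measure variance explained per
#' subpopulation under the direct and indirect models.  Genotype blocks are
#' simulated, used and discarded one subpopulation at a time, so memory
#' stays at one block rather than a full cohort.
#'
#' @param panel A `freq_panel` (full variant pool).
#' @param config A [scenario_config()]; its `p_het`/`p_eur` are overridden
#'   by the explicit arguments when given.
#' @param p_het,p_eur Cell coordinates (default from `config`).
#' @param replicate Replicate index (seed derivation input).
#' @param methods Score methods to evaluate.
#' @return Data.frame with one row per method x subpopulation: `method`,
#'   `ancestry`, `subpop`, `replicate`, `p_het`, `p_eur`, `r2_direct`,
#'   `r2_indirect`, `n_snps`.
#' @export
run_scenario_cell <- function(panel, config, p_het = config$p_het,
                              p_eur = config$p_eur, replicate = 1,
                              methods = c("AS", "FETA", "RETA", "TAMR")) {
  set.seed(cell_seed(config$seed, p_het, p_eur, replicate))
  cfg <- config
  cfg$p_het <- p_het
  cfg$p_eur <- p_eur
  causal <- sample_variants(panel, cfg$n_snp)
  truth <- draw_effect_sizes(causal, cfg)
  alloc_b <- allocate_sample_sizes(p_eur, cfg$n_base, causal)
  alloc_t <- allocate_sample_sizes(p_eur, cfg$n_target, causal)

  # base cohort: per-block GWAS, genotypes discarded immediately
  base_stats <- list()
  for (sp in causal$subpops) {
    n <- alloc_b[[sp]]
    if (n < 10) next
    a <- causal$ancestry_map[[sp]]
    g <- simulate_genotypes(causal$freqs[, sp], n)
    y <- simulate_phenotypes(g, truth$beta[, a], truth$ancestry_freqs[, a],
                             cfg$h2)
    base_stats[[sp]] <- run_gwas(g, y, variants = causal$variants,
                                 effect_alleles =
                                   unname(causal$effect_alleles),
                                 study = sp, ancestry = a)
    rm(g, y)
  }
  if (!length(base_stats))
    stop("no base study has >= 10 individuals; increase n_base")

  axes <- derive_axes(causal, names(base_stats),
                      n_axes = min(cfg$n_axes, length(base_stats) - 2),
                      method = cfg$axes_method)
  models <- lapply(stats::setNames(methods, methods), function(m)
    build_pgs_model(base_stats, m, causal, axes = axes,
                    threshold = cfg$pgs_p_threshold))

  # target cohort: score, evaluate, discard
  rows <- list()
  for (sp in causal$subpops) {
    n <- alloc_t[[sp]]
    if (n < 10) next
    a <- causal$ancestry_map[[sp]]
    g <- simulate_genotypes(causal$freqs[, sp], n)
    y <- simulate_phenotypes(g, truth$beta[, a], truth$ancestry_freqs[, a],
                             cfg$h2)
    tstats <- run_gwas(g, y, variants = causal$variants,
                       effect_alleles = unname(causal$effect_alleles),
                       study = sp, ancestry = a)
    for (m in methods) {
      sc <- score_individuals(g, models[[m]], sp)
      rows[[length(rows) + 1]] <- data.frame(
        method = m, ancestry = a, subpop = sp, replicate = replicate,
        p_het = p_het, p_eur = p_eur,
        r2_direct = evaluate_direct(sc, y),
        r2_indirect = evaluate_indirect(models[[m]], tstats,
                                        freqs = stats::setNames(
                                          causal$freqs[, sp],
                                          causal$variants),
                                        subpop = sp),
        n_snps = nrow(models[[m]]$per_subpop[[sp]]),
        stringsAsFactors = FALSE)
    }
    rm(g, y, tstats)
  }
  do.call(rbind, rows)
}

#' Run a scenario grid
#'
#' Replicated pipeline runs over the cross of heterogeneity proportions and
#' European-ancestry proportions.  Each cell x replicate is seeded
#' deterministically from the master seed via [cell_seed()], so the grid is
#' a pure function of (panel, config, seed) and adding grid points never
#' changes existing cells.  With `out_dir` set, finished cells are written
#' as TSV and skipped on re-run, making interrupted grids resumable with
#' bit-identical results.
#'
#' @param panel A `freq_panel`.
#' @param config A [scenario_config()] (its `n_replicates` and `seed` drive
#'   the grid).
#' @param p_het_values,p_eur_values Grid coordinates.
#' @param methods Score methods to evaluate.
#' @param out_dir Optional directory for per-cell result TSVs.
#' @param verbose Print per-cell progress messages.
#' @return Tidy data.frame: rows as in [run_scenario_cell()] over all
#'   cells and replicates.  Cells that fail are recorded in the
#'   `failures` attribute and the run continues.
#' @export
run_grid <- function(panel, config, p_het_values = config$p_het,
                     p_eur_values = config$p_eur,
                     methods = c("AS", "FETA", "RETA", "TAMR"),
                     out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out <- list()
  failures <- list()
  for (ph in p_het_values) for (pe in p_eur_values) {
    cell_file <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("cell_phet%s_peur%s.tsv",
                                 format(ph), format(pe)))
    if (!is.null(out_dir) && file.exists(cell_file)) {
      out[[length(out) + 1]] <- utils::read.table(cell_file, header = TRUE,
                                                  sep = "\t",
                                                  stringsAsFactors = FALSE)
      next
    }
    cell_rows <- list()
    ok <- TRUE
    for (r in seq_len(config$n_replicates)) {
      if (verbose)
        message(sprintf("cell p_het=%g p_eur=%g replicate %d", ph, pe, r))
      res <- tryCatch(run_scenario_cell(panel, config, ph, pe, r, methods),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(p_het = ph, p_eur = pe, replicate = r,
                     message = conditionMessage(res))
        ok <- FALSE
        next
      }
      cell_rows[[length(cell_rows) + 1]] <- res
    }
    cell_df <- do.call(rbind, cell_rows)
    if (!is.null(cell_df)) {
      if (!is.null(out_dir) && ok)
        utils::write.table(cell_df, cell_file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
      out[[length(out) + 1]] <- cell_df
    }
  }
  res <- do.call(rbind, out)
  attr(res, "failures") <- if (length(failures)) do.call(rbind, failures)
  res
}

#' Built-in real-trait scenario presets
#'
#' Two complex-trait configurations used for study-design exploration:
#' triglyceride levels (`TG`: h2 = 0.42, 1% heterogeneous variants, 20.2%
#' non-EUR discovery share) and type-2 diabetes liability (`T2D`: h2 =
#' 0.31, 30% heterogeneous variants, 48.9% non-EUR share; simulated as the
#' continuous underlying liability).  Heritabilities come from family
#' studies and the heterogeneity proportions from trans-ancestry
#' meta-regression estimates on the respective consortium meta-analyses.
#' The causal-variant count is a configurable default.
#'
#' @param trait `"TG"` or `"T2D"`.
#' @param n_snp Number of causal variants (default 2000; reduce for
#'   smaller-scale runs).
#' @return List of class `trait_scenario` with fields `trait`, `h2`,
#'   `p_het`, `p_eur_start`, `n_snp`, `scale`.
#' @export
trait_scenario <- function(trait = c("TG", "T2D"), n_snp = 2000) {
  trait <- match.arg(trait)
  preset <- switch(trait,
    TG  = list(h2 = 0.42, p_het = 0.01, p_eur_start = 1 - 0.202,
               scale = "quantitative"),
    T2D = list(h2 = 0.31, p_het = 0.30, p_eur_start = 1 - 0.489,
               scale = "liability"))
  structure(c(list(trait = trait, n_snp = as.integer(n_snp)), preset),
            class = "trait_scenario")
}

#' Run a real-trait scenario over a European-proportion sweep
#'
#' Applies the full pipeline under a [trait_scenario()] preset for a
#' descending sweep of European-ancestry proportions, starting at the
#' composition of the trait's source meta-analysis.  Liability-scale traits
#' are simulated as the continuous liability (no case/control
#' dichotomisation).
#'
#' @param trait A [trait_scenario()] or a trait name.
#' @param panel A `freq_panel`.
#' @param p_eur_sweep European proportions, descending; defaults to the
#'   preset's starting composition followed by 0.6, 0.4, 0.2.
#' @param config A [scenario_config()] supplying sample sizes, replicates,
#'   seed and threshold; its `n_snp`, `h2`, `p_het` are overridden by the
#'   preset.
#' @param ... Passed to [run_grid()].
#' @return Tidy results data.frame with a `trait` column.
#' @export
run_trait_scenario <- function(trait, panel, p_eur_sweep = NULL,
                               config = scenario_config(), ...) {
  if (is.character(trait)) trait <- trait_scenario(trait)
  cfg <- config
  cfg$n_snp <- trait$n_snp
  cfg$h2 <- trait$h2
  cfg$p_het <- trait$p_het
  if (is.null(p_eur_sweep)) {
    p_eur_sweep <- sort(unique(c(trait$p_eur_start,
                                 c(0.6, 0.4, 0.2)[
                                   c(0.6, 0.4, 0.2) < trait$p_eur_start])),
                        decreasing = TRUE)
  }
  res <- run_grid(panel, cfg, p_het_values = trait$p_het,
                  p_eur_values = p_eur_sweep, ...)
  res$trait <- trait$trait
  res
}

#' Relative performance difference between two score methods
#'
#' `100 * (mean R2_a - mean R2_b) / mean R2_b`, where each method's mean is
#' taken over the named ancestries' replicate means at one grid cell: the
#' headline "method a explains x% more variance than method b" number.
#'
#' @param results Tidy results (from [run_grid()] or
#'   [run_trait_scenario()]).
#' @param method_a,method_b Method labels to compare.
#' @param ancestries Ancestry labels to average over (default: all
#'   non-European ancestries present).
#' @param p_eur,p_het Optional cell filters.
#' @param value Value column (default `"r2_direct"`).
#' @return Relative difference in percent; `NaN` with a warning when the
#'   reference mean is zero.
#' @export
summarize_relative_performance <- function(results, method_a, method_b,
                                           ancestries = NULL, p_eur = NULL,
                                           p_het = NULL,
                                           value = "r2_direct") {
  d <- results
  if (!is.null(p_eur)) d <- d[abs(d$p_eur - p_eur) < 1e-9, ]
  if (!is.null(p_het)) d <- d[abs(d$p_het - p_het) < 1e-9, ]
  if (is.null(ancestries))
    ancestries <- setdiff(unique(d$ancestry), "EUR")
  d <- d[d$ancestry %in% ancestries, ]
  if (!all(c(method_a, method_b) %in% d$method))
    stop("both methods must be present in the filtered results")
  mean_of <- function(m) mean(d[[value]][d$method == m])
  ma <- mean_of(method_a)
  mb <- mean_of(method_b)
  if (mb == 0) {
    warning("reference method mean is zero; relative difference undefined")
    return(NaN)
  }
  100 * (ma - mb) / mb
}
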