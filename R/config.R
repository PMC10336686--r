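#' Load and validate a scenario configuration file
#'
#' Reads a YAML (or simple `key: value`) configuration and returns a
#' validated [scenario_config()], optionally wrapped with grid or trait
#' information.  Unknown keys are rejected, with a nearest-match suggestion
#' for likely typos; every value is checked against its allowed range and
#' defaults are applied for absent keys.
#'
#' Recognised keys: the [scenario_config()] fields (`n_snp`, `h2`,
#' `p_het`, `p_eur`, `n_base`, `n_target`, `n_replicates`, `seed`,
#' `lognormal_mu`, `lognormal_sigma`, `pgs_p_threshold`, `n_axes`,
#' `het_ancestry`, `axes_method`) plus the optional orchestration keys
#' `p_het_values`, `p_eur_values`, `methods`, `trait`.
#'
#' @param path Path to the configuration file.
#' @return A list with `config` (a `scenario_config`), and when present
#'   `p_het_values`, `p_eur_values`, `methods`, `trait`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("configuration file must be a key-value mapping")
  scen_keys <- setdiff(names(formals(scenario_config)), "...")
  grid_keys <- c("p_het_values", "p_eur_values", "methods", "trait")
  known <- c(scen_keys, grid_keys)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    # long-form synonyms a user might plausibly write
    aliases <- c(heritability = "h2", heterogeneity = "p_het",
                 eur_proportion = "p_eur", threshold = "pgs_p_threshold",
                 replicates = "n_replicates")
    cand <- c(stats::setNames(known, known), aliases)
    hints <- vapply(unknown, function(k) {
      d <- utils::adist(k, names(cand))
      if (min(d) <= 3)
        paste0(" (did you mean '", cand[[which.min(d)]], "'?)")
      else ""
    }, "")
    stop("unknown configuration key(s): ",
         paste0("'", unknown, "'", hints, collapse = ", "))
  }
  cfg <- do.call(scenario_config, raw[intersect(names(raw), scen_keys)])
  out <- list(config = cfg)
  for (k in grid_keys) if (!is.null(raw[[k]])) out[[k]] <- raw[[k]]
  if (!is.null(out$trait) && !out$trait %in% c("TG", "T2D"))
    stop("trait must be one of: TG, T2D")
  if (!is.null(out$methods)) {
    bad <- setdiff(out$methods, c("AS", "FETA", "RETA", "TAMR"))
    if (length(bad))
      stop("unknown method(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Write a run manifest
#'
#' Records beside a run's outputs everything needed to reproduce it:
#' the configuration snapshot, master seed, package version, timestamps,
#' and an MD5 digest of every input/output file.
#'
#' @param path Manifest output path (JSON).
#' @param config The configuration used (list or `scenario_config`).
#' @param files Character vector of files to digest.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, files = character(0),
                           extra = list()) {
  files <- files[file.exists(files)]
  manifest <- c(list(
    tool = "transpgs",
    version = as.character(utils::packageVersion("transpgs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    files = if (length(files))
      stats::setNames(as.list(tools::md5sum(files)), basename(files))
    else list()), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Command-line entry point
#'
#' Dispatches the `transpgs` subcommands (`synth-panel`, `simulate`,
#' `gwas`, `meta`, `pgs`, `run-scenario`, `summarize`).  Intended to be
#' called from the thin wrapper script shipped in `inst/cli/`; see
#' `transpgs_main(c("--help"))` for usage.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status (0 success, 2 usage error), invisibly.
#' @export
transpgs_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: transpgs <subcommand> [options]\n\n",
        "subcommands:\n",
        "  synth-panel   --n-variants N [--fst-ancestry F] [--fst-subpop F]\n",
        "                [--seed S] --out panel.tsv\n",
        "  simulate      --config cfg.yaml --panel panel.tsv\n",
        "                [--replicate R] --out-prefix dir/prefix\n",
        "  gwas          --genotypes g.tsv --phenotypes ph.tsv\n",
        "                --study SP --ancestry ANC --out stats.tsv\n",
        "  meta          --sumstats-dir dir --method feta|reta|tamr|as\n",
        "                [--ancestry ANC] [--n-axes T] --panel panel.tsv\n",
        "                --out meta.tsv\n",
        "  pgs           (construct + evaluate inside run-scenario)\n",
        "  run-scenario  --config cfg.yaml --panel panel.tsv --out dir\n",
        "  summarize     --results results.tsv --compare A:B\n",
        "                [--ancestries AFR,EAS,...] [--p-eur X] [--p-het X]\n",
        sep = "")
  }
  if (!length(argv) || argv[1] %in% c("--help", "-h")) {
    usage()
    return(invisible(0L))
  }
  sub <- argv[1]
  opts <- parse_cli_options(argv[-1])
  known <- c("synth-panel", "simulate", "gwas", "meta", "pgs",
             "run-scenario", "summarize")
  if (!sub %in% known) {
    message("unknown subcommand: ", sub)
    usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(sub,
      "synth-panel" = cli_synth_panel(opts),
      "simulate" = cli_simulate(opts),
      "gwas" = cli_gwas(opts),
      "meta" = cli_meta(opts),
      "pgs" = {
        message("pgs construction runs inside 'run-scenario'; see --help")
        2L
      },
      "run-scenario" = cli_run_scenario(opts),
      "summarize" = cli_summarize(opts))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status %||% 0L))
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "' (options are --key value)")
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("option --", substring(a, 3), " needs a value")
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

req_opt <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required option --", gsub("_", "-", key))
  opts[[key]]
}

cli_synth_panel <- function(opts) {
  panel <- synthesize_panel(
    n_variants = as.integer(req_opt(opts, "n_variants")),
    fst_ancestry = as.numeric(opts$fst_ancestry %||% 0.1),
    fst_subpop = as.numeric(opts$fst_subpop %||% 0.01),
    seed = as.integer(opts$seed %||% 1))
  write_frequency_table(panel, req_opt(opts, "out"))
  write_manifest(paste0(req_opt(opts, "out"), ".manifest.json"),
                 list(subcommand = "synth-panel", options = opts),
                 files = req_opt(opts, "out"))
  message("wrote ", n_variants(panel), " variants to ", opts$out)
  0L
}

cli_simulate <- function(opts) {
  cfgl <- load_config(req_opt(opts, "config"))
  panel <- load_frequency_table(req_opt(opts, "panel"))
  rep_i <- as.integer(opts$replicate %||% 1)
  pair <- simulate_cohort_pair(panel, cfgl$config, rep_i)
  prefix <- req_opt(opts, "out_prefix")
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (role in c("base", "target")) {
    samples <- list()
    for (blk in pair[[role]]) {
      if (blk$n == 0) next
      gf <- sprintf("%s_%s_%s_genotypes.tsv.gz", prefix, role, blk$subpop)
      con <- gzfile(gf, "w")
      utils::write.table(blk$genotypes, con, sep = "\t", quote = FALSE,
                         row.names = FALSE,
                         col.names = pair$panel$variants)
      close(con)
      written <- c(written, gf)
      samples[[blk$subpop]] <- data.frame(
        IID = sprintf("%s_%s_%05d", role, blk$subpop, seq_len(blk$n)),
        SUBPOP = blk$subpop, ANCESTRY = blk$ancestry,
        PHENO = blk$phenotype)
    }
    sf <- sprintf("%s_%s_samples.tsv", prefix, role)
    utils::write.table(do.call(rbind, samples), sf, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, sf)
  }
  write_manifest(paste0(prefix, "_manifest.json"),
                 cfgl$config, files = written,
                 extra = list(replicate = rep_i))
  0L
}

cli_gwas <- function(opts) {
  g <- as.matrix(utils::read.table(req_opt(opts, "genotypes"),
                                   header = TRUE, sep = "\t",
                                   check.names = FALSE))
  ph <- utils::read.table(req_opt(opts, "phenotypes"), header = TRUE,
                          sep = "\t")
  stats <- run_gwas(g, ph$PHENO, study = req_opt(opts, "study"),
                    ancestry = opts$ancestry %||% NA_character_)
  write_sumstats(stats, req_opt(opts, "out"))
  write_manifest(paste0(req_opt(opts, "out"), ".manifest.json"),
                 list(subcommand = "gwas", options = opts),
                 files = req_opt(opts, "out"))
  0L
}

cli_meta <- function(opts) {
  dir <- req_opt(opts, "sumstats_dir")
  manifest_file <- file.path(dir, "studies.tsv")
  if (!file.exists(manifest_file))
    stop("sumstats directory needs a studies.tsv manifest ",
         "(STUDY  ANCESTRY  FILE)")
  man <- utils::read.table(manifest_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats_list <- lapply(seq_len(nrow(man)), function(i)
    read_sumstats(file.path(dir, man$FILE[i]), study = man$STUDY[i],
                  ancestry = man$ANCESTRY[i]))
  m <- sumstats_matrices(stats_list)
  method <- toupper(req_opt(opts, "method"))
  res <- switch(method,
    FETA = fixed_effects_meta(m$beta, m$se),
    RETA = random_effects_meta(m$beta, m$se),
    AS = ancestry_specific_meta(stats_list, req_opt(opts, "ancestry")),
    TAMR = {
      panel <- load_frequency_table(req_opt(opts, "panel"))
      panel <- subset_panel(panel, match(m$variants, panel$variants))
      axes <- derive_axes(panel, m$studies,
                          n_axes = as.integer(opts$n_axes %||% 3))
      fit <- mr_mega_fit(m$beta, m$se, axes)
      cbind(fit$table, as.data.frame(fit$alpha))
    },
    stop("unknown method '", method, "'"))
  utils::write.table(res, req_opt(opts, "out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_manifest(paste0(req_opt(opts, "out"), ".manifest.json"),
                 list(subcommand = "meta", options = opts),
                 files = req_opt(opts, "out"))
  0L
}

cli_run_scenario <- function(opts) {
  cfgl <- load_config(req_opt(opts, "config"))
  panel <- load_frequency_table(req_opt(opts, "panel"))
  out_dir <- req_opt(opts, "out")
  res <- if (!is.null(cfgl$trait)) {
    run_trait_scenario(cfgl$trait, panel, p_eur_sweep = cfgl$p_eur_values,
                       config = cfgl$config, out_dir = out_dir)
  } else {
    run_grid(panel, cfgl$config,
             p_het_values = cfgl$p_het_values %||% cfgl$config$p_het,
             p_eur_values = cfgl$p_eur_values %||% cfgl$config$p_eur,
             methods = cfgl$methods %||% c("AS", "FETA", "RETA", "TAMR"),
             out_dir = out_dir)
  }
  rf <- file.path(out_dir, "results.tsv")
  utils::write.table(res, rf, sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- aggregate_results(res)
  af <- file.path(out_dir, "results_aggregated.tsv")
  utils::write.table(agg, af, sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"), cfgl$config,
                 files = c(rf, af),
                 extra = list(panel = req_opt(opts, "panel")))
  message("wrote ", nrow(res), " result rows to ", rf)
  0L
}

cli_summarize <- function(opts) {
  res <- utils::read.table(req_opt(opts, "results"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  cmp <- strsplit(req_opt(opts, "compare"), ":", fixed = TRUE)[[1]]
  if (length(cmp) != 2) stop("--compare expects METHOD_A:METHOD_B")
  anc <- if (!is.null(opts$ancestries))
    strsplit(opts$ancestries, ",", fixed = TRUE)[[1]]
  rel <- summarize_relative_performance(
    res, cmp[1], cmp[2], ancestries = anc,
    p_eur = if (!is.null(opts$p_eur)) as.numeric(opts$p_eur),
    p_het = if (!is.null(opts$p_het)) as.numeric(opts$p_het))
  cat(sprintf("%s vs %s relative difference: %+.2f%%\n",
              cmp[1], cmp[2], rel))
  0L
}
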