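# Shared fixtures: tiny panels and configs built in code.

# A minimal hand-built panel: `k` subpopulations per ancestry over the five
# default ancestries, constant frequency `f` everywhere unless a matrix is
# given.
toy_panel <- function(n_var = 3, f = 0.5, freqs = NULL) {
  amap <- default_ancestry_map()
  if (is.null(freqs))
    freqs <- matrix(f, n_var, length(amap),
                    dimnames = list(NULL, names(amap)))
  freq_panel(paste0("rs", seq_len(nrow(freqs))),
             rep("A", nrow(freqs)), freqs, amap)
}

# Small synthetic panel shared across tests (generated once per test run).
shared_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(synthesize_panel(3000, seed = 20260901))
    cache
  }
})

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_snp = 60, h2 = 0.5, p_het = 0.2, p_eur = 0.5,
                   n_base = 3000, n_target = 3000, n_replicates = 1,
                   seed = 20260901)
  do.call(scenario_config, utils::modifyList(defaults, args))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
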