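# Default population structure: five continental ancestry groups, four
# subpopulations each, mirroring the 1000 Genomes sampling design.
.default_structure <- list(
  AFR = c("GWD", "LWK", "MSL", "YRI"),
  AMR = c("CLM", "MXL", "PEL", "PUR"),
  EAS = c("CDX", "CHB", "JPT", "KHV"),
  EUR = c("FIN", "GBS", "TSI", "IBS"),
  SAS = c("BEB", "GIH", "PJL", "STU")
)

#' Default subpopulation-to-ancestry map
#'
#' Named character vector mapping each of the 20 default subpopulation codes
#' to its continental ancestry group (AFR, AMR, EAS, EUR, SAS).
#'
#' @return Named character vector (names = subpopulation codes, values =
#'   ancestry labels).
#' @export
default_ancestry_map <- function() {
  m <- unlist(lapply(names(.default_structure), function(a) {
    stats::setNames(rep(a, length(.default_structure[[a]])),
                    .default_structure[[a]])
  }))
  m
}

#' Construct a frequency panel
#'
#' A frequency panel holds per-subpopulation effect-allele frequencies for a
#' set of independent variants, together with the grouping of subpopulations
#' into ancestries.  It is the sampling substrate for genotype simulation and
#' the input from which axes of genetic variation are derived.
#'
#' @param variants Character vector of unique variant identifiers.
#' @param effect_alleles Character vector, one allele symbol per variant.
#' @param freqs Numeric matrix of effect-allele frequencies in \[0, 1\]; one
#'   row per variant, one column per subpopulation (columns named).
#' @param ancestry_map Named character vector mapping every subpopulation
#'   column of `freqs` to an ancestry group label.
#' @return An object of class `freq_panel`.
#' @export
freq_panel <- function(variants, effect_alleles, freqs, ancestry_map) {
  variants <- as.character(variants)
  effect_alleles <- as.character(effect_alleles)
  freqs <- as.matrix(freqs)
  storage.mode(freqs) <- "double"
  if (length(variants) != nrow(freqs))
    stop("number of variant IDs (", length(variants),
         ") does not match rows of the frequency matrix (", nrow(freqs), ")")
  if (length(effect_alleles) != length(variants))
    stop("one effect allele per variant is required")
  dup <- variants[duplicated(variants)]
  if (length(dup))
    stop("duplicate variant ID(s): ", paste(unique(dup), collapse = ", "))
  if (is.null(colnames(freqs)))
    stop("frequency matrix must have subpopulation column names")
  if (anyNA(freqs))
    stop("missing values in the frequency matrix")
  bad <- which(freqs < 0 | freqs > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop("frequency out of [0,1] for variant '", variants[bad[1, 1]],
         "' in subpopulation '", colnames(freqs)[bad[1, 2]], "'")
  unmapped <- setdiff(colnames(freqs), names(ancestry_map))
  if (length(unmapped))
    stop("subpopulation(s) not present in the ancestry map: ",
         paste(unmapped, collapse = ", "))
  rownames(freqs) <- variants
  structure(
    list(variants = variants,
         effect_alleles = stats::setNames(effect_alleles, variants),
         freqs = freqs,
         subpops = colnames(freqs),
         ancestry_map = ancestry_map[colnames(freqs)]),
    class = "freq_panel")
}

#' @export
print.freq_panel <- function(x, ...) {
  anc <- table(x$ancestry_map)
  cat("<freq_panel> ", length(x$variants), " variants x ",
      length(x$subpops), " subpopulations\n", sep = "")
  cat("  ancestries: ",
      paste(sprintf("%s (%d)", names(anc), anc), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Number of variants in a panel
#' @param panel A `freq_panel`.
#' @return Integer count.
#' @export
n_variants <- function(panel) length(panel$variants)

#' Ancestry labels of a panel
#' @param panel A `freq_panel`.
#' @return Character vector of distinct ancestry labels, in order of first
#'   appearance across the subpopulation columns.
#' @export
panel_ancestries <- function(panel) unique(unname(panel$ancestry_map))

#' Per-variant mean frequency by ancestry
#'
#' Unweighted mean of the subpopulation frequencies within each ancestry;
#' used by the common-variant filter and by the effect-size normalisation.
#'
#' @param panel A `freq_panel`.
#' @return Numeric matrix, variants x ancestries.
#' @export
ancestry_freqs <- function(panel) {
  anc <- panel_ancestries(panel)
  out <- sapply(anc, function(a) {
    cols <- panel$subpops[panel$ancestry_map == a]
    rowMeans(panel$freqs[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = n_variants(panel),
                dimnames = list(panel$variants, anc))
  out
}

#' Load a frequency table from TSV
#'
#' Reads a tab-separated table with header `VARIANT  EA  <SUBPOP1> ...
#' <SUBPOPK>`: a variant identifier, its effect allele, and one effect-allele
#' frequency column per subpopulation.  All subpopulation columns must be
#' present in `ancestry_map`.
#'
#' @param path Path to the TSV file.
#' @param ancestry_map Named character vector mapping subpopulation codes to
#'   ancestry labels, or a path to a two-column TSV `SUBPOP  ANCESTRY`.
#' @return A [freq_panel()].
#' @export
load_frequency_table <- function(path, ancestry_map = default_ancestry_map()) {
  if (is.character(ancestry_map) && length(ancestry_map) == 1 &&
      file.exists(ancestry_map))
    ancestry_map <- read_ancestry_map(ancestry_map)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("VARIANT", "EA")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("frequency table is missing required column(s): ",
         paste(miss, collapse = ", "))
  subpop_cols <- setdiff(names(df), need)
  if (!length(subpop_cols))
    stop("frequency table has no subpopulation columns")
  fr <- as.matrix(df[, subpop_cols, drop = FALSE])
  if (!is.numeric(fr))
    stop("non-numeric frequency cell(s) in column(s): ",
         paste(subpop_cols[!sapply(df[subpop_cols], is.numeric)],
               collapse = ", "))
  freq_panel(df$VARIANT, df$EA, fr, ancestry_map)
}

#' Write a frequency panel to TSV
#'
#' Inverse of [load_frequency_table()]; the text representation round-trips.
#'
#' @param panel A `freq_panel`.
#' @param path Output path.
#' @param digits Significant digits for frequencies (default keeps full
#'   precision via `format(..., digits = 17)` trimming).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(panel, path, digits = 17) {
  df <- data.frame(VARIANT = panel$variants,
                   EA = unname(panel$effect_alleles),
                   check.names = FALSE)
  fr <- as.data.frame(panel$freqs)
  for (j in seq_along(fr)) fr[[j]] <- formatC(fr[[j]], digits = digits,
                                              format = "g")
  utils::write.table(cbind(df, fr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subpopulation-to-ancestry map from TSV
#'
#' @param path Two-column TSV with header `SUBPOP  ANCESTRY`.
#' @return Named character vector.
#' @export
read_ancestry_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("SUBPOP", "ANCESTRY") %in% names(df)))
    stop("ancestry map must have columns SUBPOP and ANCESTRY")
  stats::setNames(df$ANCESTRY, df$SUBPOP)
}

#' Filter a panel to variants common in at least one ancestry
#'
#' The ancestry-level frequency of a variant is the unweighted mean of its
#' subpopulation frequencies within the ancestry.  With `mode = "any"` (the
#' default) a variant is retained iff its ancestry-level minor allele
#' frequency is at least `maf_threshold` in at least one ancestry, i.e.
#' variants rare in *all* ancestries are dropped.  `mode = "all"` applies the
#' stricter reading requiring the variant to be common in every ancestry.
#'
#' @param panel A `freq_panel`.
#' @param maf_threshold Minor-allele-frequency threshold in \[0, 0.5\]
#'   (default 0.01).
#' @param mode `"any"` (common in >= 1 ancestry) or `"all"` (common in every
#'   ancestry).
#' @return The filtered `freq_panel`.
#' @export
filter_common <- function(panel, maf_threshold = 0.01,
                          mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5)
  af <- ancestry_freqs(panel)
  maf <- pmin(af, 1 - af)
  keep <- if (mode == "any") apply(maf >= maf_threshold, 1, any)
          else apply(maf >= maf_threshold, 1, all)
  if (!any(keep))
    message("filter_common: no variant passes the MAF threshold ",
            maf_threshold, "; returning an empty panel")
  subset_panel(panel, which(keep))
}

subset_panel <- function(panel, idx) {
  freq_panel(panel$variants[idx],
             unname(panel$effect_alleles)[idx],
             panel$freqs[idx, , drop = FALSE],
             panel$ancestry_map)
}

#' Synthesize a hierarchical allele-frequency panel
#'
#' Generates per-subpopulation effect-allele frequencies under a two-level
#' Balding-Nichols hierarchy: an ancestral frequency `p0` is drawn uniformly
#' on \[0.05, 0.95\] per variant; each ancestry's frequency is drawn from a
#' Beta distribution with mean `p0` and variance `fst_ancestry * p0 * (1 -
#' p0)`; each subpopulation's frequency is drawn around its ancestry value
#' analogously with `fst_subpop`.  Draws at the Beta boundary are clamped to
#' \[0.001, 0.999\] so every variant stays polymorphic.
#'
#' @param n_variants Number of variants.
#' @param n_ancestries Number of ancestry groups (default 5).
#' @param n_subpops_per_ancestry Subpopulations per ancestry (default 4).
#' @param fst_ancestry Differentiation between ancestries (default 0.1,
#'   roughly continental-scale FST).
#' @param fst_subpop Differentiation within an ancestry (default 0.01); must
#'   be smaller than `fst_ancestry`.
#' @param seed Integer seed; the panel is a pure function of the arguments.
#' @return A [freq_panel()].  With the default 5 x 4 structure the
#'   subpopulations carry the 1000 Genomes-style codes from
#'   [default_ancestry_map()]; otherwise generic `A<i>_S<j>` codes are used.
#' @export
synthesize_panel <- function(n_variants, n_ancestries = 5,
                             n_subpops_per_ancestry = 4,
                             fst_ancestry = 0.1, fst_subpop = 0.01,
                             seed = 1) {
  stopifnot(n_variants >= 1, n_ancestries >= 1, n_subpops_per_ancestry >= 1,
            fst_subpop > 0, fst_ancestry > fst_subpop, fst_ancestry < 1)
  if (n_ancestries == 5 && n_subpops_per_ancestry == 4) {
    amap <- default_ancestry_map()
  } else {
    anc <- paste0("A", seq_len(n_ancestries))
    sp <- as.vector(t(outer(anc, seq_len(n_subpops_per_ancestry),
                            function(a, s) paste0(a, "_S", s))))
    amap <- stats::setNames(rep(anc, each = n_subpops_per_ancestry), sp)
  }
  set.seed(as.integer(seed))
  p0 <- stats::runif(n_variants, 0.05, 0.95)
  n_clamped <- 0L
  rbn <- function(p, fst) {
    # Balding-Nichols: Beta(p(1-F)/F, (1-p)(1-F)/F) has mean p and
    # variance F p (1-p)
    k <- (1 - fst) / fst
    x <- stats::rbeta(length(p), p * k, (1 - p) * k)
    n_clamped <<- n_clamped + sum(x < 0.001 | x > 0.999)
    pmin(pmax(x, 0.001), 0.999)
  }
  anc_labels <- unique(unname(amap))
  pa <- sapply(anc_labels, function(a) rbn(p0, fst_ancestry))
  fr <- sapply(names(amap), function(sp) rbn(pa[, amap[[sp]]], fst_subpop))
  colnames(fr) <- names(amap)
  if (n_clamped > 0)
    message("synthesize_panel: clamped ", n_clamped,
            " boundary draws into [0.001, 0.999]")
  freq_panel(sprintf("var%06d", seq_len(n_variants)),
             rep("A", n_variants), fr, amap)
}

#' Sample causal variants from a panel
#'
#' Uniform sample without replacement of `n_snp` variants, preserving the
#' panel's original variant order.
#'
#' @param panel A `freq_panel`.
#' @param n_snp Number of variants to keep.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return The subsetted `freq_panel`.
#' @export
sample_variants <- function(panel, n_snp, seed = NULL) {
  if (n_snp > n_variants(panel))
    stop("n_snp (", n_snp, ") exceeds the panel size (", n_variants(panel),
         ")")
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- sort(sample.int(n_variants(panel), n_snp))
  subset_panel(panel, idx)
}
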