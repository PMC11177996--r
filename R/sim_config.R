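#' Configuration for a synthetic multi-ancestry case-control study
#'
#' Describes every generative choice of the simulator: cohort composition per
#' ancestry, the block-LD structure of the genotypes, allele-frequency range,
#' causal effects on disease risk (log-odds per alternate allele), covariate
#' effects, target prevalence, cohort/array structure, gene models, and the
#' molecular QTL datasets to generate. A config plus its seed fully determines
#' every simulated output.
#'
#' @param seed integer seed; all randomness in the simulator derives from it.
#' @param ancestries list of `list(label, n_cases, n_controls)`. The case and
#'   control counts set the total sample size and the default prevalence
#'   target for that ancestry.
#' @param n_variants total number of variants; must equal the sum of
#'   `n_snps` over `ld_blocks`.
#' @param ld_blocks list of `list(n_snps, rho)`; `rho` is the AR(1)
#'   correlation of the latent Gaussian underlying each haplotype, in [0, 1).
#' @param maf_range length-2 numeric in (0, 0.5]; per-variant target
#'   alternate-allele frequencies are drawn uniformly from this range.
#' @param causal_variants list of `list(variant_index, beta)` where `beta` is
#'   either a single log-odds value used in every ancestry or a named vector
#'   keyed by ancestry label.
#' @param covariate_effects list with elements `sex`, `array`, `pc`
#'   (log-odds units; defaults 0). `sex` applies to sex == 2, `array` to any
#'   non-reference array, `pc` to the first principal component.
#' @param prevalence_target expected case fraction in (0, 1), or `NULL` to
#'   use each ancestry's `n_cases / (n_cases + n_controls)`.
#' @param cohorts list of `list(label, array_label, fraction)`; fractions must
#'   sum to 1 and are applied within every ancestry.
#' @param genes data.frame with columns `gene_id, chrom, start, end, strand`
#'   (1-based closed coordinates); a `tss` column is derived strand-aware if
#'   absent (start for "+", end for "-").
#' @param qtl_specs list of `list(gene_id, tissue, analyte_kind,
#'   causal_variant_index, effect_sd_units, shared_with_gwas)`;
#'   `analyte_kind` is one of "eQTL", "pQTL", "metabQTL".
#' @param missing_rate per-variant uniform genotype missingness rate
#'   (default 0), used to exercise the QC filters.
#' @param chrom chromosome label carried by all simulated variants.
#' @param bp_start,bp_spacing physical layout of the variant positions.
#' @param n_qtl_samples sample size of the independent panel on which QTL
#'   datasets are measured.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       ancestries,
                       n_variants,
                       ld_blocks,
                       maf_range = c(0.05, 0.5),
                       causal_variants = list(),
                       covariate_effects = list(sex = 0, array = 0, pc = 0),
                       prevalence_target = NULL,
                       cohorts = list(list(label = "cohort1",
                                           array_label = "array1",
                                           fraction = 1)),
                       genes = NULL,
                       qtl_specs = list(),
                       missing_rate = 0,
                       chrom = "1",
                       bp_start = 1e6,
                       bp_spacing = 5000,
                       n_qtl_samples = 1000) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  seed <- as.integer(seed)

  if (sum(vapply(ld_blocks, function(b) b$n_snps, numeric(1))) != n_variants)
    stop("configuration error: ld_blocks n_snps must sum to n_variants")
  rhos <- vapply(ld_blocks, function(b) b$rho, numeric(1))
  if (any(rhos < 0 | rhos >= 1))
    stop("configuration error: ld_blocks rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("configuration error: maf_range must lie within (0, 0.5]")

  for (cv in causal_variants)
    if (cv$variant_index < 1 || cv$variant_index > n_variants)
      stop("configuration error: causal_variants variant_index out of range")
  for (qs in qtl_specs)
    if (qs$causal_variant_index < 1 || qs$causal_variant_index > n_variants)
      stop("configuration error: qtl_specs causal_variant_index out of range")

  fr <- vapply(cohorts, function(co) co$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("configuration error: cohort fractions must sum to 1")

  if (!is.null(prevalence_target) &&
      (prevalence_target <= 0 || prevalence_target >= 1))
    stop("configuration error: prevalence_target must lie in (0, 1)")

  labels <- vapply(ancestries, function(a) a$label, character(1))
  if (anyDuplicated(labels)) stop("configuration error: duplicate ancestry labels")

  if (!is.null(genes)) {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(genes)))
      stop("configuration error: genes needs columns ", paste(need, collapse = ", "))
    if (!"tss" %in% names(genes))
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$chrom <- as.character(genes$chrom)
  }
  for (qs in qtl_specs) {
    if (is.null(genes) || !qs$gene_id %in% genes$gene_id)
      stop("configuration error: qtl_specs gene_id '", qs$gene_id,
           "' not present in genes")
    if (!qs$analyte_kind %in% c("eQTL", "pQTL", "metabQTL"))
      stop("configuration error: analyte_kind must be eQTL, pQTL or metabQTL")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("configuration error: missing_rate must lie in [0, 1)")

  structure(list(seed = seed, ancestries = ancestries, n_variants = n_variants,
                 ld_blocks = ld_blocks, maf_range = maf_range,
                 causal_variants = causal_variants,
                 covariate_effects = covariate_effects,
                 prevalence_target = prevalence_target, cohorts = cohorts,
                 genes = genes, qtl_specs = qtl_specs,
                 missing_rate = missing_rate, chrom = as.character(chrom),
                 bp_start = bp_start, bp_spacing = bp_spacing,
                 n_qtl_samples = n_qtl_samples),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  seed:", x$seed, "\n")
  for (a in x$ancestries)
    cat(sprintf("  ancestry %s: %d cases / %d controls\n",
                a$label, a$n_cases, a$n_controls))
  cat("  variants:", x$n_variants, "in", length(x$ld_blocks), "LD block(s)\n")
  cat("  causal variants:", length(x$causal_variants),
      " QTL datasets:", length(x$qtl_specs), "\n")
  invisible(x)
}

# deterministic sub-seed derivation; keeps results independent across stages
# while everything traces back to the single config seed
derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (ch in utf8ToInt(as.character(p)))
      h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
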