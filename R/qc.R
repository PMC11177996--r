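#' Variant quality-control thresholds
#'
#' Defaults follow standard post-imputation practice for case-control GWAS:
#' a 90% variant genotyping-rate floor, a 98% sample call-rate floor, an
#' exact Hardy-Weinberg filter at P >= 1e-6 during QC (a much stricter
#' 1e-30 filter is applied again at analysis time to catch merge artifacts),
#' and a minor allele count of at least 5. The implied MAF cutoff is always
#' derived from MAC and the actual sample size: `mac_min / (2 * n_samples)`.
#'
#' @param variant_call_rate_min,sample_call_rate_min fractions in [0, 1].
#' @param hwe_p_min exact-test P below which a variant is removed.
#' @param mac_min minimum minor allele count.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.90,
                          sample_call_rate_min = 0.98,
                          hwe_p_min = 1e-6,
                          mac_min = 5) {
  stopifnot(variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, mac_min >= 0)
  structure(list(variant_call_rate_min = variant_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 hwe_p_min = hwe_p_min, mac_min = mac_min),
            class = "qc_thresholds")
}

#' Apply variant and sample quality control
#'
#' Samples failing the call-rate floor are dropped first; variants are then
#' removed if they fail the variant call-rate, exact Hardy-Weinberg, or minor
#' allele count filter. Filter failures are evaluated jointly on the
#' sample-filtered matrix, so the variant report is order-independent; the
#' per-filter counts are non-exclusive and the removed total is their union.
#'
#' @param genotypes a `genotype_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered), `report` (counts per filter,
#'   implied MAF cutoff, kept/removed totals) and `empty` flag.
#' @export
apply_variant_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  n0 <- nrow(d)

  sample_cr <- rowMeans(!is.na(d))
  keep_s <- sample_cr >= thresholds$sample_call_rate_min
  d <- d[keep_s, , drop = FALSE]
  n <- nrow(d)

  call_rate <- colMeans(!is.na(d))
  n_AA <- colSums(d == 0, na.rm = TRUE)
  n_Aa <- colSums(d == 1, na.rm = TRUE)
  n_aa <- colSums(d == 2, na.rm = TRUE)
  hwe_p <- mapply(hwe_exact_test, n_AA, n_Aa, n_aa)
  alt_count <- 2 * n_aa + n_Aa
  tot <- 2 * (n_AA + n_Aa + n_aa)
  mac <- pmin(alt_count, tot - alt_count)

  fail_cr <- call_rate < thresholds$variant_call_rate_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  fail_mac <- mac < thresholds$mac_min
  keep <- !(fail_cr | fail_hwe | fail_mac)

  out <- genotypes
  out$dosage <- d[, keep, drop = FALSE]
  out$variants <- genotypes$variants[keep, , drop = FALSE]
  out$sample_ids <- genotypes$sample_ids[keep_s]

  report <- list(n_samples_in = n0, n_samples_removed = sum(!keep_s),
                 n_variants_in = length(keep),
                 n_fail_call_rate = sum(fail_cr),
                 n_fail_hwe = sum(fail_hwe),
                 n_fail_mac = sum(fail_mac),
                 n_removed = sum(!keep), n_kept = sum(keep),
                 implied_maf_cutoff = thresholds$mac_min / (2 * n),
                 empty = sum(keep) == 0)
  if (report$empty)
    warning("QC removed every variant: empty result")
  list(genotypes = out, report = report, empty = report$empty)
}
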