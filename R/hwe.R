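#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Enumerates every heterozygote count compatible with the observed allele
#' counts and returns the sum of the probabilities of all configurations at
#' most as probable as the observed one (the exact conditional test).
#' Monomorphic variants return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference hom, het, alternate hom).
#' @return two-sided exact P value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("input error: negative genotype count")
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("input error: no genotyped samples")
  n_a <- 2 * n_aa + n_Aa              # alternate allele count
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)

  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log conditional probability of each het count given allele counts
  logp <- vapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    lgamma(n + 1) - lgamma(hom_minor + 1) - lgamma(h + 1) -
      lgamma(hom_major + 1) + h * log(2) -
      (lgamma(2 * n + 1) - lgamma(n_minor + 1) - lgamma(2 * n - n_minor + 1))
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_Aa]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}
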