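#' Colocalization priors
#'
#' Per-SNP prior probabilities of causality for each trait (`p1`, `p2`),
#' for both traits jointly (`p12`), and the standard deviation of the
#' normal effect prior used in the approximate Bayes factor: 0.15 for
#' quantitative traits and 0.2 (log-odds scale) for case-control traits.
#'
#' @param p1,p2 per-SNP causal priors for trait 1 / trait 2.
#' @param p12 per-SNP prior of being causal for both; must satisfy
#'   `0 < p12 <= min(p1, p2) < 1`.
#' @param prior_sd_quant,prior_sd_cc effect-SD priors.
#' @return object of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  if (!(p12 > 0 && p12 <= min(p1, p2) && min(p1, p2) < 1))
    stop("input error: need 0 < p12 <= min(p1, p2) < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_cc = prior_sd_cc),
            class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `W = prior_sd^2`, `r = W/(V+W)` and `z = beta/se`:
#' `log ABF = 0.5 * log(1 - r) + (z^2 / 2) * r`. Strictly increasing in
#' `|z|` at fixed `se` and `prior_sd`.
#'
#' @param beta,se effect estimate and standard error (`se > 0`).
#' @param prior_sd standard deviation of the normal effect prior.
#' @return log approximate Bayes factor (natural log).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("input error: se must be positive")
  if (any(prior_sd <= 0)) stop("input error: prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * log1p(-r) + (z^2 / 2) * r
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalization of two traits
#'
#' Computes the five-hypothesis posterior (H0: no causal variant; H1/H2:
#' causal variant for one trait only; H3: distinct causal variants; H4: a
#' shared causal variant) from per-variant log ABFs, accumulating the
#' configuration sums in log space with log-sum-exp so that `|z|` up to 40
#' does not overflow. Variants are matched on chromosome/position with
#' allele harmonization.
#'
#' @param stats_a,stats_b data.frames with `chrom, pos, ref, alt, beta, se`
#'   (and optionally `p`).
#' @param priors a [coloc_priors()].
#' @param type_a,type_b `"cc"` (case-control; prior SD 0.2) or `"quant"`
#'   (quantitative; prior SD 0.15).
#' @return object of class `coloc_result` with `pp` (named pp_h0..pp_h4),
#'   `n_snps`, `lead_a`, `lead_b`, `colocalizes` (pp_h4 >= 0.8),
#'   `low_confidence` (n_snps < 25) and `status`. Zero overlapping variants
#'   gives `status = "no_test"` (distinct from H0).
#' @export
coloc_abf <- function(stats_a, stats_b, priors = coloc_priors(),
                      type_a = "cc", type_b = "quant") {
  stopifnot(inherits(priors, "coloc_priors"))
  sd_a <- if (type_a == "cc") priors$prior_sd_cc else priors$prior_sd_quant
  sd_b <- if (type_b == "cc") priors$prior_sd_cc else priors$prior_sd_quant

  if (!"id" %in% names(stats_a))
    stats_a$id <- sprintf("chr%s:%d:%s:%s", stats_a$chrom, stats_a$pos,
                          stats_a$ref, stats_a$alt)
  ref <- stats_a[, c("chrom", "pos", "ref", "alt", "id")]
  b <- suppressMessages(harmonize_stats(stats_b, ref))
  m <- match(b$id, stats_a$id)
  a <- stats_a[m, , drop = FALSE]
  ok <- !is.na(a$beta) & !is.na(a$se) & a$se > 0 &
    !is.na(b$beta) & !is.na(b$se) & b$se > 0
  a <- a[ok, , drop = FALSE]
  b <- b[ok, , drop = FALSE]
  n <- nrow(a)
  if (n == 0)
    return(structure(list(status = "no_test", n_snps = 0,
                          pp = stats::setNames(rep(NA_real_, 5),
                                               paste0("pp_h", 0:4)),
                          lead_a = NA, lead_b = NA, colocalizes = FALSE,
                          low_confidence = TRUE),
                     class = "coloc_result"))

  la <- wakefield_labf(a$beta, a$se, sd_a)
  lb <- wakefield_labf(b$beta, b$se, sd_b)

  sa <- logsumexp(la)                    # log sum_i ABF_A(i)
  sb <- logsumexp(lb)
  sab <- logsumexp(la + lb)              # log sum_i ABF_A(i) ABF_B(i)
  lw <- c(h0 = 0,
          h1 = log(priors$p1) + sa,
          h2 = log(priors$p2) + sb,
          h3 = log(priors$p1) + log(priors$p2) + logdiffexp(sa + sb, sab),
          h4 = log(priors$p12) + sab)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  names(pp) <- paste0("pp_h", 0:4)

  structure(list(status = "ok", n_snps = n, pp = pp,
                 lead_a = a$id[which.max(la)], lead_b = b$id[which.max(lb)],
                 colocalizes = unname(pp["pp_h4"] >= 0.8),
                 low_confidence = n < 25),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  if (x$status != "ok") {
    cat("coloc_result: no overlapping variants (no test)\n")
    return(invisible(x))
  }
  cat(sprintf("coloc_result over %d variant(s)%s\n", x$n_snps,
              if (x$low_confidence) " [low confidence]" else ""))
  print(round(x$pp, 4))
  cat(if (x$colocalizes) "  -> colocalizes (PP.H4 >= 0.8)\n"
      else "  -> does not colocalize\n")
  invisible(x)
}

#' Colocalize a GWAS locus with a molecular QTL dataset
#'
#' Restricts both datasets to the locus lead +/- 1 Mb, intersects variants,
#' and runs [coloc_abf()] with the case-control effect prior on the GWAS
#' side and the quantitative prior on the QTL side (or case-control on both
#' sides when comparing two GWAS). Fewer than 25 overlapping variants flags
#' the result low-confidence (still reported).
#'
#' @param locus a `locus`.
#' @param gwas_stats `summary_stats` for the GWAS trait.
#' @param qtl a `qtl_dataset` (or a second GWAS `summary_stats` with
#'   `type_b = "cc"`).
#' @param priors a [coloc_priors()].
#' @param type_b effect-prior type of the second dataset.
#' @return a `coloc_result` (with `locus`, `analyte_id`, `tissue` attached).
#' @export
coloc_gwas_locus <- function(locus, gwas_stats, qtl,
                             priors = coloc_priors(), type_b = "quant") {
  stopifnot(inherits(locus, "locus"))
  qstats <- if (inherits(qtl, "qtl_dataset")) qtl$stats else qtl
  in_a <- gwas_stats$chrom == locus$chrom &
    abs(gwas_stats$pos - locus$pos) <= locus$flank
  in_b <- qstats$chrom == locus$chrom &
    abs(qstats$pos - locus$pos) <= locus$flank
  res <- coloc_abf(gwas_stats[in_a, , drop = FALSE],
                   qstats[in_b, , drop = FALSE],
                   priors = priors, type_a = "cc", type_b = type_b)
  res$locus <- locus$lead_id
  if (inherits(qtl, "qtl_dataset")) {
    res$analyte_id <- qtl$analyte_id
    res$gene_id <- qtl$gene_id
    res$tissue <- qtl$tissue
    res$kind <- qtl$kind
  }
  res
}
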