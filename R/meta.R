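#' Recover a standard error from a printed beta and P value
#'
#' `se = |beta| / z`, with `z` the upper (1 - p/2) standard-normal quantile.
#' Used to consume published per-ancestry (beta, P) pairs whose SEs are not
#' printed.
#'
#' @param beta effect estimate (nonzero).
#' @param p two-sided P value in (0, 1).
#' @return standard error.
#' @export
se_from_beta_p <- function(beta, p) {
  if (any(p <= 0 | p >= 1)) stop("undefined-SE error: p must lie in (0, 1)")
  if (any(beta == 0)) stop("undefined-SE error: beta must be nonzero")
  z <- stats::qnorm(p / 2, lower.tail = FALSE)
  abs(beta) / z
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Weights are 1/SE^2; the combined estimate is the weighted mean with
#' `SE = 1/sqrt(sum w)` and a two-sided normal P.
#'
#' @param studies data.frame (or list coercible to one) with columns
#'   `beta` and `se` (all positive).
#' @return object of class `meta_result` (fixed-effect fields, plus Q/I2).
#' @export
fixed_effect_meta <- function(studies) {
  studies <- as.data.frame(studies)
  k <- nrow(studies)
  if (k == 0) stop("input error: no studies")
  if (any(studies$se <= 0)) stop("input error: SE must be positive")
  w <- 1 / studies$se^2
  beta <- sum(w * studies$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  Q <- sum(w * (studies$beta - beta)^2)
  df <- max(0, k - 1)
  structure(list(k = k, beta_fixed = beta, se_fixed = se, z_fixed = z,
                 p_fixed = 2 * stats::pnorm(-abs(z)),
                 tau2 = 0, beta_random = beta, se_random = se,
                 p_random = 2 * stats::pnorm(-abs(z)),
                 Q = Q, df = df,
                 I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
                 studies = studies, model = "fixed"),
            class = "meta_result")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Between-study variance `tau2 = max(0, (Q - df) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`; studies are re-weighted by
#' `1 / (se^2 + tau2)`. When `Q <= df` the result equals fixed effects.
#' A single study is passed through with a flag.
#'
#' @inheritParams fixed_effect_meta
#' @return object of class `meta_result` with both fixed and random fields.
#' @export
random_effects_meta <- function(studies) {
  studies <- as.data.frame(studies)
  k <- nrow(studies)
  if (k == 0) stop("input error: no studies")
  fixed <- fixed_effect_meta(studies)
  if (k < 2) {
    fixed$model <- "single_study_passthrough"
    return(fixed)
  }
  w <- 1 / studies$se^2
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (fixed$Q - fixed$df) / C)
  ws <- 1 / (studies$se^2 + tau2)
  beta <- sum(ws * studies$beta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- beta / se
  fixed$tau2 <- tau2
  fixed$beta_random <- beta
  fixed$se_random <- se
  fixed$p_random <- 2 * stats::pnorm(-abs(z))
  fixed$model <- "random"
  fixed
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result (%s, k = %d)\n", x$model, x$k))
  cat(sprintf("  fixed : beta %.4f (SE %.4f), P = %.3g\n",
              x$beta_fixed, x$se_fixed, x$p_fixed))
  cat(sprintf("  random: beta %.4f (SE %.4f), P = %.3g, tau2 = %.4f\n",
              x$beta_random, x$se_random, x$p_random, x$tau2))
  cat(sprintf("  Q = %.3f (df %d), I2 = %.1f%%\n", x$Q, x$df, x$I2))
  invisible(x)
}

# ambiguous-strand allele pairs cannot be disambiguated on swap
is_strand_ambiguous <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Harmonize summary statistics against reference alleles
#'
#' Matches by chromosome and position. Rows with identical ref/alt are kept
#' as-is; rows with swapped ref/alt have their beta sign flipped (and MAF
#' complemented); strand-ambiguous A/T and C/G variants whose alleles do not
#' match exactly, and any other allele mismatches, are dropped with a logged
#' count.
#'
#' @param stats data.frame with `chrom, pos, ref, alt, beta` (optionally
#'   `maf`, `z`).
#' @param ref_variants data.frame with `chrom, pos, ref, alt, id`.
#' @return stats restricted to matched rows, rewritten on the reference
#'   allele orientation, with the reference `id`; attribute `n_dropped`.
#' @export
harmonize_stats <- function(stats, ref_variants) {
  key_s <- paste(stats$chrom, round(as.numeric(stats$pos)))
  key_r <- paste(ref_variants$chrom, round(as.numeric(ref_variants$pos)))
  m <- match(key_s, key_r)
  keep <- !is.na(m)
  s <- stats[keep, , drop = FALSE]
  r <- ref_variants[m[keep], , drop = FALSE]

  same <- s$ref == r$ref & s$alt == r$alt
  swap <- s$ref == r$alt & s$alt == r$ref & !same
  ambiguous <- is_strand_ambiguous(s$ref, s$alt)
  ok <- same | (swap & !ambiguous)

  n_dropped <- nrow(stats) - sum(ok)
  s <- s[ok, , drop = FALSE]
  r <- r[ok, , drop = FALSE]
  flip <- (s$ref == r$alt)[]
  if (any(flip)) {
    s$beta[flip] <- -s$beta[flip]
    if ("z" %in% names(s)) s$z[flip] <- -s$z[flip]
    if ("maf" %in% names(s)) s$maf[flip] <- pmin(s$maf[flip], 1 - s$maf[flip])
    s$ref[flip] <- r$ref[flip]
    s$alt[flip] <- r$alt[flip]
  }
  s$id <- r$id
  if (n_dropped > 0)
    message(n_dropped, " variant(s) dropped during allele harmonization")
  attr(s, "n_dropped") <- n_dropped
  s
}

#' Trans-ancestry meta-analysis over per-ancestry summary statistics
#'
#' Harmonizes alleles across ancestries (sign flips on ref/alt swaps,
#' strand-ambiguous mismatches dropped), then meta-analyzes each variant
#' over the ancestries in which it passed QC (`k` may be less than the
#' number of inputs). Both fixed-effects and DerSimonian-Laird
#' random-effects results are reported; the headline `p` column is
#' random-effects.
#'
#' @param stats_list named list of `summary_stats` data.frames, one per
#'   ancestry.
#' @return data.frame of class `meta_stats` with per-variant
#'   `beta_fixed/se_fixed/p_fixed`, `beta_random/se_random/p_random`,
#'   `tau2, Q, df, I2, k` and headline `beta, se, p`.
#' @export
run_trans_ancestry_meta <- function(stats_list) {
  stopifnot(length(stats_list) >= 1)
  usable <- lapply(stats_list, function(s)
    s[!is.na(s$beta) & !is.na(s$se) & s$se > 0, , drop = FALSE])

  # reference orientation: first dataset in which each site appears
  ref <- NULL
  for (s in usable) {
    add <- s[, c("chrom", "pos", "ref", "alt", "id")]
    if (is.null(ref)) ref <- add
    else ref <- rbind(ref, add[!paste(add$chrom, add$pos) %in%
                                 paste(ref$chrom, ref$pos), ])
  }
  if (is.null(ref) || nrow(ref) == 0)
    return(structure(data.frame(), class = c("meta_stats", "data.frame"),
                     empty = TRUE))
  ref <- ref[order(ref$chrom, ref$pos), ]

  harm <- lapply(usable, harmonize_stats, ref_variants = ref)
  out <- ref
  nv <- nrow(ref)
  cols <- c("k", "beta_fixed", "se_fixed", "p_fixed", "beta_random",
            "se_random", "p_random", "tau2", "Q", "df", "I2")
  for (cc in cols) out[[cc]] <- NA_real_

  bmat <- semat <- matrix(NA_real_, nv, length(harm))
  for (i in seq_along(harm)) {
    m <- match(harm[[i]]$id, ref$id)
    bmat[m, i] <- harm[[i]]$beta
    semat[m, i] <- harm[[i]]$se
  }
  for (v in seq_len(nv)) {
    ok <- !is.na(bmat[v, ]) & !is.na(semat[v, ])
    if (!any(ok)) next
    mr <- random_effects_meta(data.frame(beta = bmat[v, ok],
                                         se = semat[v, ok]))
    out$k[v] <- mr$k
    out$beta_fixed[v] <- mr$beta_fixed; out$se_fixed[v] <- mr$se_fixed
    out$p_fixed[v] <- mr$p_fixed
    out$beta_random[v] <- mr$beta_random; out$se_random[v] <- mr$se_random
    out$p_random[v] <- mr$p_random
    out$tau2[v] <- mr$tau2; out$Q[v] <- mr$Q; out$df[v] <- mr$df
    out$I2[v] <- mr$I2
  }
  out <- out[!is.na(out$k), , drop = FALSE]
  if (nrow(out) == 0) {
    attr(out, "empty") <- TRUE
  } else {
    out$beta <- out$beta_random
    out$se <- out$se_random
    out$p <- out$p_random
  }
  class(out) <- c("meta_stats", "data.frame")
  out
}
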