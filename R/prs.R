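#' Polygenic risk score configuration
#'
#' Clump-and-threshold settings: base P thresholds 5e-8, 5e-5, 5e-2 and
#' 5e-1; clumping P 1, r2 0.1 and window 250 kb (distance from the index
#' variant); and the APOE region chr19:44,000,009-47,999,435 which can be
#' excluded from the base statistics.
#'
#' @param p_thresholds base P-value thresholds (sorted ascending).
#' @param clump_p,clump_r2,clump_kb clumping parameters.
#' @param apoe_region list `(chrom, start, end)`.
#' @param include_apoe keep the APOE region in the base statistics?
#' @return object of class `prs_config`.
#' @export
prs_config <- function(p_thresholds = c(5e-8, 5e-5, 5e-2, 5e-1),
                       clump_p = 1, clump_r2 = 0.1, clump_kb = 250,
                       apoe_region = list(chrom = "19",
                                          start = 44000009,
                                          end = 47999435),
                       include_apoe = TRUE) {
  stopifnot(!is.unsorted(p_thresholds), clump_r2 > 0, clump_r2 <= 1,
            clump_kb > 0)
  structure(list(p_thresholds = p_thresholds, clump_p = clump_p,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 apoe_region = apoe_region, include_apoe = include_apoe),
            class = "prs_config")
}

#' Greedy LD clumping of base summary statistics
#'
#' Visits variants by ascending P (restricted to `P <= clump_p`); a variant
#' is kept iff no already-kept variant within `clump_kb` kilobases has
#' squared correlation above `clump_r2` with it in the LD panel. Base
#' variants absent from the panel pass through with a logged count.
#'
#' @param base_stats data.frame with `chrom, pos, id, p`.
#' @param ld_panel `genotype_matrix` providing dosages for r2.
#' @param config a [prs_config()].
#' @return character vector of retained index-variant ids.
#' @export
clump <- function(base_stats, ld_panel, config = prs_config()) {
  b <- base_stats[!is.na(base_stats$p) & base_stats$p <= config$clump_p, ]
  if (nrow(b) == 0) return(character(0))
  b <- b[order(b$p), ]
  have <- b$id %in% colnames(ld_panel$dosage)
  if (any(!have))
    message(sum(!have), " base variant(s) absent from LD panel; passed through")

  imput <- function(id) {
    g <- as.double(ld_panel$dosage[, id])
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  }
  kept <- character(0)
  kept_rows <- b[0, ]
  for (i in seq_len(nrow(b))) {
    cand <- b[i, ]
    near <- kept_rows$chrom == cand$chrom &
      abs(kept_rows$pos - cand$pos) <= config$clump_kb * 1000
    drop <- FALSE
    if (any(near) && cand$id %in% colnames(ld_panel$dosage)) {
      g <- imput(cand$id)
      for (kid in kept_rows$id[near]) {
        if (!kid %in% colnames(ld_panel$dosage)) next
        r2 <- suppressWarnings(stats::cor(g, imput(kid))^2)
        if (!is.na(r2) && r2 > config$clump_r2) { drop <- TRUE; break }
      }
    }
    if (!drop) {
      kept <- c(kept, cand$id)
      kept_rows <- rbind(kept_rows, cand)
    }
  }
  kept
}

#' Remove the APOE region from base statistics
#'
#' Drops variants on the APOE chromosome with positions inside the closed
#' interval of the configured region, unless `include_apoe` is set.
#'
#' @param base_stats data.frame with `chrom, pos`.
#' @param config a [prs_config()].
#' @return filtered base statistics.
#' @export
exclude_apoe <- function(base_stats, config = prs_config()) {
  if (isTRUE(config$include_apoe)) return(base_stats)
  r <- config$apoe_region
  drop <- as.character(base_stats$chrom) == as.character(r$chrom) &
    base_stats$pos >= r$start & base_stats$pos <= r$end
  base_stats[!drop, , drop = FALSE]
}

#' Score target samples at one base P threshold
#'
#' The score is the sum over clumped base variants with base P at or below
#' the threshold of base beta times the harmonized alternate-allele dosage;
#' a missing dosage contributes `2 * base allele frequency * beta`
#' (mean imputation from the base frequency).
#'
#' @param genotypes target `genotype_matrix`.
#' @param base_stats base statistics (columns `chrom, pos, ref, alt, id,
#'   beta, p`, optionally `maf` used as the base allele frequency).
#' @param clumped ids retained by [clump()].
#' @param threshold base P threshold.
#' @return numeric per-sample scores; attribute `n_snps_used`; attribute
#'   `empty` when no variant passed the threshold (scores all zero).
#' @export
score_samples <- function(genotypes, base_stats, clumped, threshold) {
  use <- base_stats[base_stats$id %in% clumped &
                      !is.na(base_stats$p) & base_stats$p <= threshold, ]
  n <- nrow(genotypes$dosage)
  if (nrow(use) == 0) {
    out <- stats::setNames(rep(0, n), genotypes$sample_ids)
    attr(out, "n_snps_used") <- 0L
    attr(out, "empty") <- TRUE
    return(out)
  }
  harm <- suppressMessages(harmonize_stats(use, genotypes$variants))
  score <- rep(0, n)
  for (i in seq_len(nrow(harm))) {
    g <- as.double(genotypes$dosage[, harm$id[i]])
    if (anyNA(g)) {
      af <- if ("maf" %in% names(harm)) harm$maf[i] else
        mean(g, na.rm = TRUE) / 2
      g[is.na(g)] <- 2 * af
    }
    score <- score + harm$beta[i] * g
  }
  names(score) <- genotypes$sample_ids
  attr(score, "n_snps_used") <- nrow(harm)
  attr(score, "empty") <- FALSE
  score
}

#' Logistic association of case status with a risk score
#'
#' Fits `status ~ score` by logistic regression and reports the Wald P of
#' the score coefficient, Cox-Snell R2, and Nagelkerke R2
#' `(1 - exp(2(LL0 - LL1)/n)) / (1 - exp(2 LL0 / n))`. Complete separation
#' is reported as R2 = 1 with a flag; a constant score gives R2 = 0.
#'
#' @param scores per-sample scores.
#' @param status "case"/"control" (or 0/1) per sample.
#' @return object of class `prs_result`: `n_snps_used, r2_nagelkerke,
#'   r2_coxsnell, p_association, separation`.
#' @export
prs_association <- function(scores, status) {
  y <- if (is.character(status)) as.integer(status == "case")
       else as.integer(status)
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("input error: need at least 2 cases and 2 controls")
  n <- length(y)
  n_used <- attr(scores, "n_snps_used")
  if (is.null(n_used)) n_used <- NA_integer_

  if (stats::var(scores) == 0)
    return(structure(list(n_snps_used = n_used, r2_nagelkerke = 0,
                          r2_coxsnell = 0, p_association = 1,
                          separation = FALSE, beta = 0),
                     class = "prs_result"))

  sep <- max(scores[y == 0]) < min(scores[y == 1]) ||
    max(scores[y == 1]) < min(scores[y == 0])
  pbar <- mean(y)
  ll0 <- sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  max_r2 <- 1 - exp(2 * ll0 / n)
  if (sep) {
    return(structure(list(n_snps_used = n_used, r2_nagelkerke = 1,
                          r2_coxsnell = max_r2, p_association = NA_real_,
                          separation = TRUE, beta = Inf),
                     class = "prs_result"))
  }
  fit <- fit_logistic(cbind(1, score = as.double(scores)), y)
  if (!fit$ok) stop("prs fit failed: ", fit$reason)
  ll1 <- fit$loglik
  cox <- 1 - exp(2 * (ll0 - ll1) / n)
  nag <- cox / max_r2
  z <- fit$beta["score"] / fit$se["score"]
  structure(list(n_snps_used = n_used,
                 r2_nagelkerke = unname(min(1, nag)),
                 r2_coxsnell = unname(cox),
                 p_association = unname(2 * stats::pnorm(-abs(z))),
                 separation = FALSE, beta = unname(fit$beta["score"])),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf(
    "prs_result: Nagelkerke R2 = %.4f (Cox-Snell %.4f), P = %.3g%s\n",
    x$r2_nagelkerke, x$r2_coxsnell, x$p_association,
    if (x$separation) " [complete separation]" else ""))
  invisible(x)
}

#' Clump-and-threshold PRS analysis across thresholds
#'
#' Runs clumping once (optionally after APOE-region exclusion), scores the
#' target cohort at each configured base P threshold, and fits the logistic
#' association per threshold. Threshold variant sets are nested by
#' construction.
#'
#' @param base_stats base GWAS summary statistics.
#' @param genotypes target genotypes (also the LD panel for clumping).
#' @param phenotypes target phenotype table.
#' @param config a [prs_config()].
#' @return data.frame `{threshold, n_snps, r2_nagelkerke, r2_coxsnell, p,
#'   separation, empty}`.
#' @export
run_prs <- function(base_stats, genotypes, phenotypes,
                    config = prs_config()) {
  base <- exclude_apoe(base_stats, config)
  clumped <- clump(base, genotypes, config)
  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  rows <- lapply(config$p_thresholds, function(thr) {
    sc <- score_samples(genotypes, base, clumped, thr)
    if (isTRUE(attr(sc, "empty"))) {
      data.frame(threshold = thr, n_snps = 0L, r2_nagelkerke = NA_real_,
                 r2_coxsnell = NA_real_, p = NA_real_, separation = FALSE,
                 empty = TRUE)
    } else {
      pr <- prs_association(sc, ph$status)
      data.frame(threshold = thr, n_snps = attr(sc, "n_snps_used"),
                 r2_nagelkerke = pr$r2_nagelkerke,
                 r2_coxsnell = pr$r2_coxsnell, p = pr$p_association,
                 separation = pr$separation, empty = FALSE)
    }
  })
  do.call(rbind, rows)
}
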