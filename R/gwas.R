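#' Per-variant logistic case-control association scan
#'
#' Fits, for every variant, a logistic regression of case status on additive
#' alternate-allele dosage plus covariates (iteratively reweighted least
#' squares via `stats::glm.fit`), reporting Wald beta/SE/P. Default
#' covariates are sex, genotyping array and the first ten principal
#' components; array is omitted automatically when single-valued. Age is
#' never a covariate because sample selection is age-based. Missing dosages
#' are mean-imputed within variant. Non-converged variants are retained as
#' `NA` rows with a reason code and a logged count.
#'
#' @param genotypes a `genotype_matrix`.
#' @param phenotypes phenotype data.frame (see [simulate_phenotypes()]).
#' @param covariate_names covariate columns of `phenotypes` to adjust for;
#'   `NULL` selects the default set.
#' @param ancestry label copied into the output.
#' @return data.frame of class `summary_stats` with columns
#'   `chrom, pos, ref, alt, id, beta, se, z, p, maf, mac, n, n_cases,
#'   n_controls, converged, reason`; attribute `n_nonconverged`.
#' @export
run_single_variant_gwas <- function(genotypes, phenotypes,
                                    covariate_names = NULL,
                                    ancestry = genotypes$ancestry) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  if (anyNA(ph$sample_id)) stop("input error: phenotype/genotype sample mismatch")
  y <- as.integer(ph$status == "case")

  if (is.null(covariate_names))
    covariate_names <- c("sex", "array", paste0("pc", 1:10))
  covariate_names <- intersect(covariate_names, names(ph))
  if ("age" %in% covariate_names) {
    warning("age removed from covariates: selection is age-based")
    covariate_names <- setdiff(covariate_names, "age")
  }

  C <- build_covariates(ph, covariate_names)
  n <- length(y)
  nv <- ncol(genotypes$dosage)
  res <- data.frame(genotypes$variants,
                    beta = NA_real_, se = NA_real_, z = NA_real_,
                    p = NA_real_, maf = NA_real_, mac = NA_integer_,
                    n = n, n_cases = sum(y), n_controls = sum(1 - y),
                    converged = FALSE, reason = "",
                    stringsAsFactors = FALSE)

  for (j in seq_len(nv)) {
    g <- as.double(genotypes$dosage[, j])
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    af <- mean(g) / 2
    res$maf[j] <- min(af, 1 - af)
    res$mac[j] <- as.integer(round(min(sum(g), 2 * n - sum(g))))
    if (stats::var(g) == 0) { res$reason[j] <- "monomorphic"; next }
    X <- cbind(`(Intercept)` = 1, dosage = g, C)
    fit <- fit_logistic(X, y)
    if (!fit$ok) { res$reason[j] <- fit$reason; next }
    res$beta[j] <- fit$beta["dosage"]
    res$se[j] <- fit$se["dosage"]
    res$z[j] <- res$beta[j] / res$se[j]
    res$p[j] <- 2 * stats::pnorm(-abs(res$z[j]))
    res$converged[j] <- TRUE
  }
  n_bad <- sum(!res$converged)
  if (n_bad > 0)
    message(n_bad, " variant(s) flagged non-converged/degenerate")
  attr(res, "n_nonconverged") <- n_bad
  attr(res, "ancestry") <- ancestry
  attr(res, "covariates") <- colnames(C)
  class(res) <- c("summary_stats", "data.frame")
  res
}

# covariate design: numeric columns as-is, character/factor expanded to
# dummies; single-valued and collinear columns dropped with a warning
build_covariates <- function(ph, covariate_names) {
  cols <- list()
  for (nm in covariate_names) {
    v <- ph[[nm]]
    if (is.numeric(v)) {
      if (length(unique(v)) > 1) cols[[nm]] <- v
      else warning("covariate '", nm, "' single-valued; omitted")
    } else {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) {
        warning("covariate '", nm, "' single-valued; omitted")
      } else {
        for (l in lev[-1])
          cols[[paste0(nm, l)]] <- as.numeric(v == l)
      }
    }
  }
  if (length(cols) == 0)
    return(matrix(numeric(0), nrow = nrow(ph), ncol = 0))
  C <- do.call(cbind, cols)
  qrC <- qr(cbind(1, C))
  if (qrC$rank < ncol(C) + 1) {
    keep <- sort(qrC$pivot[seq_len(qrC$rank)])
    keep <- setdiff(keep, 1) - 1
    warning("dropping collinear covariate column(s): ",
            paste(setdiff(colnames(C), colnames(C)[keep]), collapse = ", "))
    C <- C[, keep, drop = FALSE]
  }
  C
}

# IRLS logistic fit with Wald SEs; flags non-convergence and separation
fit_logistic <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  cf <- fit$coefficients
  if (anyNA(cf))
    return(list(ok = FALSE, reason = "collinear"))
  if (!fit$converged || any(abs(cf) > 30))
    return(list(ok = FALSE, reason = "non_converged"))
  w <- fit$weights
  XtWX <- crossprod(X * w, X)
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(ok = FALSE, reason = "singular"))
  se <- sqrt(diag(cov))
  names(se) <- colnames(X)
  list(ok = TRUE, beta = cf, se = se, fit = fit,
       loglik = -fit$deviance / 2, reason = "")
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square statistic (the chi-square
#' quantile of 1 - P at 1 df) divided by its null expectation 0.45494.
#'
#' @param p_values vector of P values in (0, 1].
#' @return lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("input error: no P values")
  if (any(p_values <= 0 | p_values > 1))
    stop("input error: P values must lie in (0, 1]")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / 0.45494
}

#' Define GWAS loci around lead variants
#'
#' Greedily picks the most significant remaining genome-wide significant
#' variant as a lead, absorbs all genome-wide significant variants within
#' +/- `flank` on the same chromosome, and repeats. Every genome-wide
#' variant is assigned to exactly one locus; leads of distinct loci are more
#' than `flank` apart or on different chromosomes.
#'
#' @param sumstats a `summary_stats` data.frame.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param flank locus half-width in base pairs (default 1 Mb).
#' @param gene_models optional gene models; fills each locus's nearest gene.
#' @return list of `locus` objects (possibly empty).
#' @export
define_loci <- function(sumstats, p_threshold = 5e-8, flank = 1e6,
                        gene_models = NULL) {
  gws <- sumstats[!is.na(sumstats$p) & sumstats$p < p_threshold, ]
  loci <- list()
  while (nrow(gws) > 0) {
    i <- which.min(gws$p)
    lead <- gws[i, ]
    member <- gws$chrom == lead$chrom & abs(gws$pos - lead$pos) <= flank
    nearest <- NA_character_
    if (!is.null(gene_models)) {
      ng <- nearest_gene(lead, gene_models)
      if (!is.null(ng)) nearest <- ng
    }
    loci[[length(loci) + 1]] <- structure(
      list(lead_id = lead$id, chrom = lead$chrom, pos = lead$pos,
           p = lead$p, flank = flank,
           start = max(1, lead$pos - flank), end = lead$pos + flank,
           members = gws$id[member], independent_signals = lead$id,
           nearest_gene = nearest),
      class = "locus")
    gws <- gws[!member, ]
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s (chr%s:%d-%d): lead P = %.3g, %d GWS member(s)\n",
              x$lead_id, x$chrom, x$start, x$end, x$p, length(x$members)))
  if (!is.na(x$nearest_gene)) cat("  nearest gene:", x$nearest_gene, "\n")
  invisible(x)
}

#' Stepwise conditional analysis at a locus
#'
#' Starting from the locus lead, iteratively adds the current lead dosage as
#' a covariate and re-fits every other variant in the 1 Mb window; the most
#' significant remaining variant joins the conditioning chain while its
#' conditional P is below the significance threshold. Stops when
#' significance is attenuated (P >= threshold) or an added dosage is nearly
#' collinear with the chain.
#'
#' @param locus a `locus`.
#' @param genotypes genotypes covering the locus.
#' @param phenotypes phenotype table.
#' @param covariate_names covariates as in [run_single_variant_gwas()].
#' @param p_threshold conditional significance threshold (default 5e-8).
#' @param collinear_r2 r-squared above which an added dosage is treated as
#'   collinear with the existing chain (stops with a logged reason).
#' @return list with `independent_signals` (ordered variant ids),
#'   `stopped_reason`, and `steps` (conditional minimum P per step).
#' @export
stepwise_conditional <- function(locus, genotypes, phenotypes,
                                 covariate_names = NULL,
                                 p_threshold = 5e-8,
                                 collinear_r2 = 0.95) {
  stopifnot(inherits(locus, "locus"))
  v <- genotypes$variants
  in_win <- v$chrom == locus$chrom & abs(v$pos - locus$pos) <= locus$flank
  if (!locus$lead_id %in% v$id[in_win])
    stop("input error: genotypes do not cover the locus lead")

  ph <- phenotypes[match(genotypes$sample_ids, phenotypes$sample_id), ]
  y <- as.integer(ph$status == "case")
  if (is.null(covariate_names))
    covariate_names <- c("sex", "array", paste0("pc", 1:10))
  covariate_names <- setdiff(intersect(covariate_names, names(ph)), "age")
  C <- suppressWarnings(build_covariates(ph, covariate_names))

  imputed <- function(id) {
    g <- as.double(genotypes$dosage[, id])
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  }
  window_ids <- v$id[in_win]
  chain <- locus$lead_id
  chain_g <- matrix(imputed(locus$lead_id), ncol = 1,
                    dimnames = list(NULL, locus$lead_id))
  steps <- numeric(0)
  reason <- "attenuated"

  repeat {
    candidates <- setdiff(window_ids, chain)
    if (length(candidates) == 0) { reason <- "exhausted"; break }
    best_p <- Inf; best_id <- NA_character_
    for (id in candidates) {
      g <- imputed(id)
      if (stats::var(g) == 0) next
      X <- cbind(1, dosage = g, chain_g, C)
      fit <- fit_logistic(X, y)
      if (!fit$ok) next
      pj <- 2 * stats::pnorm(-abs(fit$beta["dosage"] / fit$se["dosage"]))
      if (pj < best_p) { best_p <- pj; best_id <- id }
    }
    if (!is.finite(best_p) || best_p >= p_threshold) break
    g <- imputed(best_id)
    r2 <- apply(chain_g, 2, function(cg) stats::cor(g, cg)^2)
    if (any(r2 > collinear_r2)) {
      reason <- "collinear"
      message("conditional chain stopped: candidate ", best_id,
              " collinear with chain (r2 = ", round(max(r2), 3), ")")
      break
    }
    chain <- c(chain, best_id)
    chain_g <- cbind(chain_g, g)
    colnames(chain_g)[ncol(chain_g)] <- best_id
    steps <- c(steps, best_p)
  }
  list(independent_signals = chain, stopped_reason = reason, steps = steps)
}

#' Cochran's Q heterogeneity across cohorts for one variant
#'
#' Tests the per-cohort effect estimates against the inverse-variance pooled
#' estimate. A variant is flagged heterogeneous when log10(het P) < -1.30103
#' (strictly), i.e. P < 0.05.
#'
#' @param betas,ses per-cohort effects and standard errors (>= 2 cohorts).
#' @return list with `Q, df, het_p, log10_het_p, heterogeneous`.
#' @export
cohort_heterogeneity <- function(betas, ses) {
  if (length(betas) < 2 || length(betas) != length(ses))
    stop("input error: need >= 2 cohorts with beta and SE")
  if (any(ses <= 0)) stop("input error: SE must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1
  het_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  list(Q = Q, df = df, het_p = het_p, log10_het_p = log10(het_p),
       heterogeneous = log10(het_p) < -1.30103)
}
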