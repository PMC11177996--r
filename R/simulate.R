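#' Simulate genotypes for one ancestry
#'
#' Draws two haplotypes per individual. Within each LD block a latent
#' standard-normal vector with AR(1) correlation `rho` is thresholded at the
#' quantile matching each variant's target alternate-allele frequency; the
#' dosage is the sum of the two haplotypes. This gives marginally correct
#' allele frequencies with tunable, monotonically decaying LD inside blocks
#' and independence across blocks. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param ancestry_label one of the configured ancestry labels, or any other
#'   label when `n` is supplied (used for reference/QTL panels).
#' @param n optional sample-size override.
#' @return an object of class `genotype_matrix`: a list with `dosage`
#'   (samples x variants integer matrix, `NA` = missing), `variants`
#'   (data.frame `chrom, pos, ref, alt, id`) and `sample_ids`.
#' @export
simulate_genotypes <- function(config, ancestry_label, n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  anc <- find_ancestry(config, ancestry_label, allow_missing = !is.null(n))
  if (is.null(n)) n <- anc$n_cases + anc$n_controls

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "geno", ancestry_label, n))

  variants <- variant_table(config)
  mafs <- variant_mafs(config)
  thr <- stats::qnorm(mafs)

  dosage <- matrix(0L, nrow = n, ncol = config$n_variants)
  for (hap in 1:2) {
    col0 <- 0L
    for (blk in config$ld_blocks) {
      m <- blk$n_snps
      rho <- blk$rho
      L <- matrix(0, n, m)
      L[, 1] <- stats::rnorm(n)
      if (m > 1) {
        s <- sqrt(1 - rho^2)
        for (j in 2:m) L[, j] <- rho * L[, j - 1] + s * stats::rnorm(n)
      }
      idx <- col0 + seq_len(m)
      dosage[, idx] <- dosage[, idx] +
        (L < matrix(thr[idx], n, m, byrow = TRUE))
      col0 <- col0 + m
    }
  }
  storage.mode(dosage) <- "integer"

  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * config$n_variants) < config$missing_rate,
                   n, config$n_variants)
    dosage[miss] <- NA_integer_
  }

  colnames(dosage) <- variants$id
  sample_ids <- sprintf("%s_%05d", ancestry_label, seq_len(n))
  rownames(dosage) <- sample_ids

  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids, ancestry = ancestry_label),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              nrow(x$dosage), ncol(x$dosage), x$ancestry))
  invisible(x)
}

variant_table <- function(config) {
  pos <- config$bp_start + (seq_len(config$n_variants) - 1L) * config$bp_spacing
  bases <- c("A", "C", "G", "T")
  ref <- bases[((seq_len(config$n_variants) - 1L) %% 4L) + 1L]
  alt <- bases[(seq_len(config$n_variants) %% 4L) + 1L]
  data.frame(chrom = config$chrom, pos = pos, ref = ref, alt = alt,
             id = sprintf("chr%s:%d:%s:%s", config$chrom, pos, ref, alt),
             stringsAsFactors = FALSE)
}

variant_mafs <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "maf"))
  stats::runif(config$n_variants, config$maf_range[1], config$maf_range[2])
}

find_ancestry <- function(config, label, allow_missing = FALSE) {
  for (a in config$ancestries) if (a$label == label) return(a)
  if (allow_missing) return(NULL)
  stop("configuration error: unknown ancestry label '", label, "'")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate case-control phenotypes and covariates
#'
#' Case probability follows a logistic model on the causal dosages and
#' covariates; the intercept is solved numerically so the expected case
#' fraction matches the prevalence target. Cases are assigned an age at onset
#' of 70 or younger (uniform on [40, 70]); controls an age at last visit
#' strictly above 70 (uniform on (70, 95]). Cohorts and genotyping arrays are
#' assigned by the configured fractions.
#'
#' @param genotypes a `genotype_matrix` from the same config.
#' @param config the [sim_config()].
#' @param ancestry_label ancestry whose causal effects and prevalence apply.
#' @return data.frame with columns `sample_id, status` ("case"/"control"),
#'   `age, sex` (1/2), `cohort, array`, and `pc1..pc10`.
#' @export
simulate_phenotypes <- function(genotypes, config, ancestry_label) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  anc <- find_ancestry(config, ancestry_label)
  n <- nrow(genotypes$dosage)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "pheno", ancestry_label, n))

  target <- config$prevalence_target
  if (is.null(target)) target <- anc$n_cases / (anc$n_cases + anc$n_controls)
  if (target <= 0 || target >= 1)
    stop("configuration error: prevalence target must lie strictly in (0, 1)")

  sex <- sample(1:2, n, replace = TRUE)
  fr <- vapply(config$cohorts, function(co) co$fraction, numeric(1))
  cohort_idx <- sample(seq_along(config$cohorts), n, replace = TRUE, prob = fr)
  cohort <- vapply(config$cohorts, function(co) co$label, character(1))[cohort_idx]
  array <- vapply(config$cohorts,
                  function(co) co$array_label, character(1))[cohort_idx]
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  eta <- numeric(n)
  for (cv in config$causal_variants) {
    b <- cv$beta
    if (!is.null(names(b))) b <- unname(b[ancestry_label])
    if (is.na(b)) b <- 0
    g <- genotypes$dosage[, cv$variant_index]
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    eta <- eta + b * g
  }
  ce <- config$covariate_effects
  ref_array <- config$cohorts[[1]]$array_label
  eta <- eta + null0(ce$sex) * (sex == 2) +
    null0(ce$array) * (array != ref_array) + null0(ce$pc) * pcs[, 1]

  f <- function(c0) mean(stats::plogis(c0 + eta)) - target
  intercept <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root

  status <- ifelse(stats::runif(n) < stats::plogis(intercept + eta),
                   "case", "control")
  age <- ifelse(status == "case",
                40 + stats::runif(n) * 30,          # onset in [40, 70]
                70.5 + stats::runif(n) * 24.5)      # last visit in (70, 95]

  data.frame(sample_id = genotypes$sample_ids, status = status,
             age = round(age, 1), sex = sex, cohort = cohort, array = array,
             pcs, stringsAsFactors = FALSE)
}

null0 <- function(x) if (is.null(x)) 0 else x

#' Simulate a molecular QTL dataset
#'
#' The molecular trait (expression, protein or metabolite level) is
#' `effect * dosage(causal variant) + N(0, 1)` noise on an independent panel;
#' per-variant summary statistics come from ordinary least squares of the
#' trait on dosage. The dataset is labeled cis when the causal variant lies
#' within 1 Mb of the mapped gene's TSS.
#'
#' @param genotypes `genotype_matrix` of the QTL measurement panel.
#' @param spec one element of the config's `qtl_specs`.
#' @param config the [sim_config()] (for gene models and the seed).
#' @return object of class `qtl_dataset` with fields `analyte_id, gene_id,
#'   tissue, kind, cis, causal_id, shared_with_gwas` and a `stats` data.frame
#'   `(chrom, pos, ref, alt, id, beta, se, p, n, cis)`.
#' @export
simulate_qtl_dataset <- function(genotypes, spec, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  gene <- config$genes[config$genes$gene_id == spec$gene_id, , drop = FALSE]
  if (nrow(gene) != 1)
    stop("configuration error: qtl spec gene_id not found: ", spec$gene_id)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, "qtl", spec$gene_id, spec$tissue,
                       spec$analyte_kind))

  g <- genotypes$dosage[, spec$causal_variant_index]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  if (stats::var(g) == 0)
    stop("simulation error: causal variant is monomorphic in the QTL panel")
  n <- length(g)
  y <- spec$effect_sd_units * g + stats::rnorm(n)

  st <- ols_scan(genotypes$dosage, y)
  stats_df <- cbind(genotypes$variants, st, n = n)
  win <- cis_window(gene)
  stats_df$cis <- stats_df$chrom == gene$chrom &
    stats_df$pos >= win[1] & stats_df$pos <= win[2]

  causal <- genotypes$variants[spec$causal_variant_index, ]
  is_cis <- causal$chrom == gene$chrom &&
    causal$pos >= win[1] && causal$pos <= win[2]

  structure(list(analyte_id = paste(spec$gene_id, spec$tissue,
                                    spec$analyte_kind, sep = "|"),
                 gene_id = spec$gene_id, tissue = spec$tissue,
                 kind = spec$analyte_kind, cis = is_cis,
                 causal_id = causal$id,
                 shared_with_gwas = isTRUE(spec$shared_with_gwas),
                 stats = stats_df),
            class = "qtl_dataset")
}

#' @export
print.qtl_dataset <- function(x, ...) {
  cat(sprintf("qtl_dataset %s: %s in %s, %d variants, %s\n", x$analyte_id,
              x$kind, x$tissue, nrow(x$stats),
              if (x$cis) "cis" else "trans"))
  invisible(x)
}

# per-variant simple linear regression of y on each dosage column
ols_scan <- function(dosage, y) {
  G <- dosage
  storage.mode(G) <- "double"
  # mean-impute missing dosages column-wise
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  n <- nrow(G)
  gbar <- colMeans(G)
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(G, yc))          # sum (g - gbar)(y - ybar)
  sxx <- colSums(G^2) - n * gbar^2
  syy <- sum(yc^2)
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  s2 <- pmax(0, (syy - beta^2 * sxx) / (n - 2))
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[is.na(p)] <- NA_real_
  data.frame(beta = beta, se = se, p = p)
}

#' Simulate a complete multi-ancestry study
#'
#' Generates genotypes and phenotypes for every configured ancestry, an
#' independent QTL measurement panel, and every configured QTL dataset.
#' Optionally writes all outputs (VCF, TSVs, BED, GFF3) to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory; created if needed.
#' @return list with `genotypes` and `phenotypes` (named by ancestry label),
#'   `qtl_panel`, `qtl_datasets`, `genes`, and `config`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  genotypes <- list(); phenotypes <- list()
  for (a in config$ancestries) {
    genotypes[[a$label]] <- simulate_genotypes(config, a$label)
    phenotypes[[a$label]] <- simulate_phenotypes(genotypes[[a$label]],
                                                 config, a$label)
  }
  qtl_panel <- simulate_genotypes(config, "qtl_panel",
                                  n = config$n_qtl_samples)
  qtl_datasets <- lapply(config$qtl_specs, function(spec)
    simulate_qtl_dataset(qtl_panel, spec, config))

  study <- list(genotypes = genotypes, phenotypes = phenotypes,
                qtl_panel = qtl_panel, qtl_datasets = qtl_datasets,
                genes = config$genes, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(genotypes)) {
      write_vcf(genotypes[[lab]],
                file.path(out_dir, paste0("genotypes_", lab, ".vcf")))
      utils::write.table(phenotypes[[lab]],
                         file.path(out_dir, paste0("phenotypes_", lab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(config$genes)) {
      write_gene_models_bed(config$genes, file.path(out_dir, "genes.bed"))
      write_gene_models_gff3(config$genes, file.path(out_dir, "genes.gff3"))
    }
    for (q in qtl_datasets)
      write_qtl_tsv(q, file.path(out_dir,
                                 paste0("qtl_", gsub("[|]", "_", q$analyte_id),
                                        ".tsv")))
  }
  study
}
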