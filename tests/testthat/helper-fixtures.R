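# fixtures are built in code; nothing is read from disk

# genotype_matrix from an explicit dosage matrix (toy inputs)
make_genotypes <- function(dosage, chrom = "1", pos = NULL,
                           ref = NULL, alt = NULL) {
  nv <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1e6, by = 5000, length.out = nv)
  if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = nv)
  if (is.null(alt)) alt <- rep(c("C", "G", "T", "A"), length.out = nv)
  v <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                  id = sprintf("chr%s:%d:%s:%s", chrom, as.integer(pos),
                               ref, alt),
                  stringsAsFactors = FALSE)
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- v$id
  ids <- sprintf("s%04d", seq_len(nrow(dosage)))
  rownames(dosage) <- ids
  structure(list(dosage = dosage, variants = v, sample_ids = ids,
                 ancestry = "toy"), class = "genotype_matrix")
}

# minimal sumstats table from parallel vectors
make_sumstats <- function(pos, beta, se, p = NULL, chrom = "1",
                          ref = NULL, alt = NULL) {
  nv <- length(pos)
  if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = nv)
  if (is.null(alt)) alt <- rep(c("C", "G", "T", "A"), length.out = nv)
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             id = sprintf("chr%s:%d:%s:%s", chrom, as.integer(pos), ref, alt),
             beta = beta, se = se, z = beta / se, p = p,
             stringsAsFactors = FALSE)
}

make_locus <- function(chrom = "1", pos = 2e6, lead_id = NULL,
                       flank = 1e6, p = 1e-9) {
  if (is.null(lead_id))
    lead_id <- sprintf("chr%s:%d:A:C", chrom, as.integer(pos))
  structure(list(lead_id = lead_id, chrom = chrom, pos = as.integer(pos),
                 p = p, flank = flank, start = max(1, pos - flank),
                 end = pos + flank, members = lead_id,
                 independent_signals = lead_id, nearest_gene = NA_character_),
            class = "locus")
}

toy_genes <- function() {
  data.frame(gene_id = c("GENE1", "DECOY1", "FARGENE"),
             chrom = "1",
             start = c(1.95e6, 2.4e6, 9e6),
             end = c(2.05e6, 2.45e6, 9.05e6),
             strand = c("+", "-", "+"),
             tss = c(1.95e6, 2.45e6, 9e6),
             stringsAsFactors = FALSE)
}

# independent enumeration oracle for the exact conditional HWE test
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- sapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    exp(lfactorial(n) - lfactorial(hom_minor) - lfactorial(h) -
          lfactorial(hom_major) + h * log(2) -
          (lfactorial(2 * n) - lfactorial(n_minor) -
             lfactorial(2 * n - n_minor)))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# brute-force configuration enumeration oracle for ABF colocalization
coloc_enum_oracle <- function(la, lb, p1, p2, p12) {
  n <- length(la)
  abf_a <- exp(la); abf_b <- exp(lb)
  w0 <- 1
  w1 <- sum(p1 * abf_a)
  w2 <- sum(p2 * abf_b)
  w3 <- 0; w4 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) w4 <- w4 + p12 * abf_a[i] * abf_b[i]
    else w3 <- w3 + p1 * p2 * abf_a[i] * abf_b[j]
  }
  pp <- c(w0, w1, w2, w3, w4)
  pp / sum(pp)
}

# a small but realistic study configuration shared by several suites
small_study_config <- function(seed = 7, n_cases = 500, n_controls = 500,
                               beta = log(2), causal = 30,
                               n_snps = 60, rho = 0.5,
                               qtl_causal = causal, qtl_effect = 0.7,
                               n_qtl = 1000) {
  genes <- data.frame(gene_id = c("GENE1", "DECOY1"), chrom = "1",
                      start = c(1.0e6, 1.20e6), end = c(1.05e6, 1.24e6),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  sim_config(seed = seed,
             ancestries = list(list(label = "POP1", n_cases = n_cases,
                                    n_controls = n_controls)),
             n_variants = n_snps,
             ld_blocks = list(list(n_snps = n_snps, rho = rho)),
             maf_range = c(0.1, 0.5),
             causal_variants = list(list(variant_index = causal,
                                         beta = beta)),
             genes = genes,
             qtl_specs = list(list(gene_id = "GENE1", tissue = "brain",
                                   analyte_kind = "eQTL",
                                   causal_variant_index = qtl_causal,
                                   effect_sd_units = qtl_effect,
                                   shared_with_gwas = qtl_causal == causal)),
             bp_start = 1e6, bp_spacing = 2000, n_qtl_samples = n_qtl)
}

# GWAS scan + QTL scan pair for colocalization calibration
sim_coloc_pair <- function(seed, shared = TRUE) {
  cfg <- small_study_config(seed = seed, n_cases = 1000, n_controls = 1000,
                            qtl_causal = if (shared) 30 else 55)
  g <- simulate_genotypes(cfg, "POP1")
  ph <- simulate_phenotypes(g, cfg, "POP1")
  gw <- suppressMessages(run_single_variant_gwas(g, ph,
                                                 covariate_names = character(0)))
  panel <- simulate_genotypes(cfg, "qtl_panel", n = 2000)
  q <- simulate_qtl_dataset(panel, cfg$qtl_specs[[1]], cfg)
  coloc_abf(gw, q$stats, type_a = "cc", type_b = "quant")
}
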