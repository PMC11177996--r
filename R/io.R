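#' Write a genotype matrix as VCF 4.2 (GT field)
#'
#' @param genotypes a `genotype_matrix`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  n <- nrow(genotypes$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=locusnominator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- genotypes$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(v$chrom[j], format(v$pos[j], scientific = FALSE),
                       v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into additive alternate-allele dosages (0/1/2, `NA` for
#' missing). Positions must be strictly increasing within chromosome.
#'
#' @param path VCF path (plain or gzipped).
#' @param ancestry optional label attached to the result.
#' @return a `genotype_matrix`.
#' @export
read_vcf_genotypes <- function(path, ancestry = NA_character_) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # count alternate alleles in the GT string, tolerant of phased separators
  dose <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    out[ok] <- vapply(strsplit(x[ok], "[/|]"),
                      function(a) sum(as.integer(a)), integer(1))
    out
  }
  dosage <- apply(gt, 1, dose)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = ncol(gt))
  variants <- data.frame(chrom = as.character(fix[, "CHROM"]),
                         pos = as.integer(fix[, "POS"]),
                         ref = as.character(fix[, "REF"]),
                         alt = as.character(fix[, "ALT"]),
                         stringsAsFactors = FALSE)
  variants$id <- sprintf("chr%s:%d:%s:%s", variants$chrom, variants$pos,
                         variants$ref, variants$alt)
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  dosage <- dosage[, ord, drop = FALSE]
  colnames(dosage) <- variants$id
  rownames(dosage) <- colnames(gt)
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = colnames(gt), ancestry = ancestry),
            class = "genotype_matrix")
}

#' Read a phenotype/covariate table
#' @param path TSV with the columns written by [simulate_study()].
#' @export
read_phenotypes_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = NA)
}

#' Write gene models as BED (0-based half-open)
#' @param genes gene-model data.frame (1-based closed internally).
#' @param path output path.
#' @export
write_gene_models_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = format(genes$start - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(genes$end, scientific = FALSE, trim = TRUE),
                    name = genes$gene_id, score = 0L,
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (1-based closed)
#' @inheritParams write_gene_models_bed
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes)))
    writeLines(paste(genes$chrom[i], "locusnominator", "gene",
                     format(genes$start[i], scientific = FALSE, trim = TRUE),
                     format(genes$end[i], scientific = FALSE, trim = TRUE),
                     ".", genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]), sep = "\t"), con)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Coordinate conversion happens at this boundary: BED input (0-based
#' half-open) and GFF3 input (1-based closed) both yield 1-based closed
#' internal coordinates, with a strand-aware TSS column.
#'
#' @param path a `.bed` or `.gff3`/`.gff` file.
#' @return data.frame `gene_id, chrom, start, end, strand, tss`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  id <- if ("ID" %in% names(df)) df$ID else df$name
  genes <- data.frame(gene_id = as.character(id),
                      chrom = as.character(df$seqnames),
                      start = df$start, end = df$end,
                      strand = as.character(df$strand),
                      stringsAsFactors = FALSE)
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene model error: missing strand for ",
         paste(genes$gene_id[!genes$strand %in% c("+", "-")], collapse = ", "))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes
}

#' Write per-variant summary statistics as TSV
#' @param sumstats a summary-statistics data.frame.
#' @param path output path.
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-variant summary statistics from TSV
#' @param path TSV path.
#' @export
read_sumstats_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a QTL dataset as TSV
#' @param qtl a `qtl_dataset`.
#' @param path output path.
#' @export
write_qtl_tsv <- function(qtl, path) {
  out <- data.frame(analyte_id = qtl$analyte_id, tissue = qtl$tissue,
                    qtl$stats[, c("chrom", "pos", "ref", "alt",
                                  "beta", "se", "p", "n")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QTL dataset from TSV
#'
#' @param path TSV with header
#'   `analyte_id, tissue, chrom, pos, ref, alt, beta, se, p, n`.
#' @param gene_id,kind analyte-to-gene mapping and QTL kind (not stored in
#'   the TSV itself; mirrors platform-documentation mapping tables).
#' @param genes optional gene models used to set the cis flag.
#' @export
read_qtl_tsv <- function(path, gene_id = NA_character_,
                         kind = "eQTL", genes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$chrom <- as.character(df$chrom)
  df$id <- sprintf("chr%s:%d:%s:%s", df$chrom, df$pos, df$ref, df$alt)
  is_cis <- NA
  if (!is.null(genes) && !is.na(gene_id) && gene_id %in% genes$gene_id) {
    win <- cis_window(genes[genes$gene_id == gene_id, , drop = FALSE])
    gchrom <- genes$chrom[genes$gene_id == gene_id]
    df$cis <- df$chrom == gchrom & df$pos >= win[1] & df$pos <= win[2]
    is_cis <- any(df$cis)
  }
  structure(list(analyte_id = df$analyte_id[1], gene_id = gene_id,
                 tissue = df$tissue[1], kind = kind, cis = is_cis,
                 causal_id = NA_character_, shared_with_gwas = NA,
                 stats = df[, setdiff(names(df), c("analyte_id", "tissue"))]),
            class = "qtl_dataset")
}
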