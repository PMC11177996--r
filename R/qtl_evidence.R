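#' Cis window around a gene's transcription start site
#'
#' The TSS is strand-aware (gene start on "+", gene end on "-"); the window
#' is TSS +/- 1 Mb, clipped at coordinate 1.
#'
#' @param gene one-row gene-model data.frame with `start`, `end`, `strand`
#'   (and optionally a precomputed `tss`).
#' @param flank half-width in base pairs (default 1 Mb).
#' @return integer vector `c(start, end)`, 1-based closed.
#' @export
cis_window <- function(gene, flank = 1e6) {
  gene <- as.data.frame(gene)
  if (!"tss" %in% names(gene) || is.na(gene$tss)) {
    if (is.na(gene$strand) || !gene$strand %in% c("+", "-"))
      stop("input error: gene strand missing, cannot place TSS")
    gene$tss <- if (gene$strand == "+") gene$start else gene$end
  }
  c(max(1, gene$tss - flank), gene$tss + flank)
}

#' Does a QTL analyte share a locus with the GWAS signal?
#'
#' True iff any association of the analyte with `p < qtl_gws` (strict) lies
#' within the locus lead +/- 1 Mb on the same chromosome.
#'
#' @param locus a `locus`.
#' @param qtl a `qtl_dataset`.
#' @param qtl_gws genome-wide significance threshold for the QTL
#'   (default 5e-8, reused from the GWAS threshold).
#' @return logical.
#' @export
shared_locus <- function(locus, qtl, qtl_gws = 5e-8) {
  stopifnot(inherits(locus, "locus"))
  st <- qtl$stats
  any(!is.na(st$p) & st$p < qtl_gws &
        st$chrom == locus$chrom & abs(st$pos - locus$pos) <= locus$flank)
}

#' Is the GWAS lead variant itself a genome-wide significant QTL?
#'
#' The lead is matched by chrom:pos:ref:alt with allele harmonization
#' (ref/alt swaps accepted). A lead absent from the QTL panel returns
#' `FALSE` with attribute `reason = "untested"`, distinguishing it from a
#' tested negative.
#'
#' @inheritParams shared_locus
#' @return logical with attribute `reason` ("tested" or "untested").
#' @export
lead_variant_is_qtl <- function(locus, qtl, qtl_gws = 5e-8) {
  stopifnot(inherits(locus, "locus"))
  st <- qtl$stats
  lead <- parse_variant_id(locus$lead_id)
  at_pos <- st$chrom == lead$chrom & st$pos == lead$pos
  same <- at_pos & st$ref == lead$ref & st$alt == lead$alt
  swap <- at_pos & st$ref == lead$alt & st$alt == lead$ref &
    !is_strand_ambiguous(st$ref, st$alt)
  hit <- same | swap
  if (!any(hit)) {
    out <- FALSE
    attr(out, "reason") <- "untested"
    return(out)
  }
  out <- any(!is.na(st$p[hit]) & st$p[hit] < qtl_gws)
  attr(out, "reason") <- "tested"
  out
}

parse_variant_id <- function(id) {
  parts <- strsplit(sub("^chr", "", id), ":")[[1]]
  list(chrom = parts[1], pos = as.integer(parts[2]),
       ref = parts[3], alt = parts[4])
}

#' Tabulate QTL overlap evidence for a set of loci
#'
#' Runs [shared_locus()] and [lead_variant_is_qtl()] for every locus x QTL
#' dataset pair, and asserts the implication that a lead-variant QTL hit
#' entails a shared locus.
#'
#' @param loci list of `locus` objects.
#' @param qtl_datasets list of `qtl_dataset` objects.
#' @param qtl_gws QTL significance threshold.
#' @return data.frame `{locus, gene, kind, tissue, shared_locus,
#'   lead_is_qtl, lead_reason}`.
#' @export
qtl_overlap_evidence <- function(loci, qtl_datasets, qtl_gws = 5e-8) {
  rows <- list()
  for (locus in loci) for (q in qtl_datasets) {
    sl <- shared_locus(locus, q, qtl_gws)
    lq <- lead_variant_is_qtl(locus, q, qtl_gws)
    if (isTRUE(lq) && !sl)
      stop("internal error: lead_variant_is_qtl implies shared_locus")
    rows[[length(rows) + 1]] <- data.frame(
      locus = locus$lead_id, gene = q$gene_id, kind = q$kind,
      tissue = q$tissue, shared_locus = sl, lead_is_qtl = as.logical(lq),
      lead_reason = attr(lq, "reason"), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
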