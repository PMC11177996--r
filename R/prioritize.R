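#' Evidence-category weights for gene nomination
#'
#' A 50-point presence/absence weighting over nine evidence categories.
#' The default table is a reconstruction honoring the published
#' constraints: the weights sum to 50; either colocalization category alone
#' (10) clears the minimum nomination score of 4 (colocalization evidence
#' alone sufficed to nominate genes); lead-variant QTL hits outweigh
#' locus-level overlap; annotation-derived categories carry the least
#' weight. All weights are overridable.
#'
#' @param coloc_pqtl,coloc_eqtl colocalization (PP.H4 >= 0.8) per QTL kind.
#' @param lead_is_pqtl,lead_is_eqtl lead variant is itself a significant QTL.
#' @param shared_locus_pqtl,shared_locus_eqtl significant QTL within the
#'   locus window.
#' @param genebased_significant gene passes the Bonferroni gene-based cutoff.
#' @param nearest_gene gene is nearest to >= 1 genome-wide significant
#'   variant in the locus.
#' @param protein_altering a genome-wide significant variant is
#'   non-synonymous exonic in the gene.
#' @param max_total,min_score,rel_diff scoring constraints: total budget,
#'   minimum nomination score, and the relative-difference pruning fraction.
#' @return object of class `evidence_weights`.
#' @export
evidence_weights <- function(coloc_pqtl = 10, coloc_eqtl = 10,
                             lead_is_pqtl = 6, lead_is_eqtl = 6,
                             shared_locus_pqtl = 4, shared_locus_eqtl = 4,
                             genebased_significant = 4,
                             nearest_gene = 4, protein_altering = 2,
                             max_total = 50, min_score = 4,
                             rel_diff = 0.20) {
  w <- c(coloc_pqtl = coloc_pqtl, coloc_eqtl = coloc_eqtl,
         lead_is_pqtl = lead_is_pqtl, lead_is_eqtl = lead_is_eqtl,
         shared_locus_pqtl = shared_locus_pqtl,
         shared_locus_eqtl = shared_locus_eqtl,
         genebased_significant = genebased_significant,
         nearest_gene = nearest_gene, protein_altering = protein_altering)
  if (any(w < 0)) stop("input error: weights must be nonnegative")
  if (sum(w) > max_total)
    stop("input error: weights exceed the ", max_total, "-point budget")
  if (min_score <= 0) stop("input error: min_score must be positive")
  if (rel_diff <= 0 || rel_diff >= 1)
    stop("input error: rel_diff must lie in (0, 1)")
  structure(list(weights = w, max_total = max_total,
                 min_score = min_score, rel_diff = rel_diff),
            class = "evidence_weights")
}

#' Nearest gene to a variant
#'
#' Distance is to the gene body (0 if inside); ties are broken by distance
#' to the TSS, then by identifier order.
#'
#' @param variant list or one-row data.frame with `chrom` and `pos`.
#' @param gene_models gene models (needs `gene_id, chrom, start, end, tss`).
#' @return gene id, or `NULL` (with a warning) if the chromosome has no
#'   genes.
#' @export
nearest_gene <- function(variant, gene_models) {
  g <- gene_models[gene_models$chrom == as.character(variant$chrom), ,
                   drop = FALSE]
  if (nrow(g) == 0) {
    warning("no genes on chromosome ", variant$chrom)
    return(NULL)
  }
  body_dist <- pmax(0, pmax(g$start - variant$pos, variant$pos - g$end))
  tss_dist <- abs(g$tss - variant$pos)
  ord <- order(body_dist, tss_dist, g$gene_id)
  g$gene_id[ord[1]]
}

#' Build the per-locus gene x evidence matrix
#'
#' One row per genomic feature whose body overlaps the locus lead +/- 1 Mb;
#' boolean columns are filled from colocalization results (PP.H4 >= 0.8 per
#' QTL kind), QTL locus-overlap and lead-variant evidence, gene-based
#' significance at the Bonferroni cutoff, the nearest-gene flag (nearest to
#' at least one genome-wide significant variant in the locus), and the
#' protein-altering flag (a genome-wide significant variant is annotated
#' non-synonymous exonic in the feature).
#'
#' @param locus a `locus`.
#' @param coloc_results list of `coloc_result`s for this locus (or a
#'   data.frame with `gene_id, kind, pp_h4`).
#' @param qtl_evidence data.frame from [qtl_overlap_evidence()].
#' @param gene_results gene-based results from [run_gene_based()] (with a
#'   `cutoff` attribute), or NULL.
#' @param annotations consequence table `{chrom, pos, ref, alt, gene,
#'   consequence}`, or NULL.
#' @param gene_models feature models (genes, lncRNA, pseudogenes; no
#'   biotype filtering).
#' @param sumstats GWAS summary statistics used for the locus (for the
#'   genome-wide significant member variants).
#' @param p_threshold genome-wide significance threshold.
#' @return data.frame of class `evidence_matrix`: one row per feature with
#'   nine boolean columns; attribute `locus`.
#' @export
build_evidence_matrix <- function(locus, coloc_results = list(),
                                  qtl_evidence = NULL, gene_results = NULL,
                                  annotations = NULL, gene_models,
                                  sumstats = NULL, p_threshold = 5e-8) {
  stopifnot(inherits(locus, "locus"))
  feat <- gene_models[gene_models$chrom == locus$chrom &
                        gene_models$end >= locus$start &
                        gene_models$start <= locus$end, , drop = FALSE]
  cats <- names(evidence_weights()$weights)
  if (nrow(feat) == 0) {
    warning("empty window: no features within the locus flanks")
    em <- data.frame(gene = character(0))
    for (cc in cats) em[[cc]] <- logical(0)
    attr(em, "locus") <- locus$lead_id
    class(em) <- c("evidence_matrix", "data.frame")
    return(em)
  }

  em <- data.frame(gene = feat$gene_id, stringsAsFactors = FALSE)
  for (cc in cats) em[[cc]] <- FALSE

  # colocalization flags per QTL kind
  cr <- normalize_coloc_results(coloc_results)
  for (i in seq_len(nrow(cr))) {
    row <- match(cr$gene_id[i], em$gene)
    if (is.na(row) || is.na(cr$pp_h4[i]) || cr$pp_h4[i] < 0.8) next
    if (cr$kind[i] == "pQTL") em$coloc_pqtl[row] <- TRUE
    if (cr$kind[i] == "eQTL") em$coloc_eqtl[row] <- TRUE
  }

  if (!is.null(qtl_evidence) && nrow(qtl_evidence) > 0) {
    qe <- qtl_evidence[qtl_evidence$locus == locus$lead_id, , drop = FALSE]
    for (i in seq_len(nrow(qe))) {
      row <- match(qe$gene[i], em$gene)
      if (is.na(row)) next
      if (qe$kind[i] == "pQTL") {
        em$shared_locus_pqtl[row] <- em$shared_locus_pqtl[row] | qe$shared_locus[i]
        em$lead_is_pqtl[row] <- em$lead_is_pqtl[row] | qe$lead_is_qtl[i]
      }
      if (qe$kind[i] == "eQTL") {
        em$shared_locus_eqtl[row] <- em$shared_locus_eqtl[row] | qe$shared_locus[i]
        em$lead_is_eqtl[row] <- em$lead_is_eqtl[row] | qe$lead_is_qtl[i]
      }
    }
  }

  if (!is.null(gene_results) && nrow(gene_results) > 0) {
    hit <- gene_results$gene[gene_results$significant]
    em$genebased_significant <- em$gene %in% hit
  }

  gws <- NULL
  if (!is.null(sumstats)) {
    gws <- sumstats[!is.na(sumstats$p) & sumstats$p < p_threshold &
                      sumstats$chrom == locus$chrom &
                      abs(sumstats$pos - locus$pos) <= locus$flank, ,
                    drop = FALSE]
    if (nrow(gws) > 0) {
      ng <- unique(vapply(seq_len(nrow(gws)), function(i) {
        res <- suppressWarnings(nearest_gene(gws[i, ], gene_models))
        if (is.null(res)) NA_character_ else res
      }, character(1)))
      em$nearest_gene <- em$gene %in% ng
    }
  }

  if (!is.null(annotations) && !is.null(gws) && nrow(gws) > 0) {
    ann <- annotations[paste(annotations$chrom, annotations$pos,
                             annotations$ref, annotations$alt) %in%
                         paste(gws$chrom, gws$pos, gws$ref, gws$alt), ,
                       drop = FALSE]
    pa <- ann$gene[is_protein_altering(ann$consequence)]
    em$protein_altering <- em$gene %in% pa
  }

  attr(em, "locus") <- locus$lead_id
  class(em) <- c("evidence_matrix", "data.frame")
  em
}

normalize_coloc_results <- function(coloc_results) {
  if (is.data.frame(coloc_results)) {
    df <- coloc_results
    if (!"pp_h4" %in% names(df)) stop("input error: coloc table needs pp_h4")
    return(df[, c("gene_id", "kind", "pp_h4")])
  }
  rows <- lapply(coloc_results, function(r) {
    if (!inherits(r, "coloc_result") || r$status != "ok") return(NULL)
    data.frame(gene_id = r$gene_id, kind = r$kind,
               pp_h4 = unname(r$pp["pp_h4"]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), kind = character(0),
                      pp_h4 = numeric(0)))
  do.call(rbind, rows)
}

is_protein_altering <- function(consequence) {
  tolower(consequence) %in% c("missense", "missense_variant",
                              "nonsynonymous", "nonsynonymous_snv",
                              "stop_gained", "stop_lost", "start_lost",
                              "frameshift", "frameshift_variant",
                              "inframe_insertion", "inframe_deletion")
}

#' Score an evidence matrix
#'
#' Each gene's score is the weighted sum of its true evidence cells.
#'
#' @param matrix an `evidence_matrix`.
#' @param weights an [evidence_weights()].
#' @return the matrix with a `score` column appended.
#' @export
score_genes <- function(matrix, weights = evidence_weights()) {
  w <- weights$weights
  sc <- numeric(nrow(matrix))
  for (cc in names(w)) sc <- sc + as.numeric(matrix[[cc]]) * w[[cc]]
  matrix$score <- sc
  matrix
}

#' Nominate likely functional genes from a scored matrix
#'
#' Keeps genes scoring at least `min_score`; among those, genes whose
#' relative difference from the top score, `(top - score) / top`, is at
#' least `rel_diff` (the comparison is `>=`) are pruned. Survivors are
#' sorted by score (descending), ties broken by number of true evidence
#' categories, then identifier order. An empty nomination is a valid
#' outcome.
#'
#' @param scored a scored `evidence_matrix` (see [score_genes()]).
#' @param weights an [evidence_weights()].
#' @return character vector of nominated gene ids (possibly empty).
#' @export
nominate <- function(scored, weights = evidence_weights()) {
  if (!"score" %in% names(scored)) scored <- score_genes(scored, weights)
  keep <- scored[scored$score >= weights$min_score, , drop = FALSE]
  if (nrow(keep) == 0) return(character(0))
  top <- max(keep$score)
  keep <- keep[(top - keep$score) / top < weights$rel_diff, , drop = FALSE]
  ncat <- rowSums(as.matrix(keep[, names(weights$weights)]))
  keep$gene[order(-keep$score, -ncat, keep$gene)]
}

#' Cell-type specificity by the 1.5x expression-fraction rule
#'
#' Given the fractions of a gene's summed expression contributed by each
#' brain cell type, the gene is called specific to the top cell type iff
#' the top fraction is at least 1.5 times the second-highest; otherwise no
#' call is made.
#'
#' @param fractions named nonnegative fractions summing to 1 (within 1e-6);
#'   at least 2 cell types.
#' @param ratio specificity ratio (default 1.5).
#' @return the specific cell-type name, or `NA_character_` for no call.
#' @export
celltype_specificity <- function(fractions, ratio = 1.5) {
  if (length(fractions) < 2)
    stop("input error: need at least 2 cell types")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-6)
    stop("input error: fractions must be nonnegative and sum to 1")
  ord <- order(fractions, decreasing = TRUE)
  top <- fractions[ord[1]]
  second <- fractions[ord[2]]
  if (top >= ratio * second) names(fractions)[ord[1]] else NA_character_
}
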