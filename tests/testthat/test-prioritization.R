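test_that("default weights respect the published constraints", {
  w <- evidence_weights()
  expect_equal(sum(w$weights), 50)
  expect_gte(w$weights[["coloc_eqtl"]], w$min_score)
  expect_gte(w$weights[["coloc_pqtl"]], w$min_score)
  expect_error(evidence_weights(coloc_pqtl = 40), "budget")
  expect_error(evidence_weights(rel_diff = 1.2), "rel_diff")
})

test_that("nearest gene: body distance, then TSS, then identifier", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "1",
                      start = c(1.00e6, 1.30e6), end = c(1.10e6, 1.40e6),
                      strand = c("+", "+"), tss = c(1.00e6, 1.30e6))
  # inside gene A
  expect_equal(nearest_gene(list(chrom = "1", pos = 1.05e6), genes), "A")
  # 5 kb from A, 195 kb from B
  expect_equal(nearest_gene(list(chrom = "1", pos = 1.105e6), genes), "A")
  # equidistant from both bodies (10 kb): B's TSS is nearer
  v <- list(chrom = "1", pos = 1.20e6)
  expect_equal(abs(1.10e6 - v$pos), abs(1.30e6 - v$pos))
  expect_equal(nearest_gene(v, genes), "B")
  expect_warning(res <- nearest_gene(list(chrom = "7", pos = 1e6), genes),
                 "no genes")
  expect_null(res)
})

test_that("evidence matrix fills categories from the right sources", {
  locus <- make_locus(pos = 2e6)
  genes <- toy_genes()   # GENE1 and DECOY1 in window, FARGENE at 9 Mb
  gws <- make_sumstats(pos = c(2.0e6, 2.42e6), beta = c(1, 0.9),
                       se = c(0.1, 0.1), p = c(1e-9, 2e-8))

  coloc_tab <- data.frame(gene_id = "GENE1", kind = "eQTL", pp_h4 = 0.95)
  qtl_ev <- data.frame(locus = locus$lead_id, gene = "GENE1", kind = "pQTL",
                       tissue = "csf", shared_locus = TRUE,
                       lead_is_qtl = FALSE, lead_reason = "tested")
  gene_res <- data.frame(gene = "DECOY1", n_snps = 3, stat = 5, p = 1e-7,
                         method = "closed_form", significant = TRUE)
  ann <- data.frame(chrom = "1", pos = 2.42e6, ref = "C", alt = "G",
                    gene = "DECOY1", consequence = "missense")
  ann$ref <- gws$ref[2]; ann$alt <- gws$alt[2]

  em <- build_evidence_matrix(locus, coloc_tab, qtl_ev, gene_res, ann,
                              genes, sumstats = gws)
  expect_setequal(em$gene, c("GENE1", "DECOY1"))   # FARGENE excluded
  g1 <- em[em$gene == "GENE1", ]
  expect_true(g1$coloc_eqtl); expect_false(g1$coloc_pqtl)
  expect_true(g1$shared_locus_pqtl); expect_false(g1$lead_is_pqtl)
  d1 <- em[em$gene == "DECOY1", ]
  expect_true(d1$genebased_significant)
  expect_true(d1$protein_altering)
  # nearest-gene flags: 2.0 Mb variant -> GENE1; 2.42 Mb variant -> DECOY1
  expect_true(g1$nearest_gene); expect_true(d1$nearest_gene)

  # sub-threshold coloc does not set the flag
  em2 <- build_evidence_matrix(locus,
                               data.frame(gene_id = "GENE1", kind = "eQTL",
                                          pp_h4 = 0.5),
                               NULL, NULL, NULL, genes)
  expect_false(em2$coloc_eqtl[em2$gene == "GENE1"])

  far_locus <- make_locus(chrom = "22", pos = 2e6)
  expect_warning(em3 <- build_evidence_matrix(far_locus, NULL, NULL, NULL,
                                              NULL, genes), "empty")
  expect_equal(nrow(em3), 0)
})

test_that("scores are the weighted sum of true cells", {
  locus <- make_locus(pos = 2e6)
  genes <- toy_genes()
  em <- build_evidence_matrix(locus, NULL, NULL, NULL, NULL, genes)
  sc <- score_genes(em)
  expect_true(all(sc$score == 0))
  em$coloc_eqtl[1] <- TRUE
  sc1 <- score_genes(em)
  expect_equal(sc1$score[1], evidence_weights()$weights[["coloc_eqtl"]])
  for (cc in names(evidence_weights()$weights)) em[[cc]][1] <- TRUE
  expect_equal(score_genes(em)$score[1], 50)
})

test_that("nomination applies min score and >= 20% relative pruning", {
  mk <- function(scores) {
    em <- data.frame(gene = names(scores))
    for (cc in names(evidence_weights()$weights)) em[[cc]] <- FALSE
    # one true category per unit of score so the tie-break column exists
    em$score <- unname(scores)
    class(em) <- c("evidence_matrix", "data.frame")
    em
  }
  # worked example: C is at exactly 20% difference and is excluded
  out <- nominate(mk(c(A = 10, B = 8.5, C = 8.0, D = 3)))
  expect_identical(out, c("A", "B"))
  expect_identical(nominate(mk(c(A = 3, B = 2))), character(0))
  # the top scorer is always nominated when anything passes
  out2 <- nominate(mk(c(A = 4)))
  expect_identical(out2, "A")

  # a single gene with only eQTL colocalization clears the minimum score
  locus <- make_locus(pos = 2e6)
  em <- build_evidence_matrix(locus,
                              data.frame(gene_id = "GENE1", kind = "eQTL",
                                         pp_h4 = 0.9),
                              NULL, NULL, NULL, toy_genes())
  expect_true("GENE1" %in% nominate(score_genes(em)))
})

test_that("adding evidence never removes a nomination (monotonicity)", {
  set.seed(81)
  w <- evidence_weights()
  cats <- names(w$weights)
  for (r in 1:25) {
    em <- data.frame(gene = c("A", "B", "C"))
    for (cc in cats) em[[cc]] <- runif(3) < 0.3
    class(em) <- c("evidence_matrix", "data.frame")
    before <- nominate(score_genes(em, w), w)
    # flip one false cell of a nominated gene to true
    if (length(before) == 0) next
    gidx <- match(before[1], em$gene)
    off <- cats[!unlist(em[gidx, cats])]
    if (length(off) == 0) next
    em2 <- em
    em2[gidx, off[1]] <- TRUE
    after <- nominate(score_genes(em2[, c("gene", cats)], w), w)
    expect_true(before[1] %in% after)
  }
})

test_that("cell-type specificity uses the 1.5x ratio rule", {
  f <- c(astro = 0.45, neuron = 0.30, oligo = 0.25)
  expect_equal(celltype_specificity(f), "astro")       # 45 >= 1.5 * 30
  expect_true(is.na(celltype_specificity(c(a = 0.5, b = 0.5))))
  f2 <- c(a = 0.45, b = 0.301, c = 0.249)
  expect_true(is.na(celltype_specificity(f2)))         # 1.495 < 1.5
  expect_error(celltype_specificity(c(a = 1)), "input error")
  expect_error(celltype_specificity(c(a = 0.7, b = 0.7)), "input error")
})
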