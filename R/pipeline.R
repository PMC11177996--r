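#' Pipeline configuration
#'
#' Bundles every stage's settings. Each published analysis threshold is a
#' named key with its conventional default: genome-wide significance 5e-8,
#' 1 Mb locus flanks, PP.H4 >= 0.8 colocalization, minimum nomination score
#' 4 with 20% relative-difference pruning, the 1.5x cell-type ratio, MAC 5,
#' and the strict analysis-time Hardy-Weinberg filter at 1e-30.
#'
#' @param sim a [sim_config()].
#' @param out_dir output directory for stage files and the manifest.
#' @param stages character vector of enabled stages, in any order; the
#'   pipeline executes them in dependency order.
#' @param qc a [qc_thresholds()].
#' @param priors a [coloc_priors()].
#' @param weights an [evidence_weights()].
#' @param prs a [prs_config()].
#' @param p_threshold,flank locus definition parameters.
#' @param strict_hwe_p analysis-time Hardy-Weinberg cutoff.
#' @param qtl_gws QTL genome-wide significance threshold.
#' @param annotations optional variant consequence table
#'   `{chrom, pos, ref, alt, gene, consequence}`.
#' @param gene_test_draws Monte-Carlo draws for the gene-based null.
#' @param log_level "quiet" or "info".
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, out_dir = NULL,
                            stages = c("simulate", "qc", "gwas", "condition",
                                       "meta", "coloc", "overlap", "genetest",
                                       "prs", "prioritize", "report"),
                            qc = qc_thresholds(), priors = coloc_priors(),
                            weights = evidence_weights(),
                            prs = prs_config(),
                            p_threshold = 5e-8, flank = 1e6,
                            strict_hwe_p = 1e-30, qtl_gws = 5e-8,
                            annotations = NULL, gene_test_draws = 1e5,
                            log_level = "info") {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, out_dir = out_dir, stages = stages, qc = qc,
                 priors = priors, weights = weights, prs = prs,
                 p_threshold = p_threshold, flank = flank,
                 strict_hwe_p = strict_hwe_p, qtl_gws = qtl_gws,
                 annotations = annotations,
                 gene_test_draws = gene_test_draws,
                 log_level = log_level),
            class = "pipeline_config")
}

stage_deps <- list(
  simulate = character(0), qc = "simulate", gwas = "qc", condition = "gwas",
  meta = "gwas", coloc = c("gwas", "meta"), overlap = c("gwas", "meta"),
  genetest = "gwas", prs = c("gwas", "meta"),
  prioritize = c("coloc", "overlap", "genetest"), report = character(0))

#' Run the full locus-nomination pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic study:
#' simulate, QC, per-ancestry GWAS (with the strict analysis-time HWE
#' filter and genomic-inflation check), stepwise conditional analysis,
#' trans-ancestry meta-analysis, locus definition, colocalization and QTL
#' overlap against every simulated QTL dataset, the gene-based test, PRS
#' (base = trans-ancestry meta statistics, target = the first ancestry),
#' gene prioritization, and a human-readable report. Any stage failure
#' aborts with the stage name; a stage whose dependency is disabled raises
#' a dependency error naming both stages.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (named list; also written as JSON when
#'   `out_dir` is set), including the locus table, nominations, PRS table
#'   and per-stage counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  enabled <- config$stages
  for (st in enabled)
    for (dep in stage_deps[[st]])
      if (!dep %in% enabled)
        stop("dependency error: stage '", st, "' requires stage '", dep, "'")

  say <- function(...) if (config$log_level != "quiet") message(...)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  manifest <- list(seed = config$sim$seed, stages = enabled, counts = list())
  env <- new.env()

  run_stage <- function(name, fn) {
    if (!name %in% enabled) return(invisible(NULL))
    say("stage: ", name)
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  run_stage("simulate", function() {
    env$study <- simulate_study(config$sim,
                                if (!is.null(out_dir))
                                  file.path(out_dir, "sim") else NULL)
    manifest$counts$simulate <<- list(
      ancestries = length(env$study$genotypes),
      n_variants = config$sim$n_variants,
      qtl_datasets = length(env$study$qtl_datasets))
  })

  run_stage("qc", function() {
    env$qc <- lapply(env$study$genotypes, apply_variant_qc,
                     thresholds = config$qc)
    manifest$counts$qc <<- lapply(env$qc, function(q) q$report)
  })

  run_stage("gwas", function() {
    env$stats <- list(); env$lambda <- list()
    for (lab in names(env$qc)) {
      g <- env$qc[[lab]]$genotypes
      # strict analysis-time HWE filter (catches merge artifacts)
      d <- g$dosage
      hwe <- mapply(hwe_exact_test, colSums(d == 0, na.rm = TRUE),
                    colSums(d == 1, na.rm = TRUE),
                    colSums(d == 2, na.rm = TRUE))
      keep <- hwe >= config$strict_hwe_p
      g$dosage <- g$dosage[, keep, drop = FALSE]
      g$variants <- g$variants[keep, , drop = FALSE]
      s <- suppressMessages(run_single_variant_gwas(
        g, env$study$phenotypes[[lab]], ancestry = lab))
      env$stats[[lab]] <- s
      env$qc[[lab]]$genotypes <- g
      env$lambda[[lab]] <- genomic_inflation(s$p[!is.na(s$p)])
      if (!is.null(out_dir))
        write_sumstats_tsv(s, file.path(out_dir,
                                        paste0("gwas_", lab, ".tsv")))
    }
    manifest$counts$gwas <<- list(
      lambda = lapply(env$lambda, function(x) round(x, 4)),
      n_tested = lapply(env$stats, nrow))
  })

  run_stage("meta", function() {
    env$meta <- run_trans_ancestry_meta(env$stats)
    if (!is.null(out_dir))
      write_sumstats_tsv(env$meta, file.path(out_dir, "meta.tsv"))
    env$loci <- define_loci(env$meta, config$p_threshold, config$flank,
                            gene_models = env$study$genes)
    manifest$counts$meta <<- list(n_variants = nrow(env$meta),
                                  n_loci = length(env$loci))
  })

  run_stage("condition", function() {
    lab <- names(env$stats)[1]
    anc_loci <- define_loci(env$stats[[lab]], config$p_threshold,
                            config$flank)
    env$signals <- lapply(anc_loci, function(l)
      stepwise_conditional(l, env$qc[[lab]]$genotypes,
                           env$study$phenotypes[[lab]],
                           p_threshold = config$p_threshold))
    manifest$counts$condition <<- list(
      n_loci = length(anc_loci),
      n_signals = vapply(env$signals,
                         function(s) length(s$independent_signals),
                         numeric(1)))
  })

  run_stage("coloc", function() {
    lab <- names(env$stats)[1]
    env$coloc <- list()
    for (l in env$loci) for (q in env$study$qtl_datasets)
      env$coloc[[length(env$coloc) + 1]] <-
      coloc_gwas_locus(l, env$stats[[lab]], q, priors = config$priors)
    manifest$counts$coloc <<- list(
      n_tests = length(env$coloc),
      n_colocalized = sum(vapply(env$coloc,
                                 function(r) isTRUE(r$colocalizes),
                                 logical(1))))
  })

  run_stage("overlap", function() {
    env$overlap <- qtl_overlap_evidence(env$loci, env$study$qtl_datasets,
                                        config$qtl_gws)
    manifest$counts$overlap <<- list(
      n_shared = sum(env$overlap$shared_locus),
      n_lead_hits = sum(env$overlap$lead_is_qtl))
  })

  run_stage("genetest", function() {
    lab <- names(env$stats)[1]
    env$genetest <- run_gene_based(env$stats[[lab]],
                                   env$qc[[lab]]$genotypes,
                                   env$study$genes,
                                   n_draws = config$gene_test_draws,
                                   seed = config$sim$seed)
    manifest$counts$genetest <<- list(
      n_genes = nrow(env$genetest),
      cutoff = attr(env$genetest, "cutoff"),
      n_significant = sum(env$genetest$significant))
  })

  run_stage("prs", function() {
    lab <- names(env$stats)[1]
    base <- env$meta
    base$maf <- env$stats[[lab]]$maf[match(base$id, env$stats[[lab]]$id)]
    env$prs <- run_prs(base, env$qc[[lab]]$genotypes,
                       env$study$phenotypes[[lab]], config$prs)
    manifest$counts$prs <<- list(n_thresholds = nrow(env$prs))
  })

  run_stage("prioritize", function() {
    env$matrices <- list(); noms <- list()
    lab <- names(env$stats)[1]
    for (l in env$loci) {
      em <- build_evidence_matrix(l, env$coloc, env$overlap, env$genetest,
                                  config$annotations, env$study$genes,
                                  sumstats = env$stats[[lab]],
                                  p_threshold = config$p_threshold)
      em <- score_genes(em, config$weights)
      env$matrices[[l$lead_id]] <- em
      noms[[l$lead_id]] <- nominate(em, config$weights)
    }
    env$nominations <- noms
    manifest$counts$prioritize <<- list(
      n_nominated = sum(lengths(noms)))
  })

  # assemble the reportable tables into the manifest
  if (!is.null(env$loci)) {
    manifest$loci <- lapply(env$loci, function(l) {
      row <- list(lead = l$lead_id, chrom = l$chrom, pos = l$pos,
                  meta_p = l$p, nearest_gene = l$nearest_gene)
      for (lab in names(env$stats)) {
        s <- env$stats[[lab]]
        i <- match(l$lead_id, s$id)
        row[[paste0("beta_", lab)]] <- if (is.na(i)) NA else s$beta[i]
        row[[paste0("p_", lab)]] <- if (is.na(i)) NA else s$p[i]
      }
      if (!is.null(env$coloc)) {
        pp <- vapply(env$coloc, function(r)
          if (identical(r$locus, l$lead_id) && r$status == "ok")
            unname(r$pp["pp_h4"]) else NA_real_, numeric(1))
        row$best_pp_h4 <- if (all(is.na(pp))) NA else max(pp, na.rm = TRUE)
      }
      row
    })
  }
  if (!is.null(env$nominations)) manifest$nominations <- env$nominations
  if (!is.null(env$prs)) manifest$prs <- env$prs
  manifest$counts <- manifest$counts

  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if ("report" %in% enabled)
      write_report(manifest, file.path(out_dir, "report.txt"))
  }
  manifest$results <- as.list(env)
  invisible(manifest)
}

#' Write a human-readable run report
#'
#' Summarizes the locus table (per-ancestry beta/P, meta P, best PP.H4),
#' nominated genes per locus, the PRS table, and QC counts. Regeneration
#' from the same manifest is idempotent.
#'
#' @param manifest a manifest from [run_pipeline()] (or read back from
#'   `manifest.json`).
#' @param path output file.
#' @return the report lines, invisibly.
#' @export
write_report <- function(manifest, path = NULL) {
  lines <- c("locusnominator run report",
             paste0("seed: ", manifest$seed),
             paste0("stages: ", paste(unlist(manifest$stages),
                                      collapse = ", ")), "")
  loci <- manifest$loci
  if (is.null(loci) || length(loci) == 0) {
    lines <- c(lines, "Loci: zero genome-wide significant loci.")
  } else {
    lines <- c(lines, sprintf("Loci (%d):", length(loci)))
    for (l in loci) {
      lines <- c(lines, sprintf(
        "  %s (chr%s:%s)  meta P = %.3g  nearest gene = %s  best PP.H4 = %s",
        l$lead, l$chrom, format(l$pos, big.mark = ","), as.numeric(l$meta_p),
        if (is.null(l$nearest_gene) || is.na(l$nearest_gene)) "-"
        else l$nearest_gene,
        if (is.null(l$best_pp_h4) || is.na(l$best_pp_h4)) "-"
        else sprintf("%.3f", as.numeric(l$best_pp_h4))))
      per_anc <- grep("^p_", names(l), value = TRUE)
      for (pa in per_anc) {
        lab <- sub("^p_", "", pa)
        b <- l[[paste0("beta_", lab)]]
        lines <- c(lines, sprintf(
          "      %-10s beta = %s  P = %s", lab,
          if (is.null(b) || is.na(b)) "NA" else sprintf("%.3f",
                                                        as.numeric(b)),
          if (is.null(l[[pa]]) || is.na(l[[pa]])) "NA"
          else sprintf("%.3g", as.numeric(l[[pa]]))))
      }
    }
  }
  lines <- c(lines, "")
  noms <- manifest$nominations
  if (!is.null(noms)) {
    lines <- c(lines, "Nominated genes:")
    for (nm in names(noms)) {
      g <- unlist(noms[[nm]])
      lines <- c(lines, sprintf("  %s: %s", nm,
                                if (length(g) == 0) "(none)"
                                else paste(g, collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  prs <- manifest$prs
  if (!is.null(prs)) {
    prs <- as.data.frame(prs)
    lines <- c(lines, "PRS (base = trans-ancestry meta):")
    for (i in seq_len(nrow(prs)))
      lines <- c(lines, sprintf(
        "  P <= %-8.0e n_snps = %-5d Nagelkerke R2 = %s  P = %s",
        prs$threshold[i], prs$n_snps[i],
        if (is.na(prs$r2_nagelkerke[i])) "NA"
        else sprintf("%.4f", prs$r2_nagelkerke[i]),
        if (is.na(prs$p[i])) "NA" else sprintf("%.3g", prs$p[i])))
    lines <- c(lines, "")
  }
  qc <- manifest$counts$qc
  if (!is.null(qc)) {
    lines <- c(lines, "QC:")
    for (lab in names(qc))
      lines <- c(lines, sprintf(
        "  %s: %s/%s variants kept (call rate %s, HWE %s, MAC %s failures)",
        lab, qc[[lab]]$n_kept, qc[[lab]]$n_variants_in,
        qc[[lab]]$n_fail_call_rate, qc[[lab]]$n_fail_hwe,
        qc[[lab]]$n_fail_mac))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
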