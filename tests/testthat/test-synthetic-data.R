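test_that("config validation names the offending field", {
  anc <- list(list(label = "A", n_cases = 10, n_controls = 10))
  expect_error(sim_config(1, anc, 10,
                          list(list(n_snps = 5, rho = 0.5))),
               "n_snps")
  expect_error(sim_config(1, anc, 10,
                          list(list(n_snps = 10, rho = 1.0))),
               "rho")
  expect_error(sim_config(1, anc, 10, list(list(n_snps = 10, rho = 0)),
                          maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(sim_config(1, anc, 10, list(list(n_snps = 10, rho = 0)),
                          causal_variants = list(list(variant_index = 11,
                                                      beta = 1))),
               "variant_index")
  expect_error(sim_config(1, anc, 10, list(list(n_snps = 10, rho = 0)),
                          cohorts = list(list(label = "c", array_label = "a",
                                              fraction = 0.5))),
               "fraction")
})

test_that("allele frequencies match their targets within Monte-Carlo error", {
  cfg <- sim_config(3, list(list(label = "A", n_cases = 5000,
                                 n_controls = 5000)),
                    n_variants = 12,
                    ld_blocks = list(list(n_snps = 12, rho = 0)),
                    maf_range = c(0.30, 0.30))
  g <- simulate_genotypes(cfg, "A")
  af <- colMeans(g$dosage) / 2
  # binomial SE at n = 10,000 individuals (20,000 alleles) ~ 0.0032
  expect_true(all(abs(af - 0.30) < 0.01))
})

test_that("LD structure: rho = 0 gives independence, AR(1) decays", {
  cfg0 <- sim_config(4, list(list(label = "A", n_cases = 5000,
                                  n_controls = 5000)),
                     n_variants = 10,
                     ld_blocks = list(list(n_snps = 10, rho = 0)),
                     maf_range = c(0.2, 0.4))
  g0 <- simulate_genotypes(cfg0, "A")
  r2 <- cor(g0$dosage)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)

  cfg9 <- sim_config(4, list(list(label = "A", n_cases = 5000,
                                  n_controls = 5000)),
                     n_variants = 10,
                     ld_blocks = list(list(n_snps = 10, rho = 0.9)),
                     maf_range = c(0.2, 0.4))
  g9 <- simulate_genotypes(cfg9, "A")
  r2 <- cor(g9$dosage)^2
  expect_gt(r2[1, 2], r2[1, 6])   # adjacent pair vs pair 5 apart
})

test_that("simulation is deterministic given the config seed", {
  cfg <- small_study_config(seed = 11)
  a <- simulate_genotypes(cfg, "POP1")
  b <- simulate_genotypes(cfg, "POP1")
  expect_identical(a$dosage, b$dosage)
  pa <- simulate_phenotypes(a, cfg, "POP1")
  pb <- simulate_phenotypes(b, cfg, "POP1")
  expect_identical(pa, pb)
  qa <- simulate_qtl_dataset(a, cfg$qtl_specs[[1]], cfg)
  qb <- simulate_qtl_dataset(b, cfg$qtl_specs[[1]], cfg)
  expect_identical(qa$stats, qb$stats)
})

test_that("null phenotype model hits the prevalence target", {
  cfg <- sim_config(5, list(list(label = "A", n_cases = 3000,
                                 n_controls = 7000)),
                    n_variants = 5,
                    ld_blocks = list(list(n_snps = 5, rho = 0)),
                    maf_range = c(0.2, 0.4),
                    prevalence_target = 0.30)
  g <- simulate_genotypes(cfg, "A")
  ph <- simulate_phenotypes(g, cfg, "A")
  expect_lt(abs(mean(ph$status == "case") - 0.30), 0.015)
})

test_that("case/control age partition holds for every sample", {
  cfg <- small_study_config(seed = 6)
  g <- simulate_genotypes(cfg, "POP1")
  ph <- simulate_phenotypes(g, cfg, "POP1")
  expect_true(all(ph$age[ph$status == "case"] <= 70))
  expect_true(all(ph$age[ph$status == "control"] > 70))
})

test_that("positive causal effect raises case dosage at the causal variant", {
  cfg <- small_study_config(seed = 8, n_cases = 2500, n_controls = 2500,
                            beta = log(2))
  g <- simulate_genotypes(cfg, "POP1")
  ph <- simulate_phenotypes(g, cfg, "POP1")
  d <- g$dosage[, 30]
  expect_gt(mean(d[ph$status == "case"]), mean(d[ph$status == "control"]))
})

test_that("QTL scan is calibrated under the null and powered under signal", {
  cfg <- small_study_config(seed = 9, n_snps = 200, rho = 0,
                            qtl_effect = 0, n_qtl = 500)
  panel <- simulate_genotypes(cfg, "qtl_panel", n = 500)
  q0 <- simulate_qtl_dataset(panel, cfg$qtl_specs[[1]], cfg)
  # null: ~5% of variants at P < 0.05, binomial SE ~ 1.5%
  expect_lt(abs(mean(q0$stats$p < 0.05) - 0.05), 0.05)

  # effect 1.0 sd/allele at n = 1000: non-centrality ~ n*2f(1-f) => power ~ 1
  hits <- vapply(1:20, function(s) {
    cfg1 <- small_study_config(seed = 100 + s, n_snps = 40, rho = 0,
                               qtl_effect = 1.0, n_qtl = 1000)
    p1 <- simulate_genotypes(cfg1, "qtl_panel", n = 1000)
    q1 <- simulate_qtl_dataset(p1, cfg1$qtl_specs[[1]], cfg1)
    q1$stats$p[30] < 5e-8
  }, logical(1))
  expect_true(all(hits))
})

test_that("shared_with_gwas ties the QTL causal index to a GWAS causal index", {
  cfg <- small_study_config(seed = 10, qtl_causal = 30)
  panel <- simulate_genotypes(cfg, "qtl_panel", n = 300)
  q <- simulate_qtl_dataset(panel, cfg$qtl_specs[[1]], cfg)
  expect_true(q$shared_with_gwas)
  expect_identical(q$causal_id, panel$variants$id[30])
})

test_that("monomorphic causal variant raises a simulation error", {
  cfg <- small_study_config(seed = 12)
  panel <- simulate_genotypes(cfg, "qtl_panel", n = 50)
  panel$dosage[, 30] <- 0L
  expect_error(simulate_qtl_dataset(panel, cfg$qtl_specs[[1]], cfg),
               "monomorphic")
})

test_that("missingness knob produces missing dosages for QC to catch", {
  cfg <- small_study_config(seed = 13)
  cfg$missing_rate <- 0.2
  g <- simulate_genotypes(cfg, "POP1")
  expect_gt(mean(is.na(g$dosage)), 0.1)
  expect_true(all(g$dosage %in% c(0L, 1L, 2L, NA)))
})
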