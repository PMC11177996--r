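test_that("clumping keeps index variants by the r2/kb rule", {
  set.seed(71)
  n <- 1000
  d1 <- rbinom(n, 2, 0.3)
  flip <- runif(n) < 0.25
  d2 <- ifelse(flip, rbinom(n, 2, 0.3), d1)     # r2 ~ 0.5 with d1
  d3 <- rbinom(n, 2, 0.3)                        # independent

  # pair 50 kb apart, correlated -> only the more significant survives
  g <- make_genotypes(cbind(d1, d2), pos = c(1e6, 1.05e6))
  base <- data.frame(chrom = "1", pos = c(1e6, 1.05e6),
                     id = g$variants$id, p = c(1e-9, 1e-5))
  expect_gt(cor(d1, d2)^2, 0.1)
  expect_equal(clump(base, g), g$variants$id[1])

  # same pair 300 kb apart -> outside the 250 kb window, both kept
  g2 <- make_genotypes(cbind(d1, d2), pos = c(1e6, 1.3e6))
  base2 <- data.frame(chrom = "1", pos = c(1e6, 1.3e6),
                      id = g2$variants$id, p = c(1e-9, 1e-5))
  expect_setequal(clump(base2, g2), g2$variants$id)

  # uncorrelated neighbour is kept; single variant clumps to itself
  g3 <- make_genotypes(cbind(d1, d3), pos = c(1e6, 1.05e6))
  base3 <- data.frame(chrom = "1", pos = c(1e6, 1.05e6),
                      id = g3$variants$id, p = c(1e-9, 1e-5))
  expect_setequal(clump(base3, g3), g3$variants$id)
  expect_equal(clump(base3[1, ], g3), g3$variants$id[1])
})

test_that("clumped sets satisfy the pairwise-r2 invariant (brute force)", {
  cfg <- small_study_config(seed = 72, n_snps = 80, rho = 0.7)
  g <- simulate_genotypes(cfg, "qtl_panel", n = 800)
  set.seed(73)
  base <- data.frame(chrom = "1", pos = g$variants$pos,
                     id = g$variants$id, p = runif(80))
  kept <- clump(base, g, prs_config())
  kd <- g$dosage[, kept, drop = FALSE]
  pos <- g$variants$pos[match(kept, g$variants$id)]
  for (i in seq_along(kept)) for (j in seq_len(i - 1)) {
    if (abs(pos[i] - pos[j]) <= 250 * 1000)
      expect_lte(cor(kd[, i], kd[, j])^2, 0.1 + 1e-12)
  }
  # every dropped variant has an explaining kept variant
  dropped <- setdiff(base$id, kept)
  for (id in dropped) {
    pd <- g$variants$pos[match(id, g$variants$id)]
    near <- kept[abs(pos - pd) <= 250 * 1000]
    r2 <- vapply(near, function(k)
      cor(g$dosage[, id], g$dosage[, k])^2, numeric(1))
    expect_true(any(r2 > 0.1), label = id)
  }
})

test_that("APOE-region exclusion uses the closed interval on chr19", {
  base <- data.frame(chrom = c("19", "19", "19", "1"),
                     pos = c(45000000, 44000008, 44000009, 45000000),
                     id = letters[1:4], p = 0.5)
  out <- exclude_apoe(base, prs_config(include_apoe = FALSE))
  expect_setequal(out$id, c("b", "d"))   # 44,000,008 is below the region
  keep <- exclude_apoe(base, prs_config(include_apoe = TRUE))
  expect_equal(nrow(keep), 4)
})

test_that("scoring is a dosage-weighted sum with harmonization", {
  g <- make_genotypes(matrix(c(0L, 1L, 2L), ncol = 1), pos = 1e6)
  base <- data.frame(chrom = "1", pos = 1e6, ref = g$variants$ref,
                     alt = g$variants$alt, id = g$variants$id,
                     beta = 0.5, p = 1e-9, maf = 0.3)
  sc <- score_samples(g, base, clumped = base$id, threshold = 5e-8)
  expect_equal(as.numeric(sc), c(0, 0.5, 1.0))

  # allele-flipped base row gives identical scores up to a constant shift
  flipped <- base
  flipped$ref <- base$alt; flipped$alt <- base$ref; flipped$beta <- -0.5
  sc2 <- score_samples(g, flipped, clumped = flipped$id, threshold = 5e-8)
  expect_equal(diff(unname(sc)), diff(unname(sc2)))

  # no variant at the strictest threshold: flagged all-zero scores
  weak <- base; weak$p <- 1e-4
  sc3 <- score_samples(g, weak, clumped = weak$id, threshold = 5e-8)
  expect_true(attr(sc3, "empty"))
  expect_equal(as.numeric(sc3), c(0, 0, 0))

  # missing dosage contributes 2 * base allele frequency * beta
  gm <- make_genotypes(matrix(c(NA, 1L, 2L), ncol = 1), pos = 1e6)
  sc4 <- score_samples(gm, base, clumped = base$id, threshold = 5e-8)
  expect_equal(unname(sc4[1]), 2 * 0.3 * 0.5)
})

test_that("Nagelkerke R2: separation, null and constant-score cases", {
  # perfectly separating balanced toy: Cox-Snell 0.75, Nagelkerke 1
  status <- rep(c("case", "control"), each = 50)
  scores <- c(rnorm(50, 5), rnorm(50, -5))
  res <- prs_association(scores, status)
  expect_true(res$separation)
  expect_equal(res$r2_nagelkerke, 1.0)
  expect_equal(res$r2_coxsnell, 0.75, tolerance = 1e-10)

  # constant score
  res0 <- prs_association(rep(1, 100), status)
  expect_equal(res0$r2_nagelkerke, 0)

  # independent score: R2 near zero most of the time
  set.seed(74)
  null_r2 <- vapply(1:20, function(i) {
    st <- sample(rep(c("case", "control"), each = 500))
    prs_association(rnorm(1000), st)$r2_nagelkerke
  }, numeric(1))
  expect_gte(mean(null_r2 < 0.01), 0.9)
  expect_error(prs_association(rnorm(4), c("case", "case", "case",
                                           "control")), "input error")
})

test_that("threshold sets are nested and R2 grows with genetic overlap", {
  cfg <- small_study_config(seed = 75, n_cases = 1000, n_controls = 1000,
                            beta = log(1.8))
  g <- simulate_genotypes(cfg, "POP1")
  ph <- simulate_phenotypes(g, cfg, "POP1")
  s <- suppressMessages(run_single_variant_gwas(g, ph,
                                                covariate_names = character(0)))
  res <- run_prs(s, g, ph, prs_config())
  expect_true(all(diff(res$n_snps) >= 0))  # nested by construction

  # monotone recovery across three base-effect tiers (same target cohort)
  r2 <- vapply(c(0, log(1.4), log(2.2)), function(b) {
    cfgb <- small_study_config(seed = 76, n_cases = 1000,
                               n_controls = 1000, beta = b)
    gb <- simulate_genotypes(cfgb, "POP1")
    phb <- simulate_phenotypes(gb, cfgb, "POP1")
    sb <- suppressMessages(run_single_variant_gwas(gb, phb,
                                                   covariate_names = character(0)))
    resb <- run_prs(sb, gb, phb, prs_config())
    resb$r2_nagelkerke[resb$threshold == 5e-1]
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})
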