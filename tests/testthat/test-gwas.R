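test_that("logistic scan reproduces the closed-form 2x2 log odds ratio", {
  # carriers: 10 cases / 90 controls exposed, 30 / 70 unexposed=... the
  # binary-dosage table (a=10, b=90, c=30, d=70) has log OR ln(10*70/(90*30))
  y <- c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70))
  dose <- c(rep(1L, 100), rep(0L, 100))
  g <- make_genotypes(matrix(dose, ncol = 1))
  ph <- data.frame(sample_id = g$sample_ids,
                   status = ifelse(y == 1, "case", "control"))
  s <- run_single_variant_gwas(g, ph, covariate_names = character(0))
  expect_equal(s$beta[1], log(10 * 70 / (90 * 30)), tolerance = 1e-6)
  expect_equal(s$beta[1], -1.3499, tolerance = 1e-4)
})

test_that("logistic fit agrees with stats::glm on a covariate toy", {
  set.seed(21)
  n <- 300
  d <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  x1 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * d[, 1] + 0.4 * x1))
  g <- make_genotypes(d)
  ph <- data.frame(sample_id = g$sample_ids,
                   status = ifelse(y == 1, "case", "control"),
                   pc1 = x1)
  s <- run_single_variant_gwas(g, ph, covariate_names = "pc1")
  ref <- glm(y ~ d[, 1] + x1, family = binomial())
  expect_equal(s$beta[1], unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(s$se[1], unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-6)
})

test_that("Wald interval covers the true effect at roughly nominal rate", {
  cover <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    n <- 600
    d <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.4 + log(1.5) * d))
    g <- make_genotypes(matrix(d, ncol = 1))
    ph <- data.frame(sample_id = g$sample_ids,
                     status = ifelse(y == 1, "case", "control"))
    s <- suppressMessages(run_single_variant_gwas(g, ph,
                                                  covariate_names = character(0)))
    abs(s$beta[1] - log(1.5)) < 1.96 * s$se[1]
  }, logical(1))
  expect_gte(mean(cover), 0.88)  # 95% nominal, binomial noise at 100 reps
})

test_that("age is never used as a covariate", {
  set.seed(22)
  d <- matrix(rbinom(100, 2, 0.3), ncol = 1)
  g <- make_genotypes(d)
  ph <- data.frame(sample_id = g$sample_ids,
                   status = rep(c("case", "control"), 50),
                   age = c(runif(50, 40, 70), runif(50, 71, 95)))
  expect_warning(s <- run_single_variant_gwas(g, ph,
                                              covariate_names = "age"),
                 "age")
  expect_false("age" %in% attr(s, "covariates"))
})

test_that("genomic inflation follows the median chi-square definition", {
  expect_equal(genomic_inflation(rep(0.5, 101)), 1.0, tolerance = 1e-4)
  # a median chi-square of 0.90988 is exactly twice the null expectation
  p2 <- pchisq(0.90988, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(rep(p2, 11)), 2.0, tolerance = 1e-4)
  set.seed(23)
  expect_equal(genomic_inflation(runif(1e5)), 1.0, tolerance = 0.02)
  expect_error(genomic_inflation(c(0.5, 0)), "input error")
  expect_error(genomic_inflation(c(0.5, 1.2)), "input error")
})

test_that("locus definition is greedy with 1 Mb absorption", {
  s <- make_sumstats(pos = c(1.0e6, 1.5e6), beta = c(1, 1),
                     se = c(0.1, 0.1), p = c(1e-9, 1e-8))
  loci <- define_loci(s)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$pos, 1.0e6)
  expect_length(loci[[1]]$members, 2)

  expect_length(define_loci(make_sumstats(1e6, 0.1, 0.1, p = 1e-5)), 0)

  s2 <- rbind(make_sumstats(1.0e6, 1, 0.1, p = 1e-9, chrom = "1"),
              make_sumstats(1.0e6, 1, 0.1, p = 1e-10, chrom = "2"))
  expect_length(define_loci(s2), 2)

  # every GWS variant in exactly one locus; leads far apart
  set.seed(24)
  pos <- sort(sample(seq(1e6, 60e6, by = 1e4), 40))
  p <- 10^-runif(40, 7.5, 15)
  s3 <- make_sumstats(pos, beta = 1, se = 0.1, p = p)
  loci3 <- define_loci(s3)
  members <- unlist(lapply(loci3, `[[`, "members"))
  gws <- s3$id[s3$p < 5e-8]
  expect_setequal(members, gws)
  expect_equal(anyDuplicated(members), 0)
  leads <- vapply(loci3, `[[`, numeric(1), "pos")
  if (length(leads) > 1)
    expect_true(all(abs(outer(leads, leads, "-"))[upper.tri(diag(length(leads)))] > 1e6))
})

test_that("cohort heterogeneity matches the hand-computed Q", {
  h <- cohort_heterogeneity(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3))
  expect_equal(h$Q, 0); expect_equal(h$het_p, 1)
  h2 <- cohort_heterogeneity(c(0.0, 1.0), c(0.1, 0.1))
  expect_equal(h2$Q, 50, tolerance = 1e-10)
  expect_equal(h2$het_p, pchisq(50, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(h2$heterogeneous)
  # boundary: het_p = 0.05 exactly is NOT flagged (strict inequality)
  q05 <- qchisq(0.05, 1, lower.tail = FALSE)
  b <- sqrt(q05 / 2) * 0.1    # two cohorts +/-b/..., SE 0.1 gives Q = q05
  h3 <- cohort_heterogeneity(c(0, 2 * b), c(0.1, 0.1))
  expect_equal(h3$het_p, 0.05, tolerance = 1e-12)
  expect_false(h3$heterogeneous)
  expect_error(cohort_heterogeneity(c(1), c(0.1)), "input error")
  expect_error(cohort_heterogeneity(c(1, 1), c(0.1, 0)), "input error")
})

test_that("stepwise conditional analysis recovers independent signals", {
  # two strong causal variants in near-linkage-equilibrium -> 2 signals
  cfg <- sim_config(31, list(list(label = "P", n_cases = 1500,
                                  n_controls = 1500)),
                    n_variants = 40,
                    ld_blocks = list(list(n_snps = 40, rho = 0.3)),
                    maf_range = c(0.2, 0.5),
                    causal_variants = list(list(variant_index = 10, beta = 0.55),
                                           list(variant_index = 30, beta = 0.55)),
                    bp_spacing = 2000)
  g <- simulate_genotypes(cfg, "P")
  ph <- simulate_phenotypes(g, cfg, "P")
  s <- suppressMessages(run_single_variant_gwas(g, ph,
                                                covariate_names = character(0)))
  loci <- define_loci(s)
  expect_length(loci, 1)
  sc <- stepwise_conditional(loci[[1]], g, ph,
                             covariate_names = character(0))
  expect_gte(length(sc$independent_signals), 2)
  # conditional chain P values at inclusion all below the threshold
  expect_true(all(sc$steps < 5e-8))
})

test_that("near-collinear duplicated signal stops the conditional chain", {
  set.seed(32)
  n <- 2000
  d1 <- rbinom(n, 2, 0.3)
  # r2 ~ 0.97 copy plus mild noise
  d2 <- pmin(2L, pmax(0L, d1 + as.integer(runif(n) < 0.02) -
                        as.integer(runif(n) < 0.02)))
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * d1))
  g <- make_genotypes(cbind(d1, d2))
  ph <- data.frame(sample_id = g$sample_ids,
                   status = ifelse(y == 1, "case", "control"))
  s <- suppressMessages(run_single_variant_gwas(g, ph,
                                                covariate_names = character(0)))
  loci <- define_loci(s)
  sc <- suppressMessages(stepwise_conditional(loci[[1]], g, ph,
                                              covariate_names = character(0)))
  expect_length(sc$independent_signals, 1)
})
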