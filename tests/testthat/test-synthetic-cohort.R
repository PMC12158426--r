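test_that("configuration validation names the offending field", {
  expect_error(cohortConfig(n_individuals = 0), "n_individuals")
  expect_error(cohortConfig(age_range = c(70, 40)), "age_range")
  expect_error(cohortConfig(missing_rate = 1), "missing_rate")
  expect_error(cohortConfig(sigma_delta = -1), "sigma_delta")
  expect_error(variantSpec("v", maf = 0.6, mode = "global_driver",
                           beta = 1), "maf")
  expect_error(variantSpec("v", maf = 0.1, mode = "cluster_marker",
                           beta = 1), "target")
  expect_error(mortalityParams(doubling_time = 0), "doubling_time")
})

test_that("the same configuration generates byte-identical cohorts", {
  cfg <- cohortConfig(n_individuals = 500, seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(traitMatrix(a), traitMatrix(b))
  expect_identical(genotypes(a), genotypes(b))
  expect_identical(trueDelta(a), trueDelta(b))
  expect_identical(diedInFollowup(a), diedInFollowup(b))
})

test_that("without noise every continuous trait is an affine function of age", {
  cfg <- leanConfig(n = 300, seed = 2, sigma_delta = 0, kappa_cluster = 0,
                    trait_noise_sd = 0)
  co <- generateCohort(cfg)
  X <- traitMatrix(co)
  age <- ages(co)
  f <- sexes(co) == "F"  # per-sex offsets differ; check within one sex
  for (j in seq_len(ncol(X))) {
    fit <- lm(X[f, j] ~ age[f])
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
})

test_that("trait-age correlation matches the closed-form attenuation", {
  ## traits = age + noise(sd 5): corr = sd(age)/sqrt(var(age) + 25)
  cfg <- leanConfig(n = 50000, seed = 3, n_clusters = 2,
                    traits_per_cluster = 2, sigma_delta = 0,
                    kappa_cluster = 0, trait_noise_sd = 5)
  co <- generateCohort(cfg)
  X <- traitMatrix(co)
  age <- ages(co)
  expected <- sd(age) / sqrt(var(age) + 25)
  for (j in seq_len(ncol(X)))
    expect_equal(abs(cor(X[, j], age)), expected, tolerance = 0.02)
})

test_that("genotype simulation matches binomial expectations and is seeded", {
  specs <- list(variantSpec("a", maf = 0.5, mode = "global_driver",
                            beta = 0))
  G <- simulateGenotypes(1e5, specs, seed = 9)
  expect_equal(mean(G[, "a"]), 1.0, tolerance = 0.01)
  expect_identical(G, simulateGenotypes(1e5, specs, seed = 9))
  empty <- simulateGenotypes(50, list())
  expect_equal(dim(empty), c(50L, 0L))
  expect_error(simulateGenotypes(10, list(list(id = "b", maf = 0.7))),
               "maf")
})

test_that("death simulation follows the exact cumulative-hazard integral", {
  par <- mortalityParams(baseline_A = 1e-5, doubling_time = 7.7,
                         followup = 5)
  ## zero baseline hazard: nobody dies
  expect_false(any(simulateMortality(rep(60, 1000), rep(0, 1000),
                                     mortalityParams(baseline_A = 0),
                                     seed = 1)))
  ## Monte Carlo at age 62 against the closed form, within 3 SE
  n <- 1e6
  p <- gompertzDeathProb(62, 0, par)
  d <- simulateMortality(rep(62, n), rep(0, n), par, seed = 2)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(d) - p), 3 * se)
  expect_error(simulateMortality(1, 1, mortalityParams(followup = -1)))
})

test_that("the aging offset has the configured composite SD and mean zero", {
  cfg <- cohortConfig(n_individuals = 50000, seed = 4)
  co <- generateCohort(cfg)
  d <- trueDelta(co)
  sdExp <- expectedDeltaSd(cfg)
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
  expect_equal(sd(d), sdExp, tolerance = 0.05 * sdExp)
})

test_that("parental lifespan is anti-correlated with the aging offset", {
  cfg <- cohortConfig(n_individuals = 10000, seed = 5)
  co <- generateCohort(cfg)
  expect_lt(cor(parentDeathAge(co), trueDelta(co)), 0)
})

test_that("disease flags are enriched among susceptibility-allele carriers", {
  cfg <- cohortConfig(n_individuals = 20000, seed = 6)
  co <- generateCohort(cfg)
  dose <- genotypes(co)[, "rs_dis_diabetes"]
  dia <- diagnoses(co)[, "diabetes"]
  carriers <- dose > 0
  tab <- table(carriers, dia)
  or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_gt(or, 1)
  ## exact binomial: carrier diagnosis rate above the non-carrier rate
  p0 <- mean(dia[!carriers])
  expect_lt(pbinom(sum(dia[carriers]) - 1, sum(carriers), p0,
                   lower.tail = FALSE), 1e-4)
  ## marginal prevalence near its target
  expect_equal(mean(dia), 0.16, tolerance = 0.02)
  ## prevalence rises with age (age-related disease)
  old <- ages(co) > 60; young <- ages(co) < 50
  expect_gt(mean(dia[old]), mean(dia[young]))
})

test_that("heavy-missing individuals carry more than 15 missing cells", {
  cfg <- cohortConfig(n_individuals = 2000, seed = 7)
  co <- generateCohort(cfg)
  md <- traitData(co)
  core <- md$trait[!md$flagSocietal & !md$flagElapsedTime &
                     !md$flagAgeDerived]
  miss <- rowSums(is.na(traitMatrix(co)[, core]))
  expect_gte(sum(miss > 15), cfg$n_heavy_missing)
})

test_that("analysis accessors never expose the true offset", {
  co <- generateCohort(cohortConfig(n_individuals = 200, seed = 8))
  for (acc in list(traitMatrix, traitData, environmentData, genotypes,
                   diagnoses)) {
    v <- acc(co)
    expect_false(any(grepl("delta_true", c(colnames(v), names(v)))))
  }
  an <- analyzeCohort(co, runConfig(cohort = S4Vectors::metadata(co)$config,
                                    min_bin = 10))
  expect_false("delta_true" %in% unlist(lapply(an, names)))
})

test_that("cohort TSV round trip preserves the analysis-facing tables", {
  co <- generateCohort(cohortConfig(n_individuals = 150, seed = 9))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_equal(traitMatrix(back), traitMatrix(co), tolerance = 1e-9)
  expect_equal(ages(back), ages(co), tolerance = 1e-9)
  expect_identical(sexes(back), sexes(co))
  expect_identical(diedInFollowup(back), diedInFollowup(co))
  expect_equal(unname(genotypes(back)), unname(genotypes(co)),
               ignore_attr = TRUE)
})
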