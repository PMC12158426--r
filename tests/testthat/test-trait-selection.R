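test_that("the age scan recovers a planted slope within its CI", {
  set.seed(21)
  n <- 5000
  age <- runif(n, 40, 70)
  X <- cbind(planted = 2 * age + rnorm(n, 0, 5),
             noise = rnorm(n))
  sc <- ageRegressionScan(X, age)
  row <- sc[sc$column == "planted", ]
  ## closed-form OLS oracle on the same rows
  fit <- lm(X[, "planted"] ~ age)
  ci <- confint(fit)["age", ]
  expect_gt(row$slope, ci[1]); expect_lt(row$slope, ci[2])
  expect_equal(row$slope, unname(coef(fit)["age"]), tolerance = 1e-10)
  expect_lt(row$adjusted_p, 1e-3)
  ## pure-noise trait stays above the threshold
  expect_gt(sc$adjusted_p[sc$column == "noise"], 1e-3)
})

test_that("Bonferroni adjustment is monotone in the number of scanned traits", {
  set.seed(22)
  n <- 500
  age <- runif(n, 40, 70)
  X5 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("t", 1:5)))
  X9 <- cbind(X5, matrix(rnorm(n * 4), n, 4,
                         dimnames = list(NULL, paste0("u", 1:4))))
  a5 <- ageRegressionScan(X5, age)
  a9 <- ageRegressionScan(X9, age)
  m <- match(a5$column, a9$column)
  expect_true(all(a9$adjusted_p[m] >= a5$adjusted_p - 1e-15))
  expect_true(all(a5$adjusted_p >= a5$raw_p))
})

test_that("traits with too few complete pairs are flagged, not fatal", {
  age <- c(50, 55, 60, 65)
  X <- cbind(ok = age * 1.5, sparse = c(1, NA, NA, NA))
  sc <- ageRegressionScan(X, age)
  expect_true(sc$untestable[sc$column == "sparse"])
  expect_false(sc$untestable[sc$column == "ok"])
})

test_that("eligibility criteria reject flagged and boundary traits", {
  md <- data.frame(trait = c("bp", "bmr", "partners", "tea", "flat"),
                   type = "continuous", cluster = NA, options = NA,
                   flagSocietal = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                   flagElapsedTime = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                   flagAgeDerived = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  scan <- data.frame(trait = md$trait, column = md$trait,
                     slope = c(1, 1, 1, 1, 1),
                     raw_p = 1e-10,
                     adjusted_p = c(1e-8, 1e-300, 1e-20, 1e-9, 1e-3),
                     n_used = 100, untestable = FALSE)
  sel <- selectAgeSensitive(scan, alpha = 1e-3, metadata = md)
  expect_equal(sel$kept, "bp")
  expect_equal(sel$rejected$reason[sel$rejected$trait == "bmr"],
               "age_derived")
  expect_equal(sel$rejected$reason[sel$rejected$trait == "partners"],
               "societal")
  expect_equal(sel$rejected$reason[sel$rejected$trait == "tea"],
               "elapsed_time")
  ## adjusted_p equal to alpha is rejected (strict inequality)
  expect_equal(sel$rejected$reason[sel$rejected$trait == "flat"],
               "not_significant")
  ## empty scan -> empty selection
  empty <- selectAgeSensitive(scan[0, ], alpha = 1e-3, metadata = md)
  expect_equal(length(empty$kept), 0L)
  ## malformed flags error
  md$flagSocietal <- NA
  expect_error(selectAgeSensitive(scan, 1e-3, md), "flagSocietal")
})

test_that("completeness tradeoff equals brute-force row enumeration", {
  x <- rbind(c(1, 1, 1), c(NA, 1, 1), c(1, NA, 1), c(1, 1, NA),
             c(NA, NA, 1))
  colnames(x) <- c("a", "b", "c")
  curve <- completenessTradeoff(x, c("a", "b", "c"))
  brute <- sapply(1:3, function(k)
    sum(rowSums(is.na(x[, 1:k, drop = FALSE])) == 0))
  expect_equal(curve$completeCount, brute)
  expect_true(all(diff(curve$completeCount) <= 0))
  ## no missing data: flat at n
  full <- completenessTradeoff(matrix(1, 7, 3,
                                      dimnames = list(NULL, c("a","b","c"))),
                               c("a", "b", "c"))
  expect_equal(full$completeCount, rep(7L, 3))
})

test_that("duplicated traits correlate perfectly and merge first", {
  set.seed(23)
  x <- rnorm(200)
  X <- cbind(a = x, b = x, c = rnorm(200), d = rnorm(200))
  tc <- traitCorrelation(X, nClusters = 3)
  expect_equal(tc$pearson["a", "b"], 1)
  expect_equal(tc$linkage$merge[1, ], c(-1, -2))  # a and b merge first
  expect_equal(unname(tc$clusterLabels["a"]), unname(tc$clusterLabels["b"]))
  ## independent noise traits are near-uncorrelated at large n
  set.seed(24)
  Y <- matrix(rnorm(2e4), 1e4, 2, dimnames = list(NULL, c("u", "v")))
  expect_lt(abs(traitCorrelation(Y, 2)$pearson["u", "v"]), 0.03)
})

test_that("zero-variance traits are reported missing with a warning", {
  X <- cbind(a = rnorm(50), flat = rep(1, 50))
  expect_warning(tc <- traitCorrelation(X, 2), "zero-variance")
  expect_true(is.na(tc$clusterLabels["flat"]))
})

test_that("tree cutting recovers planted clusters", {
  skip_if_not_installed("mclust")
  cfg <- leanConfig(n = 20000, seed = 25, n_clusters = 10,
                    traits_per_cluster = 3)
  co <- generateCohort(cfg)
  Z <- standardizeTraits(traitMatrix(co))$z
  tc <- traitCorrelation(Z, nClusters = 10)
  planted <- traitData(co)$cluster
  ari <- mclust::adjustedRandIndex(tc$clusterLabels, planted)
  expect_gt(ari, 0.9)
})
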