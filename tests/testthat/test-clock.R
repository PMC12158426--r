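test_that("one-sigma component selection matches hand computation", {
  curve <- data.frame(ncomp = 0:5,
                      rmsep = c(8.0, 6.0, 5.2, 5.05, 5.01, 5.00),
                      se = c(0.3, 0.1, 0.07, 0.06, 0.055, 0.05))
  expect_equal(selectComponents(curve), 3L)
  ## strictly flat curve: smallest admissible count is one component
  flat <- data.frame(ncomp = 0:4, rmsep = rep(5, 5), se = rep(0.1, 5))
  expect_equal(selectComponents(flat), 1L)
  expect_error(selectComponents(transform(curve, se = NA)), "missing SEs")
})

test_that("full-rank PLS predictions equal ordinary least squares", {
  set.seed(11)
  n <- 200; p <- 6
  X <- scale(matrix(rnorm(n * p), n, p, dimnames = list(NULL,
                                                        paste0("t", 1:p))))
  y <- 50 + as.numeric(X %*% rnorm(p)) + rnorm(n)
  m <- fitPlsClock(X, y, maxComponents = p, cvFolds = 5, seed = 1,
                   calibrate = FALSE)
  fitFull <- physage:::pls1Fit(X, y, p)
  predPls <- physage:::pls1Predict(fitFull, X, p)
  predOls <- unname(fitted(lm(y ~ X)))
  expect_lt(max(abs(predPls - predOls)), 1e-8)
})

test_that("a single informative trait yields a one-component model with the OLS slope", {
  set.seed(12)
  n <- 20000
  X <- cbind(x1 = rnorm(n), matrix(rnorm(n * 5), n, 5,
                                   dimnames = list(NULL, paste0("n", 1:5))))
  y <- 3 * X[, "x1"] + rnorm(n)
  m <- fitPlsClock(scale(X), y, maxComponents = 6, cvFolds = 10, seed = 2,
                   calibrate = FALSE)
  expect_equal(m@componentCount, 1L)
  expect_equal(unname(m@coefficients["x1"]), 3 * sd(X[, "x1"]),
               tolerance = 0.02)
  ## y driven only by x1: its weight is strictly largest
  w <- phenotypeWeights(m)
  expect_equal(w$trait[1], "x1")
  expect_gt(w$weight[1], 2 * max(w$weight[-1]))
})

test_that("PLS core agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  n <- 300; p <- 8
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("t", 1:p))))
  y <- as.numeric(X %*% rnorm(p)) + rnorm(n)
  fit <- physage:::pls1Fit(X, y, 3)
  ref <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pr <- predict(ref, X)$predict[, 1, 3]
  expect_lt(max(abs(physage:::pls1Predict(fit, X, 3) - pr)), 1e-6)
})

test_that("duplicated predictors receive equal weights", {
  set.seed(14)
  n <- 500
  x <- rnorm(n)
  X <- cbind(a = x, b = x, c = rnorm(n))
  y <- 2 * x + rnorm(n)
  m <- fitPlsClock(scale(X), y, maxComponents = 2, cvFolds = 5, seed = 3,
                   calibrate = FALSE)
  w <- phenotypeWeights(m)
  expect_equal(w$weight[w$trait == "a"], w$weight[w$trait == "b"],
               tolerance = 1e-10)
})

test_that("single-component weights rank identically to absolute coefficients", {
  set.seed(15)
  n <- 2000; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p,
                    dimnames = list(NULL, paste0("t", 1:p))))
  y <- as.numeric(X %*% c(3, -2, 1, 0.5, 0)) + rnorm(n, 0, 4)
  m <- fitPlsClock(X, y, maxComponents = 1, cvFolds = 5, seed = 4,
                   calibrate = FALSE)
  expect_equal(m@componentCount, 1L)
  w <- phenotypeWeights(m)
  expect_equal(w$trait, names(sort(-abs(m@coefficients))))
})

test_that("prediction is linear, complete-data only, and permutation-equivariant", {
  set.seed(16)
  n <- 400
  X <- scale(matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("t", 1:4))))
  y <- 30 + as.numeric(X %*% c(2, 1, -1, 0.5)) + rnorm(n)
  m <- fitPlsClock(X, y, maxComponents = 4, cvFolds = 5, seed = 5)
  pred <- predictAge(m, X)
  expect_lte(sqrt(mean((y - pred)^2)), sd(y))
  perm <- sample(n)
  expect_equal(predictAge(m, X[perm, ]), pred[perm])
  expect_error(predictAge(m, X[, 1:3]), "t4")
})

test_that("a noise-free cohort is predicted almost perfectly", {
  cfg <- leanConfig(n = 1500, seed = 17, sigma_delta = 0,
                    kappa_cluster = 0, trait_noise_sd = 0)
  co <- generateCohort(cfg)
  rows <- which(sexes(co) == "F")
  X <- standardizeTraits(traitMatrix(co)[rows, ])$z
  m <- fitPlsClock(X, ages(co)[rows], maxComponents = 5, cvFolds = 5,
                   seed = 6)
  expect_lt(sqrt(mean((predictAge(m, X) - ages(co)[rows])^2)), 0.1)
})

test_that("maxComponents beyond the rank is truncated with a warning", {
  set.seed(18)
  X <- scale(matrix(rnorm(40), 10, 4,
                    dimnames = list(NULL, paste0("t", 1:4))))
  y <- rnorm(10)
  expect_warning(fitPlsClock(X, y, maxComponents = 50, cvFolds = 2,
                             seed = 1, calibrate = FALSE), "truncated")
})

test_that("delta-age is exactly bin-centered", {
  set.seed(19)
  age <- runif(3000, 40, 70)
  ## predicted = age -> all zero
  expect_equal(deltaAge(computeDeltaAge(age, age)), rep(0, 3000))
  ## constant bias absorbed by centering
  expect_equal(deltaAge(computeDeltaAge(age + 3, age)), rep(0, 3000))
  ## noise case: equals per-bin demeaned noise (arithmetic oracle)
  eps <- rnorm(3000, 0, 4)
  da <- computeDeltaAge(age + eps, age, binWidth = 1, minBin = 50)
  for (b in unique(da@ageBin)) {
    sel <- da@ageBin == b
    expect_equal(deltaAge(da)[sel], eps[sel] - mean(eps[sel]),
                 tolerance = 1e-12)
  }
  ## per-bin means are zero to 1e-10 and corr with age vanishes
  mu <- tapply(deltaAge(da), da@ageBin, mean)
  expect_lt(max(abs(mu)), 1e-10)
  expect_lt(abs(cor(deltaAge(da), age)), 0.06)
  expect_error(computeDeltaAge(numeric(0), numeric(0)), "empty")
})

test_that("small age bins are merged to respect the minimum size", {
  age <- c(rep(50, 100), rep(51, 100), rep(52, 3))
  da <- computeDeltaAge(age + rnorm(203), age, minBin = 50)
  counts <- table(da@ageBin)
  expect_true(all(counts >= 50))
})
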