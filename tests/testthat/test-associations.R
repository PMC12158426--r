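test_that("the association engine reproduces lm exactly, with and without covariates", {
  set.seed(41)
  n <- 300
  y <- rnorm(n)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- cbind(z1 = rnorm(n), z2 = rnorm(n))
  res <- linearAssociation(y, X, Z)
  for (j in colnames(X)) {
    ref <- summary(lm(y ~ X[, j] + Z))$coefficients[2, ]
    row <- res[res$id == j, ]
    expect_equal(row$beta, unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(row$se, unname(ref["Std. Error"]), tolerance = 1e-10)
    expect_equal(row$p, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
  }
  ## missing cells handled per predictor
  X[1:5, "a"] <- NA
  res2 <- linearAssociation(y, X, Z)
  expect_equal(res2$n[res2$id == "a"], n - 5)
})

test_that("SNP effects are equivariant under dosage recoding", {
  set.seed(42)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  delta <- 0.4 * g + rnorm(n, 0, 3)
  a <- snpScan(delta, cbind(snp = g))
  b <- snpScan(delta, cbind(snp = 2L - g))
  expect_equal(a$beta, -b$beta, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$maf, b$maf)
  ## monomorphic SNP flagged untestable
  m <- snpScan(delta, cbind(mono = rep(1L, n)))
  expect_true(m$untestable)
  expect_error(snpScan(delta, cbind(bad = rep(3L, n))), "dosages")
})

test_that("a null SNP panel produces no genome-wide hits", {
  set.seed(43)
  n <- 5000
  delta <- rnorm(n, 0, 5)
  G <- sapply(1:1000, function(i) rbinom(n, 2, runif(1, 0.05, 0.5)))
  colnames(G) <- paste0("s", 1:1000)
  res <- snpScan(delta, G, threshold = 1e-9)
  expect_equal(sum(res$significant), 0L)
})

test_that("environment scan recovers a planted effect and respects the threshold", {
  set.seed(44)
  n <- 20000
  edu <- sample(0:4, n, replace = TRUE)
  delta <- -1.5 * (edu - 2) + rnorm(n, 0, 4)
  fac <- data.frame(education = edu, noise = rnorm(n))
  res <- scanEnvironment(delta, fac, standardize = FALSE)
  row <- res[res$id == "education", ]
  expect_lt(abs(row$beta - (-1.5)), 1.96 * row$se)
  expect_true(row$significant)
  expect_false(res$significant[res$id == "noise"])
  ## standardized scan reports years per SD
  resStd <- scanEnvironment(delta, fac, standardize = TRUE)
  expect_equal(resStd$beta[resStd$id == "education"],
               row$beta * sd(edu), tolerance = 1e-10)
  ## constant factor flagged untestable
  resC <- scanEnvironment(delta, data.frame(k = rep(1, n)))
  expect_true(resC$untestable)
  ## multichoice factors expand to per-level indicators
  gam <- factor(sample(c("never", "sometimes", "often"), n, TRUE),
                levels = c("never", "sometimes", "often"))
  resG <- scanEnvironment(delta, data.frame(gaming = gam))
  expect_setequal(resG$id, c("gaming.sometimes", "gaming.often"))
})

test_that("parental-lifespan association detects the planted sign and dies under permutation", {
  set.seed(45)
  n <- 20000
  delta <- rnorm(n, 0, 5)
  parent <- 78 - 0.4 * delta + rnorm(n, 0, 8)
  res <- parentalLifespanAssociation(delta, parent)
  expect_lt(res$beta, 0)
  expect_lt(res$p, 1e-5)
  perm <- parentalLifespanAssociation(delta, sample(parent))
  expect_gt(perm$p, 1e-4)
  ## null generator: CI covers zero
  parent0 <- 78 + rnorm(n, 0, 8)
  res0 <- parentalLifespanAssociation(delta, parent0)
  expect_lt(abs(res0$beta), 1.96 * res0$se)
  expect_error(parentalLifespanAssociation(delta[1:5], parent[1:5]),
               "fewer than 10")
})

test_that("healthy subset mask equals hand evaluation", {
  D <- cbind(diabetes = c(TRUE, FALSE, FALSE, TRUE, FALSE),
             cvd = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  m <- healthySubset(D)
  expect_equal(as.logical(m), c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(m, "excludedFraction"), 0.6)
  m2 <- healthySubset(D, criteria = "diabetes")
  expect_equal(as.logical(m2), c(FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_error(healthySubset(D, criteria = "gout"), "gout")
  ## no diagnoses set: all retained
  expect_true(all(healthySubset(D * FALSE)))
})

test_that("group profiles are centered, separable, and exchangeable", {
  set.seed(46)
  n <- 30000
  age <- runif(n, 40, 70)
  delta <- rnorm(n, 0, 3)
  ## single group: profile ~ 0 at every bin (delta is centered)
  da <- computeDeltaAge(age + delta, age)
  g1 <- groupProfile(deltaAge(da), age, rep("all", n))
  expect_true(all(abs(g1$mean) < 4 * g1$se + 1e-9))
  ## constant group effect separates at all ages
  grp <- sample(c("carrier", "noncarrier"), n, TRUE)
  shifted <- deltaAge(da) + ifelse(grp == "carrier", 1.5, 0)
  g2 <- groupProfile(shifted, age, grp)
  wide <- merge(g2[g2$group == "carrier", c("ageBin", "mean")],
                g2[g2$group == "noncarrier", c("ageBin", "mean")],
                by = "ageBin")
  expect_true(all(wide$mean.x - wide$mean.y > 0.5))
  ## random equal-size groups agree within 3 SE almost everywhere
  g3 <- groupProfile(deltaAge(da), age, sample(c("a", "b"), n, TRUE))
  wide3 <- merge(g3[g3$group == "a", ], g3[g3$group == "b", ],
                 by = "ageBin")
  z <- abs(wide3$mean.x - wide3$mean.y) /
    sqrt(wide3$se.x^2 + wide3$se.y^2)
  expect_lt(mean(z > 3), 0.2)
})
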