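## small helper: a deterministic grid for rule checks
ruleGrid <- function(sigTable, membership = c(hitA = NA, hitB = NA)) {
  rows <- do.call(rbind, lapply(names(sigTable), function(h) {
    data.frame(hit = h, model = names(sigTable[[h]]),
               beta = 0.3, se = 0.05, p = ifelse(sigTable[[h]], 1e-12, 0.5),
               n = 1000L, significant = unname(sigTable[[h]]),
               untestable = FALSE, stringsAsFactors = FALSE)
  }))
  new("DropoutGrid", results = rows,
      clusterMembership = membership,
      dropoutClusters = c("kidney", "cardio"),
      thresholds = c(snp = 1e-9, env = 1e-5, dropout = 7e-7))
}

test_that("classification rules reproduce the driver, marker and disease patterns", {
  cols <- c("full", "dropout:kidney", "dropout:cardio", "healthy")
  sig <- list(
    hitA = setNames(c(TRUE, TRUE, TRUE, TRUE), cols),          # driver
    hitB = setNames(c(TRUE, FALSE, TRUE, TRUE), cols),         # marker
    hitC = setNames(c(TRUE, TRUE, TRUE, FALSE), cols),         # disease
    hitD = setNames(c(FALSE, FALSE, FALSE, FALSE), cols),      # nothing
    hitE = setNames(c(TRUE, FALSE, FALSE, TRUE), cols))        # ambiguous
  grid <- ruleGrid(sig, membership = c(hitA = NA, hitB = "kidney",
                                       hitC = NA, hitD = NA, hitE = NA))
  lab <- classifyHits(grid)
  expect_equal(lab$label[lab$hit == "hitA"], "global_driver_candidate")
  expect_equal(lab$label[lab$hit == "hitB"], "cluster_marker(kidney)")
  expect_equal(lab$label[lab$hit == "hitC"], "disease_linked")
  expect_equal(lab$label[lab$hit == "hitD"], "inconclusive")
  expect_equal(lab$label[lab$hit == "hitE"], "inconclusive")
  ## a marker whose membership contradicts the lost dropout is inconclusive
  grid2 <- ruleGrid(sig["hitB"], membership = c(hitB = "cardio"))
  expect_equal(classifyHits(grid2)$label, "inconclusive")
})

test_that("classification is invariant to hit and column order", {
  cols <- c("full", "dropout:kidney", "dropout:cardio", "healthy")
  sig <- list(hitA = setNames(c(TRUE, TRUE, TRUE, TRUE), cols),
              hitB = setNames(c(TRUE, FALSE, TRUE, TRUE), cols))
  g1 <- ruleGrid(sig, membership = c(hitA = NA, hitB = "kidney"))
  g2 <- g1
  g2@results <- g2@results[rev(seq_len(nrow(g2@results))), ]
  l1 <- classifyHits(g1); l2 <- classifyHits(g2)
  expect_equal(l1[order(l1$hit), c("hit", "label")],
               l2[order(l2$hit), c("hit", "label")],
               ignore_attr = TRUE)
})

test_that("cross-model correlation has unit diagonal and detects independence", {
  set.seed(51)
  v <- rnorm(10000)
  M <- cbind(a = v, b = v, c = rnorm(10000))
  R2 <- crossModelCorrelation(M)
  expect_equal(diag(R2), c(a = 1, b = 1, c = 1))
  expect_equal(R2["a", "b"], 1)
  expect_lt(R2["a", "c"], 0.001)
  expect_error(crossModelCorrelation(cbind(v, c(NA, v[-1]))), "misaligned")
})

test_that("dropping a pure-noise cluster leaves delta-age essentially unchanged", {
  set.seed(52)
  n <- 4000
  age <- runif(n, 40, 70)
  delta <- rnorm(n, 0, 4)
  signal <- sapply(1:6, function(i) age + delta + rnorm(n, 0, 4))
  noise <- matrix(rnorm(n * 3), n, 3)
  X <- scale(cbind(signal, noise))
  colnames(X) <- c(paste0("s", 1:6), paste0("z", 1:3))
  lab <- c(rep("organ1", 3), rep("organ2", 3), rep("junk", 3))
  bd <- buildDropoutModels(X, age, lab, maxComponents = 5, cvFolds = 5,
                           seed = 1, minBin = 40)
  full <- fitPlsClock(X, age, maxComponents = 5, cvFolds = 5, seed = 1)
  fullDelta <- deltaAge(computeDeltaAge(predictAge(full, X), age,
                                        minBin = 40))
  r2 <- cor(fullDelta, bd$deltaAges[, "junk"])^2
  expect_gt(r2, 0.99)
  ## dropout models never see their excluded cluster's traits
  for (cl in bd$clusters)
    expect_false(any(colnames(X)[lab == cl] %in%
                       bd$models[[cl]]@traits))
  expect_error(buildDropoutModels(X[, 1:3], age, rep("only", 3)),
               "fewer than 2")
})

test_that("the association grid separates planted driver, marker and disease variants", {
  ## compact end-to-end attribution on a generated cohort
  cfg <- cohortConfig(n_individuals = 30000, seed = 53)
  co <- generateCohort(cfg)
  an <- analyzeCohort(co, runConfig(cohort = cfg))
  ok <- !is.na(an$delta)
  dd <- dropoutDeltaAges(an)
  healthy <- healthySubset(diagnoses(co))
  info <- S4Vectors::metadata(co)$snpInfo
  hits <- data.frame(id = info$id, type = "snp",
                     stringsAsFactors = FALSE)
  member <- physage:::hitClusterMembership(co, hits$id, an)
  expect_equal(unname(member["rs_mrk_kidney"]), "kidney")
  ## at n = 30k use thresholds scaled to the smaller cohort so that the
  ## pattern, not raw power, is what is examined
  grid <- dropoutAssociationGrid(hits, genotypes(co)[ok, ],
                                 an$delta[ok], dd$deltaAges[ok, ],
                                 healthy[ok], clusterMembership = member,
                                 snpThreshold = 1e-4,
                                 dropoutThreshold = 1e-4)
  res <- grid@results
  ## marker: significant in full, lost exactly in its own cluster dropout
  mk <- res[res$hit == "rs_mrk_kidney", ]
  expect_true(mk$significant[mk$model == "full"])
  expect_false(mk$significant[mk$model == "dropout:kidney"])
  expect_true(all(mk$significant[grepl("dropout", mk$model) &
                                   mk$model != "dropout:kidney"]))
  ## driver: significant everywhere
  dr <- res[res$hit == "rs_drv3", ]
  expect_true(all(dr$significant))
  ## disease variant: lost in the healthy subcohort
  ds <- res[res$hit == "rs_dis_diabetes", ]
  expect_true(ds$significant[ds$model == "full"])
  expect_false(ds$significant[ds$model == "healthy"])
})
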