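## Small, fast cohort configurations used across tests.

## minimal continuous-trait config: no multichoice, no flagged traits,
## optionally stripped of SNPs / environment / diseases
leanConfig <- function(n = 2000, seed = 1, n_clusters = 4,
                       traits_per_cluster = 2, sigma_delta = 4.3,
                       kappa_cluster = 2, trait_noise_sd = 4,
                       missing_rate = 0, n_heavy_missing = 0,
                       snps = list(), env = list(), diseases = list(),
                       ...) {
  cohortConfig(n_individuals = n, seed = seed, n_clusters = n_clusters,
               traits_per_cluster = traits_per_cluster,
               sigma_delta = sigma_delta, kappa_cluster = kappa_cluster,
               trait_noise_sd = trait_noise_sd, trait_quality = 1,
               missing_rate = missing_rate,
               n_heavy_missing = n_heavy_missing,
               n_multichoice = 0L, n_flagged = 0L, n_dimorphic = 0L,
               snp_specs = snps, env_specs = env,
               disease_specs = diseases, ...)
}

## deterministic toy matrix with planted missing cells
toyMissingMatrix <- function(n = 6, p = 4, missingPerRow = integer(n),
                             seed = 7) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("r", seq_len(n)),
                              paste0("t", seq_len(p))))
  for (i in seq_len(n)) {
    k <- min(missingPerRow[i], p)
    if (k > 0) x[i, sample(p, k)] <- NA
  }
  x
}

## brute-force KNN imputation oracle mirroring the documented semantics
knnImputeOracle <- function(x, k) {
  out <- x
  n <- nrow(x); p <- ncol(x)
  for (i in seq_len(n)) {
    miss <- which(is.na(x[i, ]))
    if (!length(miss)) next
    d <- rep(Inf, n)
    for (r in seq_len(n)) {
      if (r == i) next
      shared <- which(!is.na(x[i, ]) & !is.na(x[r, ]))
      if (length(shared))
        d[r] <- sum((x[i, shared] - x[r, shared])^2) / length(shared)
    }
    for (j in miss) {
      cand <- which(!is.na(x[, j]) & is.finite(d))
      if (!length(cand)) { out[i, j] <- mean(x[, j], na.rm = TRUE); next }
      cand <- cand[order(d[cand], cand)]   # ties -> lower row index
      out[i, j] <- mean(x[cand[seq_len(min(k, length(cand)))], j])
    }
  }
  out
}
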