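#' Simulate genotype dosages
#'
#' Each SNP is drawn i.i.d. Binomial(2, maf) per individual (independent
#' variants, no linkage structure); columns follow the order of `specs`.
#'
#' @param n number of individuals.
#' @param specs list of [variantSpec()].
#' @param seed optional integer seed; if missing, the current RNG stream is
#'   used (so the cohort generator stays a single deterministic stream).
#' @return n x length(specs) integer dosage matrix with SNP ids as columns.
#' @export
simulateGenotypes <- function(n, specs, seed = NULL) {
  if (n <= 0) stop("simulateGenotypes: n must be > 0")
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(0L, nrow = n, ncol = length(specs))
  if (length(specs)) {
    for (j in seq_along(specs)) {
      s <- specs[[j]]
      if (s$maf <= 0 || s$maf > 0.5)
        stop("simulateGenotypes: maf outside (0, 0.5] for '", s$id, "'")
      G[, j] <- rbinom(n, 2L, s$maf)
    }
    colnames(G) <- vapply(specs, `[[`, character(1), "id")
  }
  G
}

#' Closed-form probability of death within follow-up under Gompertz hazard
#'
#' With hazard h(t) = A exp(b (t + delta)) and b = log(2)/doubling_time,
#' the probability of death in `(age, age + followup]` is
#' 1 - exp(-(A/b) e^{b (age + delta)} (e^{b followup} - 1)) — the exact
#' integral of the hazard, no time discretization.
#'
#' @param age,delta years; vectors of equal length (recycled).
#' @param params a [mortalityParams()].
#' @return vector of probabilities.
#' @export
gompertzDeathProb <- function(age, delta, params) {
  b <- log(2) / params$doubling_time
  H <- (params$baseline_A / b) * exp(b * (age + delta)) *
    (exp(b * params$followup) - 1)
  1 - exp(-H)
}

#' Simulate death-within-follow-up flags
#'
#' @inheritParams gompertzDeathProb
#' @param seed optional seed (missing: current RNG stream).
#' @return logical vector of death flags.
#' @export
simulateMortality <- function(age, delta, params, seed = NULL) {
  if (length(age) != length(delta))
    stop("simulateMortality: age and delta lengths differ")
  if (params$followup <= 0) stop("simulateMortality: follow-up must be > 0")
  if (!is.null(seed)) set.seed(seed)
  runif(length(age)) < gompertzDeathProb(age, delta, params)
}

## analytic SD of a raw continuous trait (used to express marker/disease
## effects in trait-SD units without peeking at realized data)
traitAnalyticSd <- function(config, slope, quality = 1) {
  varAge <- diff(config$age_range)^2 / 12
  varDelta <- expectedDeltaSd(config)^2
  abs(slope) * sqrt(varAge + varDelta + config$kappa_cluster^2 +
                      (config$trait_noise_sd * quality)^2)
}

sampleEnv <- function(spec, n) {
  switch(spec$type,
    ordinal = sample(seq(0, spec$levels - 1), n, replace = TRUE),
    continuous = rnorm(n),
    binary = rbinom(n, 1L, spec$prob),
    multichoice = factor(sample(spec$levels, n, replace = TRUE,
                                prob = spec$prob), levels = spec$levels)
  )
}

envContribution <- function(spec, x) {
  switch(spec$type,
    ordinal = spec$effect * (as.numeric(x) - mean(seq(0, spec$levels - 1))),
    continuous = spec$effect * x,
    binary = spec$effect * (as.numeric(x) - spec$prob),
    multichoice = {
      eff <- spec$effect[as.integer(x)]
      eff - sum(spec$effect * spec$prob)
    }
  )
}

#' Generate a synthetic aging cohort
#'
#' Builds an [AgingCohort-class] carrying every statistical structure the
#' downstream stages assume.  Continuous trait `j` of cluster `c` is
#' `mu_j + s_j (age + delta + kappa theta_c) + marker and disease effects +
#' noise`, where `delta` is the latent per-person aging offset (normal core
#' plus centered genetic-driver and environmental contributions), and
#' `theta_c` is a per-person organ-cluster latent that gives traits of one
#' cluster their excess correlation.  Slopes have magnitude one with a
#' common sign per cluster (traits are expressed in age-equivalent units);
#' trait noise scales with the slope.  Multiple-choice traits are
#' quartile-discretized latents.  Death within follow-up is drawn from the
#' exact Gompertz integral on `(age + delta)`; parental age at death is
#' anti-correlated with `delta`.  Missing cells are MCAR at `missing_rate`;
#' `n_heavy_missing` individuals additionally receive 16-22 missing cells.
#' The result is a deterministic function of `config` (one seeded RNG
#' stream).
#'
#' @param config a [cohortConfig()].
#' @return An [AgingCohort-class].
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "cohortConfig"))
    config <- do.call(cohortConfig, config)
  set.seed(config$seed)
  n <- config$n_individuals
  C <- config$n_clusters
  clusters <- config$cluster_names

  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(runif(n) < config$sex_fraction, "F", "M")

  G <- simulateGenotypes(n, config$snp_specs)

  ## latent aging offset: normal core + centered drivers + centered env
  delta <- rnorm(n, 0, config$sigma_delta)
  for (j in seq_along(config$snp_specs)) {
    s <- config$snp_specs[[j]]
    if (s$mode == "global_driver")
      delta <- delta + s$beta * (G[, j] - 2 * s$maf)
  }
  env <- list()
  for (e in config$env_specs) {
    x <- sampleEnv(e, n)
    env[[e$id]] <- x
    delta <- delta + envContribution(e, x)
  }
  delta <- unname(delta)
  env <- if (length(env)) as.data.frame(env, stringsAsFactors = FALSE)
         else data.frame(row.names = seq_len(n))

  ## diseases: diagnosis probability (optionally genotype-driven on the
  ## log-odds scale, intercept solved so the marginal hits the target
  ## prevalence), disease shifts traits of one cluster later on
  dis <- matrix(FALSE, n, length(config$disease_specs))
  colnames(dis) <- vapply(config$disease_specs, `[[`, character(1), "id")
  disShift <- setNames(numeric(length(config$disease_specs)),
                       colnames(dis))
  disCluster <- setNames(character(length(config$disease_specs)),
                         colnames(dis))
  midAge <- mean(config$age_range)
  for (i in seq_along(config$disease_specs)) {
    d <- config$disease_specs[[i]]
    gamma <- 0
    dose <- rep(0L, n)
    mafD <- 0
    for (j in seq_along(config$snp_specs)) {
      s <- config$snp_specs[[j]]
      if (s$mode == "disease_susceptibility" &&
          identical(s$target, d$id)) {
        gamma <- s$beta
        dose <- G[, j]
        mafD <- s$maf
      }
    }
    ## diagnosis log-odds rise with age; intercept solved so the marginal
    ## prevalence over the age range and genotype distribution hits target
    ba <- if (is.null(d$age_logodds)) 0 else d$age_logodds
    pd <- c((1 - mafD)^2, 2 * mafD * (1 - mafD), mafD^2)
    ageGrid <- seq(config$age_range[1], config$age_range[2],
                   length.out = 61)
    a0 <- uniroot(function(a)
      mean(outer(ba * (ageGrid - midAge), gamma * 0:2, "+") |>
             (\(m) plogis(a + m) %*% pd)()) - d$prevalence,
      c(-30, 30))$root
    p <- plogis(a0 + gamma * dose + ba * (age - midAge))
    dis[, i] <- runif(n) < p
    disShift[i] <- d$shift
    disCluster[i] <- d$cluster
  }

  theta <- matrix(rnorm(n * C), n, C)
  clusterSign <- sample(c(-1, 1), C, replace = TRUE)

  nCore <- C * config$traits_per_cluster
  traitIds <- character(0)
  traitCluster <- character(0)
  traitType <- character(0)
  traitOptions <- character(0)
  flagS <- logical(0); flagE <- logical(0); flagA <- logical(0)
  columns <- list()

  makeLatent <- function(cl, s, quality = 1) {
    base <- age + delta + config$kappa_cluster * theta[, cl]
    ## disease = organ-specific aging: the whole cluster reads as `shift`
    ## years older in the diseased
    for (i in seq_along(config$disease_specs)) {
      if (disCluster[i] == clusters[cl])
        base <- base + dis[, i] * disShift[i]
    }
    s * base + rnorm(n, 0, abs(s) * config$trait_noise_sd * quality)
  }

  for (cl in seq_len(C)) {
    for (t in seq_len(config$traits_per_cluster)) {
      id <- paste0(clusters[cl], "_", t)
      s <- clusterSign[cl]
      q <- config$trait_quality[t]
      ## sex-dimorphic traits: near-flat slope in males (hormone-like)
      dimorphic <- config$n_dimorphic > 0 &&
        (cl == 1 && t == config$traits_per_cluster)
      x <- makeLatent(cl, s, q)
      if (dimorphic) {
        xm <- 0.2 * s * (age + delta) +
          rnorm(n, 0, config$trait_noise_sd * q)
        x <- ifelse(sex == "M", xm, x)
      }
      ## per-trait, per-sex mean offsets (removed by per-sex scaling)
      x <- x + rnorm(1, 0, 2) + ifelse(sex == "F", 0, rnorm(1, 0, 2))
      for (v in config$snp_specs) {
        if (v$mode == "cluster_marker" && identical(v$target, id)) {
          vi <- match(v$id, colnames(G))
          x <- x + v$beta * traitAnalyticSd(config, s, q) * sign(s) *
            G[, vi]
        }
      }
      columns[[id]] <- x
      traitIds <- c(traitIds, id)
      traitCluster <- c(traitCluster, clusters[cl])
      traitType <- c(traitType, "continuous")
      traitOptions <- c(traitOptions, NA_character_)
      flagS <- c(flagS, FALSE); flagE <- c(flagE, FALSE)
      flagA <- c(flagA, FALSE)
    }
  }

  ## multiple-choice traits: quartile-discretized latents ("do you take
  ## naps"-style items), assigned to the last clusters
  mcOptions <- c("never", "rarely", "sometimes", "often")
  for (m in seq_len(config$n_multichoice)) {
    cl <- C - (m - 1) %% C
    id <- paste0(clusters[cl], "_mc", m)
    lat <- makeLatent(cl, clusterSign[cl])
    q <- quantile(lat, c(0.25, 0.5, 0.75))
    columns[[id]] <- as.numeric(cut(lat, c(-Inf, q, Inf), labels = FALSE))
    traitIds <- c(traitIds, id)
    traitCluster <- c(traitCluster, clusters[cl])
    traitType <- c(traitType, "multichoice")
    traitOptions <- c(traitOptions, paste(mcOptions, collapse = ","))
    flagS <- c(flagS, FALSE); flagE <- c(flagE, FALSE); flagA <- c(flagA, FALSE)
  }

  ## age-associated but excluded traits: societal-norm, elapsed-time and
  ## age-derived items (the lifetime-partners / tea-years / BMR analogues)
  if (config$n_flagged >= 1) {
    columns[["societal_partners"]] <- 0.3 * (2010 - age) + rnorm(n, 0, 3)
    traitIds <- c(traitIds, "societal_partners")
    traitCluster <- c(traitCluster, NA_character_)
    traitType <- c(traitType, "continuous")
    traitOptions <- c(traitOptions, NA_character_)
    flagS <- c(flagS, TRUE); flagE <- c(flagE, FALSE); flagA <- c(flagA, FALSE)
  }
  if (config$n_flagged >= 2) {
    columns[["elapsed_tea_years"]] <- 0.5 * age + rnorm(n, 0, 4)
    traitIds <- c(traitIds, "elapsed_tea_years")
    traitCluster <- c(traitCluster, NA_character_)
    traitType <- c(traitType, "continuous")
    traitOptions <- c(traitOptions, NA_character_)
    flagS <- c(flagS, FALSE); flagE <- c(flagE, TRUE); flagA <- c(flagA, FALSE)
  }
  if (config$n_flagged >= 3) {
    columns[["derived_bmr"]] <- -0.9 * age + rnorm(n, 0, 0.5)
    traitIds <- c(traitIds, "derived_bmr")
    traitCluster <- c(traitCluster, NA_character_)
    traitType <- c(traitType, "continuous")
    traitOptions <- c(traitOptions, NA_character_)
    flagS <- c(flagS, FALSE); flagE <- c(flagE, FALSE); flagA <- c(flagA, TRUE)
  }

  X <- do.call(cbind, columns)
  colnames(X) <- traitIds

  ## missingness: MCAR cells, plus heavy-missing individuals (> 15 cells,
  ## placed among the modeled core traits so the filter sees them)
  if (config$missing_rate > 0) {
    mask <- matrix(runif(length(X)) < config$missing_rate, nrow = n)
    X[mask] <- NA
  }
  if (config$n_heavy_missing > 0) {
    heavy <- sample(n, min(config$n_heavy_missing, n))
    coreCols <- seq_len(min(nCore + config$n_multichoice, ncol(X)))
    for (i in heavy) {
      k <- sample(16:22, 1)
      X[i, sample(coreCols, min(k, length(coreCols)))] <- NA
    }
  }

  parent <- config$parental_base - config$parental_gamma * delta +
    rnorm(n, 0, config$parental_sd)
  died <- simulateMortality(age, delta, config$gompertz)

  ids <- sprintf("id%06d", seq_len(n))
  rownames(X) <- ids
  rownames(G) <- ids
  rownames(dis) <- ids
  rownames(env) <- ids

  cd <- DataFrame(age = age, sex = sex, diedInFollowup = died,
                  parentDeathAge = parent, row.names = ids)
  rd <- DataFrame(trait = traitIds, type = traitType,
                  cluster = traitCluster, options = traitOptions,
                  flagSocietal = flagS, flagElapsedTime = flagE,
                  flagAgeDerived = flagA, row.names = traitIds)
  se <- SummarizedExperiment(assays = list(traits = t(X)),
                             colData = cd, rowData = rd)
  out <- new("AgingCohort", se, genotypes = G, environment = env,
             diagnoses = dis, truth = data.frame(delta_true = delta,
                                                 row.names = ids))
  metadata(out)$config <- config
  metadata(out)$snpInfo <- data.frame(
    id = vapply(config$snp_specs, `[[`, character(1), "id"),
    mode = vapply(config$snp_specs, `[[`, character(1), "mode"),
    target = vapply(config$snp_specs, function(s)
      if (is.null(s$target)) NA_character_ else s$target, character(1)),
    stringsAsFactors = FALSE)
  out
}

#' @importFrom stats uniroot
NULL

#' Cohort driven by d independent latent axes
#'
#' A harness for the component-selection experiment: traits are random
#' linear combinations of `d` independent standard-normal latent factors
#' plus noise, and the response ("age") loads on all `d` factors.  The
#' number of PLS components needed to predict the response then equals the
#' planted latent dimension, which [selectComponents()] should recover.
#'
#' @param n individuals.
#' @param d latent dimension.
#' @param p number of traits.
#' @param noise_x,noise_y residual SDs of traits and response.
#' @param seed integer seed.
#' @return list with standardized trait matrix `X`, response `y`, and `d`.
#' @export
latentAxisCohort <- function(n = 4000, d = 5, p = 30, noise_x = 1,
                             noise_y = 2, seed = 1) {
  set.seed(seed)
  F <- matrix(rnorm(n * d), n, d)
  L <- matrix(rnorm(p * d), d, p)
  X <- F %*% L + matrix(rnorm(n * p, 0, noise_x), n, p)
  beta <- seq(2, 4, length.out = d)
  y <- as.numeric(F %*% beta) + rnorm(n, 0, noise_y)
  colnames(X) <- paste0("t", seq_len(p))
  list(X = scale(X), y = y, d = d)
}
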