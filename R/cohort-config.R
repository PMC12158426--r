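#' Specify a synthetic variant
#'
#' Declares one SNP of the synthetic genotype panel and how it acts on the
#' cohort. Three modes mirror the three biological situations the
#' downstream attribution stage must tell apart:
#' \describe{
#'   \item{`global_driver`}{adds `beta * (dosage - 2*maf)` years to the
#'     latent aging offset, i.e. accelerates aging of every organ system.}
#'   \item{`cluster_marker`}{adds `beta` trait-SDs per allele to a single
#'     named trait (a strong cis effect on one biomarker, the cystatin-C
#'     situation), leaving the aging offset untouched.}
#'   \item{`disease_susceptibility`}{adds `beta` to the log-odds of one
#'     named disease per allele; the disease, not the allele, then shifts
#'     the traits of one cluster.}
#' }
#'
#' @param id variant label.
#' @param maf minor allele frequency, in (0, 0.5].
#' @param mode one of `"global_driver"`, `"cluster_marker"`,
#'   `"disease_susceptibility"`.
#' @param beta effect size: years per allele (driver), trait SD per allele
#'   (marker), or log-odds per allele (disease susceptibility).
#' @param target target trait id (marker) or disease id (susceptibility);
#'   must be `NULL` for a global driver.
#' @return A `variantSpec` list.
#' @export
variantSpec <- function(id, maf, mode = c("global_driver", "cluster_marker",
                                          "disease_susceptibility"),
                        beta, target = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5)
    stop("variantSpec '", id, "': maf must be in (0, 0.5]")
  if (mode != "global_driver" && is.null(target))
    stop("variantSpec '", id, "': target required for mode '", mode, "'")
  structure(list(id = as.character(id), maf = maf, mode = mode,
                 beta = beta, target = target),
            class = "variantSpec")
}

#' Gompertz mortality parameters for the generator
#'
#' @param baseline_A hazard per year extrapolated to age 0 (>= 0).
#' @param doubling_time years over which the hazard doubles; the default
#'   7.7 years is the mortality-rate doubling time estimated from the
#'   cohort the clock framework was developed on.
#' @param followup follow-up window in years over which deaths are counted.
#' @return A `mortalityParams` list.
#' @export
mortalityParams <- function(baseline_A = 4e-5, doubling_time = 7.7,
                            followup = 5) {
  if (baseline_A < 0) stop("mortalityParams: baseline_A must be >= 0")
  if (doubling_time <= 0) stop("mortalityParams: doubling_time must be > 0")
  if (followup <= 0) stop("mortalityParams: followup must be > 0")
  structure(list(baseline_A = baseline_A, doubling_time = doubling_time,
                 followup = followup),
            class = "mortalityParams")
}

#' Specify an environmental factor acting on the aging offset
#'
#' @param id factor name.
#' @param type `"ordinal"` (integer levels `0:(nLevels-1)`), `"continuous"`
#'   (standard normal), `"binary"`, or `"multichoice"` (unordered labels).
#' @param effect years of aging offset per unit (ordinal/continuous/binary)
#'   or a vector of per-option effects (multichoice).  Effects are applied
#'   centered so the offset stays mean zero.
#' @param levels option labels (multichoice) or level count (ordinal).
#' @param prob sampling probabilities (multichoice/binary).
#' @return An `envSpec` list.
#' @export
envSpec <- function(id, type = c("ordinal", "continuous", "binary",
                                 "multichoice"),
                    effect, levels = NULL, prob = NULL) {
  type <- match.arg(type)
  if (type == "multichoice") {
    if (is.null(levels) || length(effect) != length(levels))
      stop("envSpec '", id, "': multichoice needs one effect per level")
    if (is.null(prob)) prob <- rep(1 / length(levels), length(levels))
  }
  if (type == "ordinal" && is.null(levels)) levels <- 5L
  structure(list(id = as.character(id), type = type, effect = effect,
                 levels = levels, prob = prob),
            class = "envSpec")
}

#' Specify a disease of the synthetic cohort
#'
#' A disease hits with probability `prevalence` (its log-odds optionally
#' raised by a susceptibility variant), and when present ages the affected
#' organ system: every trait of `cluster` behaves as if that organ were
#' `shift` years older, while the global latent aging offset is untouched.
#' This dissociation — a disease that makes carriers look physiologically
#' older while their overall aging is unaffected — is what the
#' healthy-subcohort re-test detects.
#'
#' @param id disease name.
#' @param prevalence target marginal probability of diagnosis over the
#'   cohort's age range.
#' @param cluster trait cluster whose traits the disease shifts.
#' @param shift years of organ-specific aging conferred by the disease.
#' @param age_logodds increase in diagnosis log-odds per year of age
#'   (default 0.07, roughly doubling prevalence every decade, as for the
#'   common age-related diseases this emulates).
#' @return A `diseaseSpec` list.
#' @export
diseaseSpec <- function(id, prevalence, cluster, shift = 10,
                        age_logodds = 0.07) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("diseaseSpec '", id, "': prevalence must be in (0, 1)")
  structure(list(id = as.character(id), prevalence = prevalence,
                 cluster = as.character(cluster), shift = shift,
                 age_logodds = age_logodds),
            class = "diseaseSpec")
}

defaultClusterNames <- function(k) {
  base <- c("muscle", "body", "kidney", "cardio", "blood", "metabolic",
            "neuro", "lipid", "lung", "general")
  if (k <= length(base)) base[seq_len(k)]
  else c(base, paste0("cluster", seq_len(k - length(base))))
}

defaultSnpSpecs <- function() {
  list(
    variantSpec("rs_drv1", maf = 0.30, mode = "global_driver", beta = 0.5),
    variantSpec("rs_drv2", maf = 0.20, mode = "global_driver", beta = 0.4),
    variantSpec("rs_drv3", maf = 0.40, mode = "global_driver", beta = 0.6),
    variantSpec("rs_mrk_kidney", maf = 0.15, mode = "cluster_marker",
                beta = 0.56, target = "kidney_1"),
    variantSpec("rs_mrk_muscle", maf = 0.15, mode = "cluster_marker",
                beta = 0.56, target = "muscle_1"),
    variantSpec("rs_mrk_lipid", maf = 0.15, mode = "cluster_marker",
                beta = 0.56, target = "lipid_1"),
    variantSpec("rs_dis_diabetes", maf = 0.30,
                mode = "disease_susceptibility", beta = 2.0,
                target = "diabetes")
  )
}

defaultEnvSpecs <- function() {
  list(
    envSpec("education", type = "ordinal", effect = -1.51, levels = 5L),
    envSpec("income", type = "continuous", effect = -0.81),
    envSpec("gaming", type = "multichoice",
            effect = c(never = 0, sometimes = -1.1, often = -2.2),
            levels = c("never", "sometimes", "often"),
            prob = c(0.45, 0.35, 0.20)),
    envSpec("smoking", type = "binary", effect = 1.0, prob = 0.3)
  )
}

defaultDiseaseSpecs <- function() {
  list(
    diseaseSpec("diabetes", prevalence = 0.16, cluster = "metabolic",
                shift = 12),
    diseaseSpec("cvd", prevalence = 0.12, cluster = "cardio", shift = 10),
    diseaseSpec("asthma", prevalence = 0.10, cluster = "lung", shift = 10)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline is validated under:
#' ages uniform on 40-70, ten organ-system trait clusters of three
#' continuous traits each (plus two multiple-choice traits and three
#' excluded-by-flag traits), a latent per-person aging offset with genetic
#' and environmental determinants whose composite SD is ~5 years, trait
#' noise of 4 age-equivalent years, Gompertz mortality on (age + offset)
#' doubling every 7.7 years over a 5-year follow-up, parental lifespans
#' anti-correlated with the offset, 0.5% missing cells plus 2.7% of
#' individuals with more than 15 missing values.
#'
#' @param n_individuals cohort size.
#' @param age_range years, `c(min, max)`; ages drawn uniformly.
#' @param n_clusters number of organ-system trait clusters.
#' @param traits_per_cluster continuous traits per cluster.
#' @param sex_fraction proportion of females.
#' @param sigma_delta SD (years) of the normal core of the latent aging
#'   offset; genetic and environmental contributions add to it (see
#'   [expectedDeltaSd()]).
#' @param kappa_cluster SD (years) of the per-person, per-cluster latent
#'   shared by traits of one cluster (organ-specific variation).
#' @param trait_noise_sd per-trait measurement noise, in age-equivalent
#'   years (noise scales with the trait's slope).
#' @param trait_quality per-position noise multipliers within each
#'   cluster.  The default `c(0.75, 4, 5)` makes the first trait of every
#'   cluster a low-noise "hero" trait accompanied by two much noisier
#'   satellites, reproducing the observed concentration of clock weight on
#'   a handful of strong traits (blood pressure, cystatin-C, forced
#'   expiratory volume and the like) among many weakly age-correlated
#'   ones.
#' @param missing_rate MCAR cell missingness.
#' @param n_heavy_missing individuals given > 15 missing cells (default
#'   2.7% of the cohort).
#' @param n_multichoice number of multiple-choice traits.
#' @param n_flagged number of age-associated but excluded traits (one each
#'   flagged societal, elapsed-time and age-derived).
#' @param n_dimorphic if positive, one trait gets a near-flat slope in
#'   males (a sex-hormone-like dynamic); set 0 to disable.
#' @param snp_specs list of [variantSpec()].
#' @param env_specs list of [envSpec()].
#' @param disease_specs list of [diseaseSpec()].
#' @param gompertz [mortalityParams()].
#' @param parental_gamma years of parental lifespan lost per year of aging
#'   offset.
#' @param parental_base,parental_sd mean and residual SD of parental age at
#'   death.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A validated `cohortConfig` list.
#' @export
cohortConfig <- function(n_individuals = 20000L,
                         age_range = c(40, 70),
                         n_clusters = 10L,
                         traits_per_cluster = 3L,
                         sex_fraction = 0.5,
                         sigma_delta = 4.3,
                         kappa_cluster = 2,
                         trait_noise_sd = 4,
                         trait_quality = c(0.75, 4, 5),
                         missing_rate = 0.005,
                         n_heavy_missing = NULL,
                         n_multichoice = 2L,
                         n_flagged = 3L,
                         n_dimorphic = 1L,
                         snp_specs = defaultSnpSpecs(),
                         env_specs = defaultEnvSpecs(),
                         disease_specs = defaultDiseaseSpecs(),
                         gompertz = mortalityParams(),
                         parental_gamma = 0.4,
                         parental_base = 78,
                         parental_sd = 8,
                         seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals <= 0)
    stop("cohortConfig: n_individuals must be > 0")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("cohortConfig: age_range min must be < max")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("cohortConfig: missing_rate must be in [0, 1)")
  if (sigma_delta < 0) stop("cohortConfig: sigma_delta must be >= 0")
  if (sex_fraction < 0 || sex_fraction > 1)
    stop("cohortConfig: sex_fraction must be in [0, 1]")
  if (n_clusters < 1) stop("cohortConfig: n_clusters must be >= 1")
  if (traits_per_cluster < 1)
    stop("cohortConfig: traits_per_cluster must be >= 1")
  if (!inherits(gompertz, "mortalityParams"))
    stop("cohortConfig: gompertz must be a mortalityParams object")
  for (s in snp_specs) if (!inherits(s, "variantSpec"))
    stop("cohortConfig: snp_specs must be variantSpec objects")
  if (is.null(n_heavy_missing))
    n_heavy_missing <- as.integer(round(0.027 * n_individuals))
  structure(list(
    n_individuals = as.integer(n_individuals), age_range = age_range,
    n_clusters = as.integer(n_clusters),
    traits_per_cluster = as.integer(traits_per_cluster),
    sex_fraction = sex_fraction, sigma_delta = sigma_delta,
    kappa_cluster = kappa_cluster, trait_noise_sd = trait_noise_sd,
    trait_quality = rep_len(trait_quality, traits_per_cluster),
    missing_rate = missing_rate,
    n_heavy_missing = as.integer(n_heavy_missing),
    n_multichoice = as.integer(n_multichoice),
    n_flagged = as.integer(n_flagged),
    n_dimorphic = as.integer(n_dimorphic),
    snp_specs = snp_specs, env_specs = env_specs,
    disease_specs = disease_specs, gompertz = gompertz,
    parental_gamma = parental_gamma, parental_base = parental_base,
    parental_sd = parental_sd, seed = as.integer(seed),
    cluster_names = defaultClusterNames(n_clusters)
  ), class = "cohortConfig")
}

envEffectVariance <- function(spec) {
  switch(spec$type,
    ordinal = {
      lev <- seq(0, spec$levels - 1)
      spec$effect^2 * var(lev) * (length(lev) - 1) / length(lev)
    },
    continuous = spec$effect^2,
    binary = spec$effect^2 * spec$prob * (1 - spec$prob),
    multichoice = {
      m <- sum(spec$effect * spec$prob)
      sum(spec$prob * (spec$effect - m)^2)
    }
  )
}

#' Composite SD of the latent aging offset implied by a configuration
#'
#' The offset is the sum of its normal core (`sigma_delta`), centered
#' global-driver genetic contributions and centered environmental
#' contributions; this returns the SD of that sum.
#'
#' @param config a [cohortConfig()].
#' @return SD in years.
#' @export
expectedDeltaSd <- function(config) {
  v <- config$sigma_delta^2
  for (s in config$snp_specs) {
    if (s$mode == "global_driver")
      v <- v + s$beta^2 * 2 * s$maf * (1 - s$maf)
  }
  for (e in config$env_specs) v <- v + envEffectVariance(e)
  sqrt(v)
}
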