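#' Binned mortality table
#'
#' Bins a stratification variable (age or delta-age), merges bins with
#' fewer than `minBin` members into their nearest neighbour, and tabulates
#' the fraction who died within the follow-up window per bin.
#'
#' @param values binning variable (years).
#' @param died logical death-within-follow-up flags.
#' @param binWidth bin width (default 1 year).
#' @param minBin minimum individuals per bin (default 50).
#' @return data.frame with `center`, `atRisk`, `deaths`, `rate`.
#' @export
binnedMortality <- function(values, died, binWidth = 1, minBin = 50) {
  stopifnot(length(values) == length(died))
  bins <- floor(values / binWidth) * binWidth + binWidth / 2
  merged <- mergeSmallBins(bins, minBin)
  f <- factor(merged$bins)
  atRisk <- as.integer(table(f))
  deaths <- as.integer(tapply(as.logical(died), f, sum))
  out <- data.frame(center = as.numeric(levels(f)), atRisk = atRisk,
                    deaths = deaths, rate = deaths / atRisk)
  if (!nrow(out)) stop("binnedMortality: no usable bins; widen the bins")
  out
}

#' Fit a Gompertz (exponential) curve to binned mortality
#'
#' Weighted least squares of `log(rate)` on bin center with death-count
#' weights; zero-death bins are excluded with a warning.  Returns hazard
#' scale A, log-slope b, the mortality-rate doubling time `log(2)/b` and a
#' confidence interval for b from the weighted regression.  A
#' non-positive slope yields an infinite doubling time with a warning.
#'
#' @param table a mortality table from [binnedMortality()].
#' @param level confidence level for the interval on b (default 0.95).
#' @return A [GompertzFit-class].
#' @export
fitGompertz <- function(table, level = 0.95) {
  use <- table$deaths > 0 & table$atRisk > 0
  if (any(!use & table$atRisk > 0))
    warning("fitGompertz: excluding ", sum(!use & table$atRisk > 0),
            " zero-death bin(s) from the log fit")
  tab <- table[use, , drop = FALSE]
  if (nrow(tab) < 3)
    stop("fitGompertz: fewer than 3 usable bins")
  fit <- lm(log(rate) ~ center, data = tab, weights = tab$deaths)
  b <- unname(coef(fit)[2])
  A <- exp(unname(coef(fit)[1]))
  ci <- suppressMessages(confint(fit, "center", level = level))
  doubling <- if (b > 1e-8) log(2) / b else Inf
  if (b <= 1e-8)
    warning("fitGompertz: non-positive slope; doubling time infinite")
  new("GompertzFit", A = A, b = b, doublingTime = doubling,
      ciB = as.numeric(ci), rSquared = summary(fit)$r.squared,
      nBins = nrow(tab),
      seB = unname(summary(fit)$coefficients[2, 2]))
}

#' @rdname accessors
#' @export
setMethod("doublingTime", "GompertzFit", function(x) x@doublingTime)

setMethod("show", "GompertzFit", function(object) {
  cat("GompertzFit: A =", format(object@A, digits = 4),
      " b =", format(object@b, digits = 4), "\n")
  cat("  doubling time:", format(object@doublingTime, digits = 3),
      "years (CI on b:",
      paste(format(object@ciB, digits = 3), collapse = ", "), ")\n")
  cat("  bins:", object@nBins,
      " log-scale R^2:", format(object@rSquared, digits = 3), "\n")
})

#' Mortality stratified by delta-age
#'
#' Bins mortality over delta-age instead of age — for a single
#' chronological age (`fixedAge`, integer years) or for all ages pooled —
#' and fits a Gompertz curve to the result.  Among people of identical
#' chronological age, a Gompertz-like rise of mortality with delta-age is
#' the signature that the clock measures biological age.
#'
#' @param delta delta-age values.
#' @param died death flags.
#' @param age chronological ages (needed when `fixedAge` is given).
#' @param fixedAge integer age to stratify on, or `NULL` for all ages.
#' @param binWidth,minBin binning parameters.
#' @return list with `table` and `fit`.
#' @export
deltaAgeMortality <- function(delta, died, age = NULL, fixedAge = NULL,
                              binWidth = 1, minBin = 50) {
  if (!is.null(fixedAge)) {
    if (is.null(age)) stop("deltaAgeMortality: age needed with fixedAge")
    sel <- floor(age) == fixedAge
    if (sum(sel) < 3 * minBin)
      stop("deltaAgeMortality: stratum too small (", sum(sel), " rows)")
    delta <- delta[sel]; died <- died[sel]
  }
  tab <- binnedMortality(delta, died, binWidth = binWidth, minBin = minBin)
  list(table = tab, fit = fitGompertz(tab))
}

#' Mortality-risk equivalence of delta-age and chronological years
#'
#' Fits a complementary-log-log binary regression of death-in-follow-up on
#' age and delta-age (equivalent to a Gompertz log-hazard model
#' `log h = c + b1 age + b2 deltaAge` under the exact cumulative-hazard
#' link) and returns the ratio `b2 / b1` with a delta-method confidence
#' interval.  A ratio of 1 means one year of delta-age carries the same
#' mortality penalty as one chronological year.
#'
#' @param age,delta,died aligned vectors.
#' @param level confidence level (default 0.95).
#' @return list with `ratio`, `ci`, `b_age`, `b_delta`, their SEs and the
#'   fitted model's convergence flag.
#' @export
yearEquivalence <- function(age, delta, died, level = 0.95) {
  stopifnot(length(age) == length(delta), length(age) == length(died))
  fit <- glm(died ~ age + delta,
             family = binomial(link = "cloglog"))
  if (!fit$converged) stop("yearEquivalence: model did not converge")
  cf <- coef(fit)
  V <- vcov(fit)
  if (any(!is.finite(cf)) || any(diag(V) > 1e3))
    stop("yearEquivalence: degenerate fit (separation?)")
  b1 <- cf["age"]; b2 <- cf["delta"]
  ratio <- b2 / b1
  ## delta method for b2/b1
  grad <- c(-b2 / b1^2, 1 / b1)
  vr <- as.numeric(t(grad) %*% V[c("age", "delta"), c("age", "delta")] %*%
                     grad)
  zq <- qnorm(1 - (1 - level) / 2)
  list(ratio = unname(ratio),
       ci = unname(ratio + c(-1, 1) * zq * sqrt(vr)),
       b_age = unname(b1), b_delta = unname(b2),
       se_age = sqrt(V["age", "age"]),
       se_delta = sqrt(V["delta", "delta"]),
       converged = fit$converged)
}
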