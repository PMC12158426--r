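## PLS1 core (NIPALS solution via the deflation-free kernel recursion;
## exact for a univariate response).  X and y are centered on the
## training means internally.  Only the covariance vector s = X'f is
## deflated (s <- s - q_k t't p_k) and scores come from the rotated
## weights (t_k = X r_k, r_k = w_k - sum_j (p_j'w_k) r_j), so no n x p
## copy of X is ever made.  Returns weights W, X-loadings P, y-loadings
## q, rotated weights Wstar and the per-component coefficient matrix
## (p x K): column k = coefficients using components 1..k.
pls1Fit <- function(X, y, K) {
  n <- nrow(X); p <- ncol(X)
  K <- min(K, p, n - 1)
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)   # single centered copy
  f <- y - my
  W <- P <- R <- matrix(0, p, K)
  q <- numeric(K)
  s <- as.numeric(crossprod(Xc, f))
  used <- 0
  for (k in seq_len(K)) {
    nw <- sqrt(sum(s^2))
    if (nw < 1e-10) break
    w <- s / nw
    r <- w
    if (k > 1) {
      proj <- crossprod(P[, seq_len(k - 1), drop = FALSE], w)
      r <- w - R[, seq_len(k - 1), drop = FALSE] %*% proj
    }
    t <- as.numeric(Xc %*% r)
    tt <- sum(t^2)
    if (tt < 1e-10) break
    pk <- as.numeric(crossprod(Xc, t)) / tt
    qk <- sum(f * t) / tt
    W[, k] <- w; P[, k] <- pk; R[, k] <- r; q[k] <- qk
    s <- s - qk * tt * pk
    used <- k
  }
  if (used == 0) stop("pls1Fit: response has no covariance with X")
  idx <- seq_len(used)
  W <- W[, idx, drop = FALSE]
  P <- P[, idx, drop = FALSE]
  R <- R[, idx, drop = FALSE]
  q <- q[idx]
  ## R equals W (P'W)^-1, the rotated weights; B_k = R[,1:k] q[1:k]
  B <- apply(upper.tri(diag(used), diag = TRUE), 2, function(m)
    R[, m, drop = FALSE] %*% q[m])
  B <- matrix(B, nrow = p)
  list(W = W, P = P, q = q, Wstar = R, B = B, xMeans = mx, yMean = my,
       ncomp = used)
}

pls1Predict <- function(fit, X, k) {
  Xc <- sweep(as.matrix(X), 2, fit$xMeans)
  fit$yMean + as.numeric(Xc %*% fit$B[, k])
}

#' Select the PLS component count by the one-sigma rule
#'
#' Returns the smallest component count (at least 1) whose cross-validated
#' RMSEP does not exceed the global minimum RMSEP plus the standard error
#' at that minimum.  The first curve entry is the intercept-only model
#' (0 components) and is not itself a candidate.
#'
#' @param curve data.frame with `ncomp` (starting at 0), `rmsep`, `se`.
#' @return selected component count (integer >= 1).
#' @export
selectComponents <- function(curve) {
  stopifnot(all(c("ncomp", "rmsep", "se") %in% names(curve)),
            nrow(curve) >= 2)
  if (anyNA(curve$se)) stop("selectComponents: missing SEs in RMSEP curve")
  i <- which.min(curve$rmsep)
  lim <- curve$rmsep[i] + curve$se[i]
  cand <- curve$ncomp >= 1 & curve$rmsep <= lim
  if (!any(cand)) return(1L)  # nothing beats the intercept: minimal model
  as.integer(min(curve$ncomp[cand]))
}

#' Fit a PLS age clock with cross-validated component selection
#'
#' PLS1 regression of age on a complete, standardized trait matrix for one
#' sex at a time.  The RMSEP curve is estimated by `cvFolds`-fold
#' cross-validation with a randomized, seeded fold assignment, the
#' component count chosen by the one-sigma rule, and the model refit on
#' all rows.  By default a slope calibration is then applied: raw
#' predictions are regressed on age and rescaled by the inverse slope, the
#' standard age-bias correction that removes regression-to-the-mean
#' shrinkage so that a year of delta-age is on the scale of a
#' chronological year.
#'
#' @param X complete standardized matrix (individuals x traits).
#' @param age chronological ages.
#' @param maxComponents most components probed (truncated to the matrix
#'   rank with a warning).
#' @param cvFolds cross-validation fold count (default 10).
#' @param seed seed for the fold assignment.
#' @param calibrate apply the slope calibration (default TRUE).
#' @param sex optional label stored on the model.
#' @param scaler optional scaler (from preprocessing) stored for reuse.
#' @return A [ClockModel-class].
#' @export
fitPlsClock <- function(X, age, maxComponents = 10, cvFolds = 10,
                        seed = 1, calibrate = TRUE, sex = NA_character_,
                        scaler = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(age))
  if (anyNA(X)) stop("fitPlsClock: X must be complete (impute first)")
  n <- nrow(X); p <- ncol(X)
  rank <- min(p, n - 1)
  if (maxComponents > rank) {
    warning("fitPlsClock: maxComponents exceeds rank, truncated to ", rank)
    maxComponents <- rank
  }
  set.seed(seed)
  fold <- sample(rep(seq_len(cvFolds), length.out = n))
  K <- maxComponents
  sqerr <- matrix(0, cvFolds, K + 1)  # column 1 = intercept-only
  cnt <- numeric(cvFolds)
  kUsed <- K
  for (f in seq_len(cvFolds)) {
    tr <- fold != f
    fit <- pls1Fit(X[tr, , drop = FALSE], age[tr], K)
    kf <- fit$ncomp
    kUsed <- min(kUsed, kf)
    te <- which(!tr)
    cnt[f] <- length(te)
    sqerr[f, 1] <- sum((age[te] - mean(age[tr]))^2)
    for (k in seq_len(K)) {
      kk <- min(k, kf)
      pred <- pls1Predict(fit, X[te, , drop = FALSE], kk)
      sqerr[f, k + 1] <- sum((age[te] - pred)^2)
    }
  }
  foldRmsep <- sqrt(sweep(sqerr, 1, cnt, "/"))
  rmsep <- sqrt(colSums(sqerr) / n)
  se <- apply(foldRmsep, 2, sd) / sqrt(cvFolds)
  curve <- data.frame(ncomp = 0:K, rmsep = rmsep, se = se)
  ncomp <- min(selectComponents(curve), kUsed)

  fit <- pls1Fit(X, age, ncomp)
  ncomp <- min(ncomp, fit$ncomp)
  B <- fit$B[, ncomp]
  intercept <- fit$yMean - sum(B * fit$xMeans)
  calib <- c(alpha = 0, slope = 1)
  if (calibrate) {
    raw <- intercept + as.numeric(X %*% B)
    cf <- coef(lm(raw ~ age))
    if (is.finite(cf[2]) && cf[2] > 1e-8) {
      calib <- c(alpha = unname(cf[1]), slope = unname(cf[2]))
      B <- B / calib["slope"]
      intercept <- (intercept - calib["alpha"]) / calib["slope"]
    }
  }
  new("ClockModel",
      sex = as.character(sex),
      traits = colnames(X),
      componentCount = as.integer(ncomp),
      xWeights = fit$Wstar[, seq_len(ncomp), drop = FALSE],
      xLoadings = fit$P[, seq_len(ncomp), drop = FALSE],
      yLoadings = fit$q[seq_len(ncomp)],
      coefficients = setNames(as.numeric(B), colnames(X)),
      intercept = unname(intercept),
      rmsepCurve = curve,
      cvFolds = as.integer(cvFolds),
      calibration = calib,
      scaler = if (is.null(scaler))
        data.frame(column = character(0), mean = numeric(0),
                   sd = numeric(0)) else scaler,
      seed = as.integer(seed))
}

#' Predict age from a fitted clock
#'
#' Linear and order-independent: `intercept + X %*% coefficients`.
#'
#' @param model a [ClockModel-class].
#' @param X matrix whose columns match the model's traits.
#' @return predicted ages.
#' @export
predictAge <- function(model, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), model@traits)) {
    miss <- setdiff(model@traits, colnames(X))
    if (length(miss))
      stop("predictAge: missing trait column(s): ",
           paste(miss, collapse = ", "))
    X <- X[, model@traits, drop = FALSE]
  }
  if (anyNA(X)) stop("predictAge: X must be complete")
  model@intercept + as.numeric(X %*% model@coefficients)
}

#' Per-phenotype weight in the fitted clock
#'
#' The clock's components are deconstructed into per-trait weights:
#' `weight_j = sum_k | wstar_jk * q_k |`, the summed absolute contribution
#' of trait j across all selected components (rotated X-weights times
#' y-loadings).  For a single-component model the ranking coincides with
#' ranking by absolute coefficient.
#'
#' @param model a [ClockModel-class].
#' @return data.frame of `trait`, `weight`, sorted descending (ties broken
#'   by trait id).
#' @export
phenotypeWeights <- function(model) {
  contrib <- sweep(abs(model@xWeights), 2, abs(model@yLoadings), "*")
  w <- rowSums(contrib)
  out <- data.frame(trait = model@traits, weight = unname(w),
                    stringsAsFactors = FALSE)
  out[order(-out$weight, out$trait), , drop = FALSE]
}

#' @rdname accessors
#' @export
setMethod("componentCount", "ClockModel", function(x) x@componentCount)

#' @rdname accessors
#' @export
setMethod("rmsepCurve", "ClockModel", function(x) x@rmsepCurve)

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel (sex:", object@sex, ")\n")
  cat("  traits:", length(object@traits),
      " components:", object@componentCount,
      " cvFolds:", object@cvFolds, "\n")
  i <- object@componentCount + 1
  cat("  CV RMSEP at selection:",
      sprintf("%.3f", object@rmsepCurve$rmsep[i]), "years\n")
})
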