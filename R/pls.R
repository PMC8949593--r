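#' Fit a PLS1 regression model by NIPALS
#'
#' Single-response partial least squares with NIPALS deflation. `X` and `y`
#' are centered internally (means stored in the model). For each latent
#' variable: `w = X'y / ||X'y||`, `t = Xw`, `p = X't / t't`,
#' `q = y't / t't`, then `X <- X - t p'`, `y <- y - t q`. The regression
#' vector `b = W (P'W)^-1 q` is mapped back to the uncentered frame so that
#' predictions are `(X_new - x_mean) b + y_mean`. Per-LV explained variance
#' is accounted from the deflation: `100 * ||t p'||_F^2 / ||X_c||_F^2` for
#' X and `100 * q^2 t't / ||y_c||^2` for y.
#'
#' @param X Numeric matrix, samples x variables (already preprocessed), or
#'   a [SpectrumSet-class] (spectra become rows).
#' @param y Numeric response (amorphous content, % w/w), one per sample.
#' @param nLV Number of latent variables (>= 1; <= min(n - 1, p)).
#' @param wavenumber Optional variable axis stored with the model (taken
#'   from `X` when it is a `SpectrumSet`).
#' @param chainState Optional frozen preprocessing state
#'   (see [fitChain()]) carried for prediction-time replay.
#' @return A [PLSModel-class].
#' @seealso [loocv()], [predict,PLSModel-method], [hotellingEllipse()]
#' @export
fitPLS <- function(X, y, nLV, wavenumber = NULL, chainState = list()) {
  if (is(X, "SpectrumSet")) {
    wavenumber <- wavenumbers(X)
    X <- t(intensityMatrix(X))
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  nLV <- as.integer(nLV)
  stopifnot(length(y) == n, nLV >= 1L)
  if (n < nLV + 1L) stop("need at least nLV + 1 samples")
  if (ncol(X) < nLV) stop("need at least nLV variables")
  if (is.null(wavenumber)) wavenumber <- seq_len(ncol(X))
  xMean <- colMeans(X)
  yMean <- mean(y)
  dec <- .nipals(sweep(X, 2L, xMean), y - yMean, nLV)
  if (dec$nComp < nLV)
    stop("degenerate fit: residual y is orthogonal to X after ",
         dec$nComp, " component(s)")
  PtW <- crossprod(dec$P, dec$W)
  R <- dec$W %*% solve(PtW)
  b <- drop(R %*% dec$q)
  new("PLSModel", nLV = nLV, wavenumber = as.numeric(wavenumber),
      xMean = xMean, yMean = yMean,
      weights = dec$W, xLoadings = dec$P, yLoadings = dec$q,
      coef = b, projection = R, scores = dec$T,
      xVarExplained = dec$xVar, yVarExplained = dec$yVar,
      chainState = if (inherits(chainState, "FittedChain"))
        list(state = chainState) else chainState)
}

## NIPALS PLS1 core on centered data; stops early on a degenerate component
.nipals <- function(Xc, yc, nLV) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, nLV); P <- matrix(0, p, nLV); Tm <- matrix(0, n, nLV)
  q <- numeric(nLV); xVar <- numeric(nLV); yVar <- numeric(nLV)
  ssX <- sum(Xc^2); ssY <- sum(yc^2)
  nComp <- 0L
  for (a in seq_len(nLV)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(ssX))) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-300) break
    pv <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
    xVar[a] <- if (ssX > 0) 100 * tt * sum(pv^2) / ssX else 0
    yVar[a] <- if (ssY > 0) 100 * qa^2 * tt / ssY else 0
    nComp <- a
  }
  idx <- seq_len(max(nComp, 1L))
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       T = Tm[, idx, drop = FALSE], q = q[idx],
       xVar = xVar[idx], yVar = yVar[idx], nComp = nComp)
}

#' Predict amorphous content from a fitted PLS model
#'
#' @param object A [PLSModel-class].
#' @param newdata Numeric matrix (samples x variables) on the model's
#'   retained variable set, a numeric vector (one sample), or a
#'   [SpectrumSet-class] whose axis must equal the model's axis exactly.
#'   Spectra must already carry the model's frozen preprocessing.
#' @param ... Ignored.
#' @return Numeric predictions, `(X - x_mean) b + y_mean`.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  X <- .coerceToModelFrame(object, newdata)
  drop(sweep(X, 2L, object@xMean) %*% object@coef) + object@yMean
})

.coerceToModelFrame <- function(object, newdata) {
  if (is(newdata, "SpectrumSet")) {
    wn <- wavenumbers(newdata)
    if (length(wn) != length(object@wavenumber) ||
        any(wn != object@wavenumber))
      stop("axis mismatch: spectra are not on the model's retained wavenumber set")
    X <- t(intensityMatrix(newdata))
  } else {
    X <- if (is.vector(newdata)) matrix(newdata, nrow = 1L)
         else as.matrix(newdata)
    if (ncol(X) != length(object@coef))
      stop("axis mismatch: expected ", length(object@coef),
           " variables, got ", ncol(X))
  }
  X
}

#' Project new spectra into a model's score space
#'
#' Scores for new (preprocessed) samples: `T_new = (X - x_mean) W (P'W)^-1`.
#'
#' @inheritParams predict,PLSModel-method
#' @return Numeric matrix, samples x nLV.
#' @export
projectScores <- function(object, newdata) {
  stopifnot(is(object, "PLSModel"))
  X <- .coerceToModelFrame(object, newdata)
  sweep(X, 2L, object@xMean) %*% object@projection
}

#' @rdname fitPLS
#' @export
setMethod("explainedVariance", "PLSModel",
          function(object) object@xVarExplained)

#' @export
setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variable(s), %d variables, %d calibration samples\n",
              object@nLV, length(object@coef), nrow(object@scores)))
  cat(sprintf("  X variance explained per LV (%%): %s\n",
              paste(sprintf("%.2f", object@xVarExplained), collapse = ", ")))
  cat(sprintf("  y variance explained per LV (%%): %s\n",
              paste(sprintf("%.2f", object@yVarExplained), collapse = ", ")))
})

#' Leave-one-out cross-validation for PLS latent-variable selection
#'
#' For each candidate count `k = 1..maxLV`, each sample is held out in
#' turn, the model is refit on the remainder (including re-centering of X
#' and y inside the fold) and the held-out sample predicted; `rmsecv(k)` is
#' the root mean squared held-out error. The selected count is the
#' smallest `k` whose RMSECV is within 2% of the minimum (parsimony rule,
#' recorded verbatim in `selection_rule`). Counts whose fold fits are
#' degenerate are reported as `NA`.
#'
#' @inheritParams fitPLS
#' @param maxLV Largest count to evaluate (<= n - 2).
#' @return A `CrossValResult` list: `rmsecv_by_nlv`, `selected_n_lv`,
#'   `selection_rule`.
#' @export
loocv <- function(X, y, maxLV) {
  if (is(X, "SpectrumSet")) X <- t(intensityMatrix(X))
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  maxLV <- as.integer(maxLV)
  stopifnot(length(y) == n, maxLV >= 1L)
  if (maxLV > n - 2L) stop("maxLV must be <= n - 2")
  sqerr <- matrix(NA_real_, n, maxLV)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    xm <- colMeans(Xtr); ym <- mean(ytr)
    dec <- .nipals(sweep(Xtr, 2L, xm), ytr - ym, maxLV)
    xc <- X[i, ] - xm
    for (k in seq_len(dec$nComp)) {
      bk <- drop(dec$W[, 1:k, drop = FALSE] %*%
                 solve(crossprod(dec$P[, 1:k, drop = FALSE],
                                 dec$W[, 1:k, drop = FALSE])) %*%
                 dec$q[1:k])
      sqerr[i, k] <- (sum(xc * bk) + ym - y[i])^2
    }
  }
  rmsecv <- sqrt(colMeans(sqerr))           # NA if any fold was degenerate
  avail <- which(!is.na(rmsecv))
  if (!length(avail)) stop("all candidate LV counts were degenerate")
  best <- min(rmsecv[avail])
  sel <- avail[which(rmsecv[avail] <= 1.02 * best)[1L]]
  structure(list(rmsecv_by_nlv = rmsecv, selected_n_lv = as.integer(sel),
                 selection_rule =
                   "smallest nLV with RMSECV <= 1.02 * min(RMSECV)"),
            class = "CrossValResult")
}

#' Validation metrics (ICH-style)
#'
#' Root mean square error `sqrt(mean((y - yhat)^2))`, coefficient of
#' determination `R^2 = 1 - SSE/SST` (penalizing bias, not a squared
#' correlation), and mean signed bias `mean(yhat - y)`.
#'
#' @param yTrue,yPred Numeric vectors of equal length >= 2.
#' @param context One of `"CAL"`, `"CV"`, `"PRED"` (labels the RMSE as
#'   RMSEC / RMSECV / RMSEP).
#' @return List with `rmse`, `r2`, `bias`, `n`, `context`.
#' @export
validationMetrics <- function(yTrue, yPred, context = c("CAL", "CV", "PRED")) {
  context <- match.arg(context)
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred) || length(yTrue) < 2L)
    stop("yTrue and yPred must have equal length >= 2")
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("r2 undefined: zero variance in yTrue")
  sse <- sum((yTrue - yPred)^2)
  list(rmse = sqrt(mean((yTrue - yPred)^2)), r2 = 1 - sse / sst,
       bias = mean(yPred - yTrue), n = length(yTrue), context = context)
}

#' Hotelling T-squared confidence ellipse in score space
#'
#' Builds the alpha-level admissibility ellipse for a pair of latent
#' variables from the calibration scores: per-LV score variances use the
#' n - 1 denominator and the limit is the small-sample F form
#' `T2_lim = 2 (n - 1) / (n - 2) * F(1 - alpha; 2, n - 2)`. A sample with
#' scores `t` is inside when `sum_k t_k^2 / var_k <= T2_lim`.
#'
#' @param object A [PLSModel-class] with >= 4 calibration samples and >= 2
#'   LVs (or at least `max(lvPair)`), or a numeric matrix of calibration
#'   scores (samples x LVs).
#' @param lvPair Which two LVs span the ellipse (default LV1 vs LV2).
#' @param alpha Significance level (default 0.05, i.e. a 95% ellipse).
#' @return A `ScoresEllipse` list: `t2_limit`, `score_var`, `lv_pair`,
#'   `alpha`, `n_cal`.
#' @export
hotellingEllipse <- function(object, lvPair = c(1L, 2L), alpha = 0.05) {
  stopifnot(length(lvPair) == 2L, alpha > 0, alpha < 1)
  S <- if (is(object, "PLSModel")) object@scores else as.matrix(object)
  n <- nrow(S)
  if (n < 4L) stop("need >= 4 calibration samples for the ellipse")
  if (max(lvPair) > ncol(S))
    stop("model has only ", ncol(S), " latent variable(s)")
  v <- apply(S[, lvPair, drop = FALSE], 2L, stats::var)
  if (any(v == 0)) stop("degenerate: zero score variance")
  lim <- 2 * (n - 1) / (n - 2) * stats::qf(1 - alpha, 2, n - 2)
  structure(list(t2_limit = lim, score_var = v,
                 lv_pair = as.integer(lvPair), alpha = alpha, n_cal = n),
            class = "ScoresEllipse")
}

#' @rdname hotellingEllipse
#' @param ellipse A `ScoresEllipse`.
#' @param scores Numeric matrix of scores for the ellipse's LV pair
#'   (samples x 2), e.g. columns of [projectScores()].
#' @return `t2Statistic`: the T-squared value per sample; `inEllipse`:
#'   logical membership (`T2 <= t2_limit`).
#' @export
t2Statistic <- function(ellipse, scores) {
  stopifnot(inherits(ellipse, "ScoresEllipse"))
  scores <- if (is.vector(scores)) matrix(scores, nrow = 1L)
            else as.matrix(scores)
  stopifnot(ncol(scores) == 2L)
  drop(scores^2 %*% (1 / ellipse$score_var))
}

#' @rdname hotellingEllipse
#' @export
inEllipse <- function(ellipse, scores) {
  t2Statistic(ellipse, scores) <= ellipse$t2_limit
}

.MODEL_FORMAT_VERSION <- "1"

#' Save / load a PLS model as JSON
#'
#' All numeric fields round-trip at full double precision (>= 15
#' significant digits); the frozen preprocessing state is embedded so a
#' loaded model predicts identically to the original. Files written by a
#' different format version, or corrupted files, raise a clear error.
#'
#' @param object A [PLSModel-class].
#' @param path JSON file path.
#' @return `saveModel`: `path`, invisibly. `loadModel`: the restored
#'   [PLSModel-class].
#' @export
saveModel <- function(object, path) {
  stopifnot(is(object, "PLSModel"))
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    n_lv = object@nLV, wavenumber = object@wavenumber,
    x_mean = object@xMean, y_mean = object@yMean,
    weights = object@weights, x_loadings = object@xLoadings,
    y_loadings = object@yLoadings, coef = object@coef,
    projection = object@projection, scores = object@scores,
    x_var_explained = object@xVarExplained,
    y_var_explained = object@yVarExplained,
    chain_state = as.character(jsonlite::serializeJSON(object@chainState,
                                                       digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  req <- c("format_version", "n_lv", "wavenumber", "x_mean", "y_mean",
           "weights", "x_loadings", "y_loadings", "coef", "projection",
           "scores", "chain_state")
  if (!is.list(obj) || !all(req %in% names(obj)))
    stop("corrupted model file: missing fields ",
         paste(setdiff(req, names(obj)), collapse = ", "))
  if (!identical(as.character(obj$format_version), .MODEL_FORMAT_VERSION))
    stop("model format version mismatch: file has '", obj$format_version,
         "', this package reads '", .MODEL_FORMAT_VERSION, "'")
  asMat <- function(m) if (is.matrix(m)) m else as.matrix(m)
  new("PLSModel", nLV = as.integer(obj$n_lv),
      wavenumber = as.numeric(obj$wavenumber),
      xMean = as.numeric(obj$x_mean), yMean = as.numeric(obj$y_mean),
      weights = asMat(obj$weights), xLoadings = asMat(obj$x_loadings),
      yLoadings = as.numeric(obj$y_loadings), coef = as.numeric(obj$coef),
      projection = asMat(obj$projection), scores = asMat(obj$scores),
      xVarExplained = as.numeric(obj$x_var_explained),
      yVarExplained = as.numeric(obj$y_var_explained),
      chainState = jsonlite::unserializeJSON(obj$chain_state))
}
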