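#' @importFrom signal sgolay
#' @importFrom Matrix Diagonal bandSparse crossprod solve
NULL

## rebuild a set with a new axis/intensity, preserving per-spectrum metadata
.replaceData <- function(x, wn, m) {
  colnames(m) <- colnames(assay(x, "intensity"))
  se <- SummarizedExperiment(
    assays = list(intensity = m),
    rowData = DataFrame(wavenumber = as.numeric(wn)),
    colData = colData(x), metadata = metadata(x))
  new("SpectrumSet", se)
}

## split an axis into contiguous runs of its base (smallest) step; an axis
## whose small steps are not mutually equal is irregular -> NULL
.uniformSegments <- function(wn) {
  d <- diff(wn)
  h <- min(d)
  gap <- which(abs(d - h) > 1e-9 * abs(h))
  if (any(d[gap] < h)) return(NULL)
  bounds <- c(0L, gap, length(wn))
  segs <- lapply(seq_len(length(bounds) - 1L), function(i)
    (bounds[i] + 1L):bounds[i + 1L])
  list(step = h, segments = segs)
}

#' Savitzky-Golay derivative filter
#'
#' Differentiates each spectrum by fitting a least-squares polynomial of
#' degree `polyorder` over a sliding centered window of `window` points and
#' taking the `derivOrder`-th derivative of the fit at the window center,
#' expressed per unit axis step (cm^-1). Edge points that cannot carry a
#' full window are trimmed — `(window - 1)/2` points at each end — rather
#' than extrapolated, and the axis is trimmed identically. The filter
#' reproduces polynomials of degree <= `polyorder` exactly at interior
#' points.
#'
#' @param x A [SpectrumSet-class] on a uniform-step axis.
#' @param window Odd window length in points (>= 5; default 21).
#' @param polyorder Polynomial degree (default 2; must be < `window`).
#' @param derivOrder Derivative order (default 2; must be <= `polyorder`).
#' @return A `SpectrumSet` with trimmed axis.
#' @export
savgolDerivative <- function(x, window = 21L, polyorder = 2L,
                             derivOrder = 2L) {
  stopifnot(is(x, "SpectrumSet"))
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    stop("window must be an odd integer >= 5")
  if (polyorder >= window) stop("polyorder must be < window")
  if (derivOrder > polyorder) stop("derivOrder must be <= polyorder")
  wn <- wavenumbers(x)
  if (length(wn) < window)
    stop("spectrum has ", length(wn), " points; need >= window (", window, ")")
  segs <- .uniformSegments(wn)
  if (is.null(segs))
    stop("axis step is not uniform; resample explicitly before filtering")
  if (any(lengths(segs$segments) < window))
    stop("axis is not uniform in steps of ", segs$step,
         " cm^-1 over windows of ", window,
         " points; resample explicitly before filtering")
  half <- (window - 1L) %/% 2L
  coef <- rev(signal::sgolay(p = polyorder, n = window, m = derivOrder)[half + 1L, ])
  m <- intensityMatrix(x)
  ## the derivative is evaluated independently on each contiguous uniform
  ## segment (region selection may leave gaps); edges of every segment are
  ## trimmed by (window - 1)/2 points
  pieces <- lapply(segs$segments, function(idx) {
    sub <- m[idx, , drop = FALSE]
    out <- apply(sub, 2L, function(v)
      drop(stats::embed(v, window) %*% coef)) / segs$step^derivOrder
    if (is.vector(out)) out <- matrix(out, ncol = ncol(m))
    list(wn = wn[idx][(half + 1L):(length(idx) - half)], m = out)
  })
  .replaceData(x, unlist(lapply(pieces, `[[`, "wn")),
               do.call(rbind, lapply(pieces, `[[`, "m")))
}

#' Standard normal variate (SNV) scatter correction
#'
#' Standardizes each spectrum to zero mean and unit standard deviation
#' (n - 1 denominator), removing per-spectrum multiplicative scatter and
#' additive offset: `snv(a*x + b) == snv(x)` for `a > 0`.
#'
#' @param x A [SpectrumSet-class].
#' @return A `SpectrumSet` of standardized spectra.
#' @export
snv <- function(x) {
  stopifnot(is(x, "SpectrumSet"))
  m <- intensityMatrix(x)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  if (any(sdv == 0))
    stop("degenerate input: constant spectrum (zero standard deviation) in column ",
         which(sdv == 0)[1L])
  .replaceData(x, wavenumbers(x), sweep(sweep(m, 2L, mu), 2L, sdv, "/"))
}

#' Whittaker asymmetric-least-squares baseline correction
#'
#' Estimates a smooth baseline `z` per spectrum by minimizing
#' `sum_i w_i (x_i - z_i)^2 + lambda * sum (d2 z)^2` (second-order
#' differences), with the asymmetric-weight iteration: starting from
#' all-ones weights, weights are reset to `p` where `x > z` (points above
#' the baseline, i.e. peaks) and `1 - p` where `x <= z`, until the weights
#' stabilize (relative change < `tol`) or `maxIter` is reached. With small
#' `p` the baseline hugs the lower envelope, passing under peaks. The
#' banded normal equations are solved sparsely.
#'
#' @param x A [SpectrumSet-class] with >= 4 points.
#' @param lam Smoothness factor lambda >= 0 (default 100000).
#' @param p Asymmetry factor in (0, 1) (default 0.001).
#' @param maxIter Maximum weight iterations (default 10).
#' @param tol Relative weight-change convergence threshold (default 1e-6).
#' @return List with `baseline` and `corrected` (`x - baseline`), both
#'   `SpectrumSet`s.
#' @export
whittakerBaseline <- function(x, lam = 1e5, p = 0.001, maxIter = 10L,
                              tol = 1e-6) {
  stopifnot(is(x, "SpectrumSet"), lam >= 0, p > 0, p < 1)
  wn <- wavenumbers(x)
  n <- length(wn)
  if (n < 4L) stop("need at least 4 points for a second-difference penalty")
  DtD <- .secondDiffPenalty(n)
  m <- intensityMatrix(x)
  z <- apply(m, 2L, .alsBaseline, DtD = DtD, lam = lam, p = p,
             maxIter = maxIter, tol = tol)
  list(baseline = .replaceData(x, wn, z),
       corrected = .replaceData(x, wn, m - z))
}

.secondDiffPenalty <- function(n) {
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  Matrix::crossprod(D)
}

.alsBaseline <- function(v, DtD, lam, p, maxIter, tol) {
  n <- length(v)
  w <- rep(1, n)
  z <- v
  for (it in seq_len(maxIter)) {
    A <- Matrix::Diagonal(x = w) + lam * DtD
    z <- as.numeric(Matrix::solve(A, w * v))
    wNew <- ifelse(v > z, p, 1 - p)
    change <- sum(abs(wNew - w)) / sum(w)
    w <- wNew
    if (change < tol) break
  }
  z
}

#' Normalize spectra to the area of a reference peak
#'
#' Divides each spectrum by its trapezoidal area over the closed window
#' `[center - halfWidth, center + halfWidth]` (default: the 1614 cm^-1
#' drug marker band, +/- 15 cm^-1), removing per-spectrum positive scale:
#' after normalization the window area is exactly 1.
#'
#' @param x A [SpectrumSet-class] whose axis has >= 3 points in the window.
#' @param center Window center, cm^-1 (default 1614).
#' @param halfWidth Window half width, cm^-1 (default 15).
#' @return A `SpectrumSet`.
#' @export
normalizeToPeakArea <- function(x, center = 1614, halfWidth = 15) {
  stopifnot(is(x, "SpectrumSet"))
  wn <- wavenumbers(x)
  idx <- which(wn >= center - halfWidth & wn <= center + halfWidth)
  if (length(idx) < 3L)
    stop(sprintf("window [%g, %g] cm^-1 covers only %d axis points (need >= 3)",
                 center - halfWidth, center + halfWidth, length(idx)))
  m <- intensityMatrix(x)
  area <- apply(m[idx, , drop = FALSE], 2L, .trapz, x = wn[idx])
  if (any(area <= 0))
    stop(sprintf("degenerate input: non-positive peak area in window [%g, %g] cm^-1",
                 center - halfWidth, center + halfWidth))
  .replaceData(x, wn, sweep(m, 2L, area, "/"))
}

.trapz <- function(y, x) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Select wavenumber regions
#'
#' Retains axis points lying inside any `keep` interval (closed bounds) and
#' outside every `exclude` interval (closed bounds; exclusion wins on
#' boundary points). Point order is preserved.
#'
#' @param x A [SpectrumSet-class].
#' @param keep,exclude Lists of `c(lower, upper)` intervals (cm^-1);
#'   `keep = NULL` keeps the whole axis.
#' @return A `SpectrumSet` restricted to the selected points.
#' @export
selectRegion <- function(x, keep = NULL, exclude = NULL) {
  stopifnot(is(x, "SpectrumSet"))
  wn <- wavenumbers(x)
  inAny <- function(iv) {
    hit <- rep(FALSE, length(wn))
    for (b in iv) {
      if (length(b) != 2L || b[1L] > b[2L])
        stop("intervals must be c(lower, upper) with lower <= upper")
      hit <- hit | (wn >= b[1L] & wn <= b[2L])
    }
    hit
  }
  sel <- if (is.null(keep)) rep(TRUE, length(wn)) else inAny(keep)
  if (!is.null(exclude)) sel <- sel & !inAny(exclude)
  if (!any(sel)) stop("region selection leaves no axis points")
  .replaceData(x, wn[sel], intensityMatrix(x)[sel, , drop = FALSE])
}

#' Mean-center a set of spectra
#'
#' Subtracts the per-wavenumber mean computed over the set. The returned
#' means are the frozen statistics used to center later prediction samples
#' against the calibration set (no refitting on test data).
#'
#' @param x A [SpectrumSet-class] with >= 2 spectra.
#' @return List with `set` (centered `SpectrumSet`) and `means` (numeric).
#' @export
meanCenter <- function(x) {
  stopifnot(is(x, "SpectrumSet"))
  if (ncol(x) < 2L) stop("mean-centering needs at least 2 spectra")
  m <- intensityMatrix(x)
  mu <- rowMeans(m)
  list(set = .replaceData(x, wavenumbers(x), m - mu), means = mu)
}

.CHAIN_STEPS <- c("select_region", "savgol", "snv", "whittaker",
                  "normalize_to_peak_area", "mean_center")
.NORM_STEPS <- c("snv", "normalize_to_peak_area")

#' Preprocessing chains
#'
#' A `PreprocessChain` is an ordered list of named preprocessing steps with
#' parameters. Two presets encode the reference NIR and Raman methods:
#'
#' * `nirDefaultChain()`: select 4000-6200 cm^-1 excluding the water band
#'   4800-5200 cm^-1; Savitzky-Golay 2nd derivative (21-point window, 2nd
#'   order polynomial); SNV; mean-centering.
#' * `ramanDefaultChain()`: select 1000-1700 cm^-1; Whittaker
#'   asymmetric-least-squares baseline (lambda = 100000, p = 0.001);
#'   normalization to the 1614 cm^-1 peak area; mean-centering.
#'
#' [fitChain()] applies a chain to a calibration set and freezes every
#' set-level statistic (the mean-centering means); [applyChain()] replays
#' the frozen chain on new spectra without refitting, so prediction data
#' never leak into calibration statistics.
#'
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param steps List of `list(name = , params = list(...))` entries; step
#'   names from `select_region`, `savgol`, `snv`, `whittaker`,
#'   `normalize_to_peak_area`, `mean_center`. At most one normalization
#'   step (`snv` / `normalize_to_peak_area`) is allowed.
#' @return A `PreprocessChain`.
#' @export
preprocessChain <- function(modality, steps) {
  modality <- match.arg(modality, .MODALITIES)
  nm <- vapply(steps, `[[`, character(1), "name")
  if (!all(nm %in% .CHAIN_STEPS))
    stop("unknown step(s): ", paste(setdiff(nm, .CHAIN_STEPS), collapse = ", "))
  if (sum(nm %in% .NORM_STEPS) > 1L)
    stop("at most one normalization step per chain")
  structure(list(modality = modality, steps = steps),
            class = "PreprocessChain")
}

#' @rdname preprocessChain
#' @export
nirDefaultChain <- function() {
  preprocessChain("NIR", list(
    list(name = "select_region",
         params = list(keep = list(c(4000, 6200)),
                       exclude = list(c(4800, 5200)))),
    list(name = "savgol",
         params = list(window = 21L, polyorder = 2L, derivOrder = 2L)),
    list(name = "snv", params = list()),
    list(name = "mean_center", params = list())))
}

#' @rdname preprocessChain
#' @export
ramanDefaultChain <- function() {
  preprocessChain("RAMAN", list(
    list(name = "select_region", params = list(keep = list(c(1000, 1700)))),
    list(name = "whittaker", params = list(lam = 1e5, p = 0.001)),
    list(name = "normalize_to_peak_area",
         params = list(center = 1614, halfWidth = 15)),
    list(name = "mean_center", params = list())))
}

.applyStep <- function(x, step, fitted, fit) {
  p <- step$params
  switch(step$name,
    select_region = list(set = do.call(selectRegion, c(list(x), p)),
                         state = NULL),
    savgol = list(set = do.call(savgolDerivative, c(list(x), p)),
                  state = NULL),
    snv = list(set = snv(x), state = NULL),
    whittaker = list(set = do.call(whittakerBaseline, c(list(x), p))$corrected,
                     state = NULL),
    normalize_to_peak_area = list(set = do.call(normalizeToPeakArea,
                                                c(list(x), p)),
                                  state = NULL),
    mean_center = {
      if (fit) {
        mc <- meanCenter(x)
        list(set = mc$set, state = list(means = mc$means,
                                        axis = wavenumbers(x)))
      } else {
        if (is.null(fitted))
          stop("no frozen means available; fit the chain on calibration data first")
        if (length(fitted$axis) != length(wavenumbers(x)) ||
            any(fitted$axis != wavenumbers(x)))
          stop("axis mismatch between frozen means and new spectra")
        list(set = .replaceData(x, wavenumbers(x),
                                intensityMatrix(x) - fitted$means),
             state = fitted)
      }
    },
    stop("unknown step: ", step$name))
}

.runChain <- function(x, chain, fittedStates, fit) {
  states <- vector("list", length(chain$steps))
  for (i in seq_along(chain$steps)) {
    res <- tryCatch(
      .applyStep(x, chain$steps[[i]], fittedStates[[i]], fit),
      error = function(e)
        stop(sprintf("chain step %d (%s): %s", i, chain$steps[[i]]$name,
                     conditionMessage(e)), call. = FALSE))
    x <- res$set
    states[[i]] <- res$state
  }
  list(set = x, states = states)
}

#' @rdname preprocessChain
#' @param x A [SpectrumSet-class] (calibration data for `fitChain`; new
#'   data for `applyChain`).
#' @param chain A `PreprocessChain`.
#' @return `fitChain`: list with `set` (processed calibration set) and
#'   `state` (a `FittedChain` holding the chain and frozen statistics).
#' @export
fitChain <- function(x, chain) {
  stopifnot(inherits(chain, "PreprocessChain"))
  if (modality(x) != chain$modality)
    stop("chain modality (", chain$modality, ") does not match set (",
         modality(x), ")")
  res <- .runChain(x, chain, vector("list", length(chain$steps)), fit = TRUE)
  list(set = res$set,
       state = structure(list(chain = chain, fitted = res$states,
                              axis = wavenumbers(res$set)),
                         class = "FittedChain"))
}

#' @rdname preprocessChain
#' @param state A `FittedChain` from [fitChain()].
#' @return `applyChain`: the processed `SpectrumSet` using frozen statistics.
#' @export
applyChain <- function(x, state) {
  stopifnot(inherits(state, "FittedChain"))
  .runChain(x, state$chain, state$fitted, fit = FALSE)$set
}
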