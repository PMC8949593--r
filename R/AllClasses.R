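#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

.MODALITIES <- c("NIR", "RAMAN")
.PRESENTATIONS <- c("POWDER", "COMPRESSED_SQUARE", "PRINTED_DISC")
.POLYMER_GRADES <- c("HPC_SSL", "HPC_SL", "HPC_L")
.COMPONENTS <- c("CRYSTALLINE_DRUG", "AMORPHOUS_DRUG", "POLYMER", "COLOURANT")

## Nominal acquisition windows per modality; out-of-range axes warn, not fail.
.MODALITY_RANGE <- list(NIR = c(3600, 12500), RAMAN = c(100, 2000))

#' SpectrumSet: a set of spectra sharing one wavenumber axis
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] with an
#' `"intensity"` assay (wavenumbers in rows, spectra in columns), the
#' wavenumber axis in `rowData(x)$wavenumber`, per-spectrum metadata
#' (`sample_id`, `position_id`, `presentation` and, optionally, the mixture
#' composition columns `crystalline`, `amorphous`, `polymer`, `colourant`,
#' `polymer_grade`) in `colData`, and the acquisition modality
#' (`"NIR"` or `"RAMAN"`) in `metadata(x)$modality`.
#'
#' The axis is normalized to strictly ascending order at construction;
#' spectra supplied on a descending axis are reversed consistently. All
#' member spectra share the axis exactly (by value): spectra acquired on
#' different grids must be resampled explicitly before being combined.
#'
#' @seealso [SpectrumSet()] for the constructor, [wavenumbers()],
#'   [intensityMatrix()], [modality()], [compositions()],
#'   [averageReplicates()]
#' @export
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  msg <- character()
  wn <- rowData(object)$wavenumber
  if (is.null(wn))
    return("rowData must contain a 'wavenumber' column")
  if (length(wn) < 2L)
    msg <- c(msg, "a spectrum needs at least 2 points")
  if (any(diff(wn) <= 0))
    msg <- c(msg, "wavenumber axis must be strictly ascending")
  mod <- metadata(object)$modality
  if (is.null(mod) || !mod %in% .MODALITIES)
    msg <- c(msg, "metadata()$modality must be 'NIR' or 'RAMAN'")
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  cd <- colData(object)
  for (col in c("sample_id", "position_id", "presentation"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain '%s'", col))
  if ("position_id" %in% colnames(cd) && any(cd$position_id < 0L))
    msg <- c(msg, "position_id must be >= 0 (0 marks replicate-averaged spectra)")
  if ("presentation" %in% colnames(cd) &&
      !all(cd$presentation %in% .PRESENTATIONS))
    msg <- c(msg, sprintf("presentation must be one of %s",
                          paste(.PRESENTATIONS, collapse = ", ")))
  if (all(c("crystalline", "amorphous", "polymer", "colourant") %in%
          colnames(cd)) && nrow(cd) > 0L) {
    tot <- cd$crystalline + cd$amorphous + cd$polymer + cd$colourant
    if (any(cd$crystalline < 0 | cd$amorphous < 0 |
            cd$polymer < 0 | cd$colourant < 0))
      msg <- c(msg, "composition mass fractions must be >= 0")
    if (any(abs(tot - 100) > 1e-9))
      msg <- c(msg, "composition mass fractions must sum to 100")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param wavenumber Numeric axis in cm^-1, strictly monotone (either
#'   direction; normalized to ascending).
#' @param intensity Numeric matrix, `length(wavenumber)` rows, one column per
#'   spectrum; or a numeric vector for a single spectrum.
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param sampleId Character vector, one entry per column. Sample ids may not
#'   contain the reserved `"__"` delimiter used in CSV column headers.
#' @param positionId Integer vector of scan positions (>= 1; 0 is reserved
#'   for replicate-averaged spectra). Default all 1.
#' @param presentation One of `"POWDER"`, `"COMPRESSED_SQUARE"`,
#'   `"PRINTED_DISC"`; recycled across spectra.
#' @param composition Optional `data.frame` keyed by `sample_id` with columns
#'   `crystalline`, `amorphous`, `polymer`, `colourant`, `polymer_grade`
#'   (mass fractions in % w/w summing to 100).
#' @return A [SpectrumSet-class] object with ascending axis.
#' @examples
#' wn <- seq(100, 2000, by = 1)
#' s <- SpectrumSet(wn, matrix(rnorm(length(wn) * 2), ncol = 2), "RAMAN",
#'                  sampleId = c("a", "a"), positionId = c(1L, 2L))
#' @export
SpectrumSet <- function(wavenumber, intensity, modality,
                        sampleId, positionId = NULL,
                        presentation = "POWDER", composition = NULL) {
  modality <- match.arg(modality, .MODALITIES)
  if (is.vector(intensity)) intensity <- matrix(intensity, ncol = 1L)
  intensity <- as.matrix(intensity)
  wavenumber <- as.numeric(wavenumber)
  if (nrow(intensity) != length(wavenumber))
    stop("intensity must have one row per wavenumber (",
         nrow(intensity), " rows vs ", length(wavenumber), " wavenumbers)")
  if (length(wavenumber) < 2L)
    stop("a spectrum needs at least 2 points")
  d <- diff(wavenumber)
  if (all(d < 0)) {              # descending axis: normalize
    wavenumber <- rev(wavenumber)
    intensity <- intensity[rev(seq_len(nrow(intensity))), , drop = FALSE]
  } else if (any(d <= 0)) {
    stop("wavenumber axis must be strictly monotone")
  }
  rng <- .MODALITY_RANGE[[modality]]
  if (wavenumber[1L] < rng[1L] || wavenumber[length(wavenumber)] > rng[2L])
    warning(sprintf("%s axis extends outside the nominal %g-%g cm^-1 range",
                    modality, rng[1L], rng[2L]))
  n <- ncol(intensity)
  sampleId <- as.character(rep_len(sampleId, n))
  if (any(grepl("__", sampleId, fixed = TRUE)))
    stop("sample ids may not contain the reserved '__' delimiter")
  if (is.null(positionId)) positionId <- rep.int(1L, n)
  positionId <- as.integer(rep_len(positionId, n))
  presentation <- as.character(rep_len(presentation, n))
  cd <- DataFrame(sample_id = sampleId, position_id = positionId,
                  presentation = presentation)
  if (!is.null(composition)) {
    composition <- as.data.frame(composition)
    if (!"sample_id" %in% colnames(composition))
      stop("composition must have a 'sample_id' column")
    idx <- match(sampleId, composition$sample_id)
    if (anyNA(idx))
      stop("composition missing sample ids: ",
           paste(unique(sampleId[is.na(idx)]), collapse = ", "))
    for (col in setdiff(colnames(composition), "sample_id"))
      cd[[col]] <- composition[[col]][idx]
  }
  colnames(intensity) <- sprintf("%s__%d", sampleId, positionId)
  rownames(intensity) <- NULL
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = DataFrame(wavenumber = wavenumber),
    colData = cd,
    metadata = list(modality = modality))
  new("SpectrumSet", se)
}

#' PLS1 regression model (NIPALS)
#'
#' Holds the latent-variable decomposition fitted by [fitPLS()]: weights
#' `W`, X-loadings `P`, y-loadings `q`, calibration scores `T`, the
#' regression vector mapped back to the uncentered frame, per-LV explained
#' variance for X and y, and the frozen preprocessing state used to bring
#' new spectra onto the model's variable space.
#'
#' @slot nLV number of latent variables.
#' @slot wavenumber retained variable axis (cm^-1).
#' @slot xMean,yMean centering applied internally during fitting.
#' @slot weights,xLoadings variables x nLV matrices (W, P).
#' @slot yLoadings per-LV y loadings (q).
#' @slot coef regression vector b = W (P'W)^-1 q.
#' @slot projection W (P'W)^-1: maps centered spectra to scores.
#' @slot scores calibration scores T (samples x nLV).
#' @slot xVarExplained,yVarExplained per-LV % of (centered) X / y variance.
#' @slot chainState frozen preprocessing chain state (list), or empty list.
#' @seealso [fitPLS()], [predict,PLSModel-method], [hotellingEllipse()]
#' @export
setClass("PLSModel",
  representation(nLV = "integer", wavenumber = "numeric",
                 xMean = "numeric", yMean = "numeric",
                 weights = "matrix", xLoadings = "matrix",
                 yLoadings = "numeric", coef = "numeric",
                 projection = "matrix", scores = "matrix",
                 xVarExplained = "numeric", yVarExplained = "numeric",
                 chainState = "list"))

setValidity("PLSModel", function(object) {
  msg <- character()
  a <- object@nLV
  if (a < 1L) msg <- c(msg, "nLV must be >= 1")
  if (ncol(object@weights) != a || ncol(object@xLoadings) != a ||
      length(object@yLoadings) != a || ncol(object@scores) != a)
    msg <- c(msg, "W, P, q, T must all have nLV components")
  if (length(object@coef) != length(object@wavenumber))
    msg <- c(msg, "regression vector must match the variable axis")
  ## score columns must be mutually orthogonal (NIPALS invariant)
  T <- object@scores
  if (a > 1L) {
    G <- crossprod(T)
    nrm <- sqrt(diag(G))
    off <- abs(G[upper.tri(G)]) / (outer(nrm, nrm)[upper.tri(G)])
    if (any(off > 1e-8)) msg <- c(msg, "score columns are not orthogonal")
  }
  if (any(object@xVarExplained < -1e-9) ||
      sum(object@xVarExplained) > 100 + 1e-6)
    msg <- c(msg, "xVarExplained entries must be >= 0 and sum to <= 100")
  if (length(msg)) msg else TRUE
})
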