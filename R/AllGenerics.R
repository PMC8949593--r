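#' @rdname SpectrumSet
#' @param x A `SpectrumSet`.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectrumSet
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname SpectrumSet
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname SpectrumSet
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SpectrumSet
#' @export
setGeneric("positionIds", function(x) standardGeneric("positionIds"))

#' @rdname SpectrumSet
#' @export
setGeneric("presentations", function(x) standardGeneric("presentations"))

#' @rdname SpectrumSet
#' @export
setGeneric("compositions", function(x) standardGeneric("compositions"))

#' Average replicate position scans into one spectrum per sample
#'
#' Each sample's final spectrum is the arithmetic per-wavenumber mean of the
#' spectra recorded at its scan positions; the averaged spectrum carries
#' `position_id = 0`. Sets already holding one spectrum per sample pass
#' through unchanged (up to `position_id`), so the operation is idempotent.
#'
#' @param x A [SpectrumSet-class].
#' @return A `SpectrumSet` with one spectrum per `sample_id`, in first-
#'   occurrence order.
#' @export
setGeneric("averageReplicates", function(x) standardGeneric("averageReplicates"))

#' @rdname fitPLS
#' @param object A `PLSModel`.
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))
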