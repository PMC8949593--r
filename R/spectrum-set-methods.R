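#' @rdname SpectrumSet
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x) rowData(x)$wavenumber)

#' @rdname SpectrumSet
#' @export
setMethod("intensityMatrix", "SpectrumSet", function(x) {
  m <- assay(x, "intensity")
  rownames(m) <- NULL
  m
})

#' @rdname SpectrumSet
#' @export
setMethod("modality", "SpectrumSet", function(x) metadata(x)$modality)

#' @rdname SpectrumSet
#' @export
setMethod("sampleIds", "SpectrumSet", function(x) colData(x)$sample_id)

#' @rdname SpectrumSet
#' @export
setMethod("positionIds", "SpectrumSet", function(x) colData(x)$position_id)

#' @rdname SpectrumSet
#' @export
setMethod("presentations", "SpectrumSet", function(x) colData(x)$presentation)

#' @rdname SpectrumSet
#' @export
setMethod("compositions", "SpectrumSet", function(x) {
  cd <- as.data.frame(colData(x))
  cols <- intersect(c("crystalline", "amorphous", "polymer", "colourant",
                      "polymer_grade"), colnames(cd))
  if (!length(cols)) return(NULL)
  out <- cd[!duplicated(cd$sample_id), c("sample_id", cols), drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @export
setMethod("show", "SpectrumSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("SpectrumSet (%s): %d spectra, %d points, %g-%g cm^-1\n",
              modality(object), ncol(object), length(wn),
              wn[1L], wn[length(wn)]))
  cat(sprintf("  samples: %d unique | positions: %s | presentation: %s\n",
              length(unique(sampleIds(object))),
              paste(unique(positionIds(object)), collapse = ","),
              paste(unique(presentations(object)), collapse = ",")))
  if (!is.null(compositions(object)))
    cat("  compositions attached (% w/w crystalline/amorphous/polymer/colourant)\n")
})

#' @rdname averageReplicates
#' @export
setMethod("averageReplicates", "SpectrumSet", function(x) {
  ids <- sampleIds(x)
  uniq <- unique(ids)
  m <- intensityMatrix(x)
  avg <- vapply(uniq, function(id)
    rowMeans(m[, ids == id, drop = FALSE]), numeric(nrow(m)))
  first <- match(uniq, ids)
  cd <- colData(x)[first, , drop = FALSE]
  comp <- compositions(x)
  SpectrumSet(wavenumbers(x), avg, modality(x),
              sampleId = uniq, positionId = rep.int(0L, length(uniq)),
              presentation = as.character(cd$presentation),
              composition = comp)
})

#' Build a mixture composition table
#'
#' Mass fractions are in % w/w and must sum to 100 within 1e-9 per sample.
#' In the calibration design the total drug load (crystalline + amorphous)
#' is 20% w/w, the polymer 77% and the colourant 3%; general mixtures are
#' not restricted to that split.
#'
#' @param sampleId Character ids.
#' @param crystalline,amorphous,polymer,colourant Mass fractions (% w/w).
#' @param polymerGrade One of `"HPC_SSL"`, `"HPC_SL"`, `"HPC_L"`.
#' @return A `data.frame`, one row per sample.
#' @examples
#' mixtureComposition("Cal1", crystalline = 20, amorphous = 0)
#' @export
mixtureComposition <- function(sampleId, crystalline, amorphous,
                               polymer = 77, colourant = 3,
                               polymerGrade = "HPC_L") {
  n <- length(sampleId)
  df <- data.frame(sample_id = as.character(sampleId),
                   crystalline = rep_len(crystalline, n),
                   amorphous = rep_len(amorphous, n),
                   polymer = rep_len(polymer, n),
                   colourant = rep_len(colourant, n),
                   polymer_grade = rep_len(polymerGrade, n),
                   stringsAsFactors = FALSE)
  if (!all(df$polymer_grade %in% .POLYMER_GRADES))
    stop("polymer_grade must be one of ", paste(.POLYMER_GRADES, collapse = ", "))
  fr <- df[, c("crystalline", "amorphous", "polymer", "colourant")]
  if (any(fr < 0)) stop("mass fractions must be >= 0")
  tot <- rowSums(fr)
  if (any(abs(tot - 100) > 1e-9))
    stop("mass fractions must sum to 100 (got ",
         paste(signif(tot[abs(tot - 100) > 1e-9], 10), collapse = ", "), ")")
  df
}

#' Six-level crystalline/amorphous calibration compositions
#'
#' The standard calibration design at a fixed 20% w/w drug load: crystalline
#' drug at 20, 16, 12, 8, 4, 0% w/w against the complementary amorphous
#' fraction, with 77% w/w polymer and 3% w/w colourant throughout.
#'
#' @param polymerGrade Polymer grade label recorded in the design.
#' @return A 6-row `data.frame` (`Cal1` ... `Cal6`).
#' @export
calibrationCompositions <- function(polymerGrade = "HPC_L") {
  cryst <- seq(20, 0, by = -4)
  mixtureComposition(sprintf("Cal%d", 1:6),
                     crystalline = cryst, amorphous = 20 - cryst,
                     polymerGrade = polymerGrade)
}
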