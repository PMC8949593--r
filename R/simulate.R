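#' Noise model for simulated spectra
#'
#' @param additiveSd SD of i.i.d. additive detector noise (intensity units).
#' @param multiplicativeSd Log-scale SD of the per-spectrum multiplicative
#'   scatter factor `exp(N(0, sd^2))` (dimensionless).
#' @param baselineOffsetSd SD of the random constant baseline offset
#'   (intensity units).
#' @param baselineSlopeSd SD of the random linear baseline tilt, expressed
#'   as the intensity change from the axis midpoint to either end.
#' @param discExtraScatter Multiplier applied to `multiplicativeSd` when the
#'   presentation is `PRINTED_DISC` (sintered surfaces scatter more
#'   variably than powders).
#' @return A list of class `NoiseModel`.
#' @export
noiseModel <- function(additiveSd = 0.002, multiplicativeSd = 0.05,
                       baselineOffsetSd = 0.02, baselineSlopeSd = 0.01,
                       discExtraScatter = 1.5) {
  stopifnot(additiveSd >= 0, multiplicativeSd >= 0, baselineOffsetSd >= 0,
            baselineSlopeSd >= 0, discExtraScatter >= 0)
  structure(list(additive_sd = additiveSd,
                 multiplicative_sd = multiplicativeSd,
                 baseline_offset_sd = baselineOffsetSd,
                 baseline_slope_sd = baselineSlopeSd,
                 disc_extra_scatter = discExtraScatter),
            class = "NoiseModel")
}

#' Default acquisition grid per modality
#'
#' NIR: 3600 to 12496 cm^-1 on a uniform 8 cm^-1 grid anchored at 3600
#' (FT-NIR reflectance acquisition window). Raman: 100 to 2000 cm^-1 at
#' 1 cm^-1 steps.
#'
#' @param modality `"NIR"` or `"RAMAN"`.
#' @return Ascending numeric axis.
#' @export
defaultGrid <- function(modality) {
  modality <- match.arg(modality, .MODALITIES)
  if (modality == "NIR") seq(3600, 12500, by = 8) else seq(100, 2000, by = 1)
}

#' Simulation configuration
#'
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param grid Strictly ascending uniform axis; defaults to
#'   [defaultGrid()] for the modality.
#' @param signatures Named list of component signatures
#'   ([defaultSignatures()] by default).
#' @param noise A [noiseModel()].
#' @param replicatesPerSample Scan positions recorded per sample (>= 1).
#' @param seed Integer seed consumed by the generators.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(modality, grid = defaultGrid(modality),
                             signatures = defaultSignatures(modality),
                             noise = noiseModel(),
                             replicatesPerSample = 3L, seed = 1L) {
  modality <- match.arg(modality, .MODALITIES)
  grid <- as.numeric(grid)
  d <- diff(grid)
  if (any(d <= 0) || max(abs(d - d[1L])) > 1e-9 * abs(d[1L]))
    stop("grid must be strictly ascending with uniform step")
  stopifnot(replicatesPerSample >= 1L, inherits(noise, "NoiseModel"))
  if (!all(.COMPONENTS %in% names(signatures)))
    stop("signatures must name all of ", paste(.COMPONENTS, collapse = ", "))
  structure(list(modality = modality, grid = grid, signatures = signatures,
                 noise = noise,
                 replicates_per_sample = as.integer(replicatesPerSample),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate one position spectrum of a mixture
#'
#' The noiseless core is the mass-fraction-weighted sum of the rendered
#' component signatures (linear mixing with equal per-component scattering
#' efficiency); the amorphous fraction thereby also scales the water band
#' (NIR) and fluorescence background (Raman) carried by the amorphous
#' signature. The core is then multiplied by a log-normal scatter factor
#' (inflated by `disc_extra_scatter` for printed discs), tilted by a random
#' linear baseline, and perturbed by additive noise. Randomness is drawn
#' from R's current RNG stream: seed the stream (or use the seeded
#' generators) for reproducibility.
#'
#' @param comp One-row composition `data.frame` (see [mixtureComposition()]).
#' @param cfg A [simulationConfig()].
#' @param presentation Sample presentation; `"PRINTED_DISC"` activates the
#'   extra scatter term.
#' @return Numeric intensity vector on `cfg$grid`.
#' @export
simulateMixture <- function(comp, cfg, presentation = "POWDER") {
  stopifnot(inherits(cfg, "SimulationConfig"))
  presentation <- match.arg(presentation, .PRESENTATIONS)
  comp <- as.data.frame(comp)
  stopifnot(nrow(comp) == 1L)
  frac <- c(CRYSTALLINE_DRUG = comp$crystalline, AMORPHOUS_DRUG = comp$amorphous,
            POLYMER = comp$polymer, COLOURANT = comp$colourant) / 100
  ax <- cfg$grid
  core <- numeric(length(ax))
  for (nm in .COMPONENTS)
    if (frac[[nm]] != 0)
      core <- core + frac[[nm]] * renderSignature(cfg$signatures[[nm]], ax)
  nz <- cfg$noise
  msd <- nz$multiplicative_sd *
    if (presentation == "PRINTED_DISC") nz$disc_extra_scatter else 1
  scatter <- if (msd > 0) exp(stats::rnorm(1L, 0, msd)) else 1
  offset <- if (nz$baseline_offset_sd > 0)
    stats::rnorm(1L, 0, nz$baseline_offset_sd) else 0
  slope <- if (nz$baseline_slope_sd > 0)
    stats::rnorm(1L, 0, nz$baseline_slope_sd) else 0
  mid <- (ax[1L] + ax[length(ax)]) / 2
  half <- (ax[length(ax)] - ax[1L]) / 2
  baseline <- offset + slope * (ax - mid) / half
  eps <- if (nz$additive_sd > 0)
    stats::rnorm(length(ax), 0, nz$additive_sd) else 0
  scatter * core + baseline + eps
}

.simulateSamples <- function(compdf, cfg, presentation) {
  nrep <- cfg$replicates_per_sample
  cols <- vector("list", nrow(compdf) * nrep)
  sid <- character(length(cols)); pid <- integer(length(cols))
  k <- 0L
  for (i in seq_len(nrow(compdf))) {
    for (r in seq_len(nrep)) {
      k <- k + 1L
      cols[[k]] <- simulateMixture(compdf[i, , drop = FALSE], cfg, presentation)
      sid[k] <- compdf$sample_id[i]
      pid[k] <- r
    }
  }
  SpectrumSet(cfg$grid, do.call(cbind, cols), cfg$modality,
              sampleId = sid, positionId = pid, presentation = presentation,
              composition = compdf)
}

#' Generate the six-level calibration design
#'
#' Instantiates the standard design — crystalline drug 20, 16, 12, 8, 4,
#' 0% w/w against the complementary amorphous fraction at a fixed 20% w/w
#' drug load, 77% polymer, 3% colourant — with `preparationsPerLevel`
#' independent preparations per level, simulates
#' `cfg$replicates_per_sample` position scans per preparation, averages the
#' positions ([averageReplicates()]), and holds out `nValidation` samples
#' (drawn without replacement, seeded by `cfg$seed`) for internal
#' validation. Defaults give 14 calibration and 4 validation samples.
#'
#' @param cfg A [simulationConfig()].
#' @param preparationsPerLevel Preparations per composition level.
#' @param nValidation Samples held out for internal validation
#'   (must be < total samples).
#' @param presentation Presentation of the calibration samples.
#' @param polymerGrade Grade recorded in the design metadata.
#' @return List with `calibration` and `validation` (replicate-averaged
#'   [SpectrumSet-class]s) and `compositions` (the full design table).
#' @export
generateCalibrationDesign <- function(cfg, preparationsPerLevel = 3L,
                                      nValidation = 4L,
                                      presentation = "POWDER",
                                      polymerGrade = "HPC_L") {
  stopifnot(inherits(cfg, "SimulationConfig"))
  nTot <- 6L * preparationsPerLevel
  if (nValidation >= nTot)
    stop("nValidation (", nValidation, ") must be smaller than the total ",
         "number of samples (", nTot, ")")
  base <- calibrationCompositions(polymerGrade)
  compdf <- base[rep(seq_len(6L), each = preparationsPerLevel), ]
  compdf$sample_id <- sprintf("%s_p%d", compdf$sample_id,
                              rep(seq_len(preparationsPerLevel), times = 6L))
  rownames(compdf) <- NULL
  set.seed(cfg$seed)
  all <- .simulateSamples(compdf, cfg, presentation)
  avg <- averageReplicates(all)
  valIds <- sample(compdf$sample_id, nValidation)
  isVal <- sampleIds(avg) %in% valIds
  list(calibration = avg[, !isVal], validation = avg[, isVal],
       compositions = compdf)
}

#' Generate printed-disc spectra with known amorphous conversion
#'
#' Emulates 3D-printed discs whose 20% w/w drug load is partially converted
#' to the amorphous form during sintering, with conversion depending on the
#' polymer grade (by default L > SL > SSL, echoing the higher conversion
#' seen with higher-molecular-weight polymer grades). True amorphous
#' content is `20 * conversion` % w/w and is retained in the metadata for
#' recovery testing. Disc presentation activates the extra scatter noise.
#'
#' @param cfg A [simulationConfig()].
#' @param conversions Named numeric vector in \[0, 1\]: fraction of the drug
#'   load converted per polymer grade. The default values are invented
#'   fixtures giving ~18.4/17.4/12.8% w/w amorphous for L/SL/SSL.
#' @param nDiscsPerGrade Discs per grade.
#' @param seed Seed; defaults to `cfg$seed + 1` so discs and calibration
#'   samples drawn from the same config use distinct noise streams.
#' @return A replicate-averaged [SpectrumSet-class] with ground-truth
#'   compositions attached.
#' @export
generateDiscSet <- function(cfg,
                            conversions = c(HPC_L = 0.92, HPC_SL = 0.87,
                                            HPC_SSL = 0.64),
                            nDiscsPerGrade = 3L, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            all(conversions >= 0 & conversions <= 1),
            all(names(conversions) %in% .POLYMER_GRADES))
  grades <- names(conversions)
  compdf <- do.call(rbind, lapply(grades, function(g) {
    amorph <- 20 * conversions[[g]]
    mixtureComposition(sprintf("%s-disc%d", g, seq_len(nDiscsPerGrade)),
                       crystalline = 20 - amorph, amorphous = amorph,
                       polymerGrade = g)
  }))
  set.seed(seed)
  all <- .simulateSamples(compdf, cfg, "PRINTED_DISC")
  averageReplicates(all)
}
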