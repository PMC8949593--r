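#' Peak and component-signature builders for the spectrum simulator
#'
#' `peakSpec()` describes a single band as a pseudo-Voigt profile
#' parameterized by center (cm^-1), full width at half maximum (cm^-1),
#' height, and a Gaussian/Lorentzian blend factor (`shapeMix = 0` pure
#' Gaussian, `1` pure Lorentzian). `componentSignature()` bundles the peak
#' list of one mixture component with its modality-specific background
#' terms: a fluorescence background (Raman only) and a bounded water
#' absorption band around 5000 cm^-1 (NIR only).
#'
#' @param center Peak center, cm^-1.
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param height Peak height at center (>= 0), arbitrary intensity units.
#' @param shapeMix Lorentzian fraction in \[0, 1\].
#' @return `peakSpec`: a one-row `data.frame`; rbind rows to build peak lists.
#' @export
peakSpec <- function(center, fwhm, height, shapeMix = 0) {
  stopifnot(all(fwhm > 0), all(height >= 0),
            all(shapeMix >= 0 & shapeMix <= 1))
  data.frame(center = center, fwhm = fwhm, height = height,
             shape_mix = shapeMix)
}

#' @rdname peakSpec
#' @param name Component: `"CRYSTALLINE_DRUG"`, `"AMORPHOUS_DRUG"`,
#'   `"POLYMER"` or `"COLOURANT"`.
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param peaks A peak `data.frame` from [peakSpec()] (possibly 0 rows).
#' @param fluorescenceAmplitude Raman fluorescence background amplitude at
#'   zero shift (>= 0; must be 0 for NIR signatures).
#' @param waterBandAmplitude NIR water-band amplitude (>= 0; must be 0 for
#'   Raman signatures).
#' @export
componentSignature <- function(name, modality, peaks = peakSpec(0, 1, 0)[0, ],
                               fluorescenceAmplitude = 0,
                               waterBandAmplitude = 0) {
  name <- match.arg(name, .COMPONENTS)
  modality <- match.arg(modality, .MODALITIES)
  stopifnot(fluorescenceAmplitude >= 0, waterBandAmplitude >= 0)
  if (modality == "NIR" && fluorescenceAmplitude != 0)
    stop("NIR signatures must have fluorescenceAmplitude = 0")
  if (modality == "RAMAN" && waterBandAmplitude != 0)
    stop("Raman signatures must have waterBandAmplitude = 0")
  structure(list(name = name, modality = modality, peaks = peaks,
                 fluorescence_amplitude = fluorescenceAmplitude,
                 water_band_amplitude = waterBandAmplitude),
            class = "ComponentSignature")
}

## Raman fluorescence decay constant (cm^-1) and NIR water-band geometry.
.FLUOR_TAU <- 600
.WATER_CENTER <- 5000
.WATER_FWHM <- 300
.WATER_SUPPORT <- c(4600, 5400)

.pseudoVoigt <- function(axis, center, fwhm, height, shapeMix) {
  u <- (axis - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  height * ((1 - shapeMix) * g + shapeMix * l)
}

#' Render a component signature on a wavenumber axis
#'
#' The rendered curve is the sum of the signature's pseudo-Voigt peaks plus,
#' for Raman, a fluorescence background `A * exp(-shift / 600)` and, for
#' NIR, a broad Gaussian water band centered at 5000 cm^-1 (FWHM 300 cm^-1)
#' truncated to zero outside 4600-5400 cm^-1. All values are >= 0.
#'
#' @param sig A [componentSignature()].
#' @param axis Ascending numeric wavenumber axis (cm^-1).
#' @return Numeric intensity vector, same length as `axis`.
#' @export
renderSignature <- function(sig, axis) {
  stopifnot(inherits(sig, "ComponentSignature"), !is.unsorted(axis))
  y <- numeric(length(axis))
  pk <- sig$peaks
  for (i in seq_len(nrow(pk)))
    y <- y + .pseudoVoigt(axis, pk$center[i], pk$fwhm[i], pk$height[i],
                          pk$shape_mix[i])
  if (sig$fluorescence_amplitude > 0)
    y <- y + sig$fluorescence_amplitude * exp(-axis / .FLUOR_TAU)
  if (sig$water_band_amplitude > 0) {
    wb <- .pseudoVoigt(axis, .WATER_CENTER, .WATER_FWHM,
                       sig$water_band_amplitude, 0)
    wb[axis < .WATER_SUPPORT[1L] | axis > .WATER_SUPPORT[2L]] <- 0
    y <- y + wb
  }
  y
}

#' Default component signatures for the mixture simulator
#'
#' Encodes the solid-state spectral contrasts between crystalline and
#' amorphous drug. NIR: the crystalline drug shows the resolved C-H
#' first-overtone double peak at 5800/5900 cm^-1; the amorphous form
#' collapses it into a single broader, taller band shifted to 5775 cm^-1
#' and adds a water band near 5000 cm^-1 (the amorphous form is the more
#' hygroscopic). Raman: the crystalline drug has sharp rings ridden by the
#' nu(C=C) marker at 1618 cm^-1; the amorphous form keeps the same centers
#' but at >= 2.5x the width and 0.4x the height, over a stronger
#' fluorescence background. The polymer contributes broad low-intensity
#' features and the colourant a near-flat offset.
#'
#' Peak centers 5775/5800/5900 and 1618 cm^-1 (and the ~5000 cm^-1 water
#' band) are literature-anchored; all heights, widths and background
#' amplitudes are invented fixture defaults chosen to look like plausible
#' pharmaceutical spectra, and are freely overridable via
#' [simulationConfig()].
#'
#' @param modality `"NIR"` or `"RAMAN"`.
#' @return Named list of [componentSignature()] objects, one per component.
#' @export
defaultSignatures <- function(modality) {
  modality <- match.arg(modality, .MODALITIES)
  if (modality == "NIR") {
    list(
      CRYSTALLINE_DRUG = componentSignature(
        "CRYSTALLINE_DRUG", "NIR",
        rbind(peakSpec(5800, 40, 1.00, 0.3),
              peakSpec(5900, 40, 0.85, 0.3),
              peakSpec(4350, 70, 0.50, 0.3),
              peakSpec(6100, 90, 0.25, 0.3))),
      AMORPHOUS_DRUG = componentSignature(
        "AMORPHOUS_DRUG", "NIR",
        rbind(peakSpec(5775, 120, 1.35, 0.3),
              peakSpec(4350, 110, 0.45, 0.3),
              peakSpec(6100, 150, 0.20, 0.3)),
        waterBandAmplitude = 0.5),
      POLYMER = componentSignature(
        "POLYMER", "NIR",
        rbind(peakSpec(4250, 150, 0.18, 0.2),
              peakSpec(4750, 200, 0.15, 0.2),
              peakSpec(5600, 250, 0.12, 0.2),
              peakSpec(6900, 300, 0.20, 0.2),
              peakSpec(8300, 400, 0.10, 0.2))),
      COLOURANT = componentSignature(
        "COLOURANT", "NIR",
        peakSpec(8000, 20000, 0.05, 0)))
  } else {
    cryst <- rbind(
      peakSpec(1618, 8, 1.00, 0.7),
      peakSpec(1550, 8, 0.40, 0.7),
      peakSpec(1450, 9, 0.35, 0.7),
      peakSpec(1380, 8, 0.30, 0.7),
      peakSpec(1228, 8, 0.35, 0.7),
      peakSpec(1140, 9, 0.30, 0.7),
      peakSpec(1040, 8, 0.25, 0.7),
      peakSpec(740, 9, 0.30, 0.7),
      peakSpec(680, 8, 0.25, 0.7),
      peakSpec(520, 10, 0.20, 0.7))
    amorph <- cryst
    amorph$fwhm <- cryst$fwhm * 2.5
    amorph$height <- cryst$height * 0.4
    list(
      CRYSTALLINE_DRUG = componentSignature("CRYSTALLINE_DRUG", "RAMAN", cryst),
      AMORPHOUS_DRUG = componentSignature("AMORPHOUS_DRUG", "RAMAN", amorph,
                                          fluorescenceAmplitude = 0.6),
      POLYMER = componentSignature(
        "POLYMER", "RAMAN",
        rbind(peakSpec(900, 60, 0.08, 0.3),
              peakSpec(1120, 70, 0.10, 0.3),
              peakSpec(1370, 80, 0.08, 0.3),
              peakSpec(1460, 60, 0.06, 0.3))),
      COLOURANT = componentSignature(
        "COLOURANT", "RAMAN",
        peakSpec(1000, 20000, 0.03, 0)))
  }
}
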