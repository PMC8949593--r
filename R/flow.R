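#' Powder flow indices: densities, compressibility index, Hausner ratio
#'
#' Bulk density is `mass / bulk volume` and tapped density
#' `mass / tapped volume` (g/mL). The compressibility (Carr) index is
#' `CI = 100 * (rho_t - rho_b) / rho_t` (%), and the Hausner ratio
#' `HR = rho_t / rho_b`; the two are linked by `CI = 100 * (1 - 1/HR)`.
#' Tapping cannot decrease density, so `rho_t < rho_b` is rejected.
#'
#' @param mass Powder mass, g (> 0).
#' @param volume,bulkVolume,tappedVolume Volumes, mL (> 0; tapped <= bulk).
#' @param rhoB,rhoT Bulk and tapped density, g/mL.
#' @return Numeric value(s) of the respective quantity.
#' @examples
#' bulkDensity(3.9, 10)        # 0.39 g/mL
#' carrIndex(0.26, 0.52)       # 50 %
#' hausnerRatio(0.26, 0.52)    # 2.00
#' @export
bulkDensity <- function(mass, volume) {
  if (any(mass <= 0)) stop("mass must be > 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  mass / volume
}

#' @rdname bulkDensity
#' @export
tappedDensity <- function(mass, volume) bulkDensity(mass, volume)

#' @rdname bulkDensity
#' @export
carrIndex <- function(rhoB, rhoT) {
  if (any(rhoB <= 0)) stop("bulk density must be > 0")
  if (any(rhoT < rhoB))
    stop("tapped density below bulk density: tapping cannot decrease density")
  100 * (rhoT - rhoB) / rhoT
}

#' @rdname bulkDensity
#' @export
hausnerRatio <- function(rhoB, rhoT) {
  if (any(rhoB <= 0)) stop("bulk density must be > 0")
  rhoT / rhoB
}

.FLOW_CLASSES <- c("EXCELLENT", "GOOD", "FAIR", "PASSABLE", "POOR",
                   "VERY_POOR")
## CI band lower bounds (half-open bands, upper class from 32 up)
.FLOW_BREAKS <- c(0, 11, 16, 21, 26, 32)

#' Classify powder flow from the compressibility index
#'
#' Pharmacopoeial-style bands on CI (%) with half-open boundaries:
#' \[0, 11) excellent, \[11, 16) good, \[16, 21) fair, \[21, 26) passable,
#' \[26, 32) poor, \[32, Inf) very poor. The companion Hausner-ratio bands
#' (e.g. 1.26-1.34 passable, 1.35-1.45 poor) are informational; the class
#' is keyed on CI.
#'
#' @param ci Compressibility index (%), >= 0.
#' @return Character vector of flow classes (severity-ordered factor levels
#'   in `levels()`).
#' @examples
#' classifyFlow(c(23.8, 28.6, 36, 50))
#' @export
classifyFlow <- function(ci) {
  if (any(ci < 0)) stop("compressibility index must be >= 0")
  idx <- findInterval(ci, .FLOW_BREAKS)
  factor(.FLOW_CLASSES[idx], levels = .FLOW_CLASSES)
}

#' Summarize replicate powder-flow measurements
#'
#' Computes the flow indices per replicate first and then averages
#' (mean of ratios, with n - 1 standard deviations), matching how
#' replicate SDs of ratio quantities arise in routine powder
#' characterization. The flow class is assigned from the mean CI. Note the
#' mean of per-replicate ratios generally differs from the ratio of mean
#' densities; both conventions are well-defined, and this function commits
#' to the per-replicate one.
#'
#' @param measurements `data.frame` with columns `mass_g`,
#'   `bulk_volume_ml`, `tapped_volume_ml`, one row per replicate (>= 1).
#' @return A list of class `FlowIndices`: per-quantity `mean` and `sd`
#'   (`bulk_density`, `tapped_density`, `carr_index`, `hausner_ratio`),
#'   `n`, per-replicate table, and `flow_class`.
#' @examples
#' m <- data.frame(mass_g = c(3.9, 4.0, 3.8), bulk_volume_ml = 10,
#'                 tapped_volume_ml = c(7.4, 7.6, 7.5))
#' summarizeReplicates(m)
#' @export
summarizeReplicates <- function(measurements) {
  measurements <- as.data.frame(measurements)
  req <- c("mass_g", "bulk_volume_ml", "tapped_volume_ml")
  if (!all(req %in% colnames(measurements)))
    stop("measurements must have columns ", paste(req, collapse = ", "))
  if (nrow(measurements) < 1L) stop("need at least one replicate")
  if (any(measurements$tapped_volume_ml > measurements$bulk_volume_ml))
    stop("tapped volume cannot exceed bulk volume")
  rb <- bulkDensity(measurements$mass_g, measurements$bulk_volume_ml)
  rt <- tappedDensity(measurements$mass_g, measurements$tapped_volume_ml)
  ci <- carrIndex(rb, rt)
  hr <- hausnerRatio(rb, rt)
  sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
  per <- data.frame(replicate = seq_len(nrow(measurements)),
                    bulk_density = rb, tapped_density = rt,
                    carr_index = ci, hausner_ratio = hr)
  structure(list(
    n = nrow(per),
    bulk_density = c(mean = mean(rb), sd = sd0(rb)),
    tapped_density = c(mean = mean(rt), sd = sd0(rt)),
    carr_index = c(mean = mean(ci), sd = sd0(ci)),
    hausner_ratio = c(mean = mean(hr), sd = sd0(hr)),
    flow_class = as.character(classifyFlow(mean(ci))),
    replicates = per), class = "FlowIndices")
}

#' @export
print.FlowIndices <- function(x, ...) {
  cat(sprintf("Powder flow (n = %d replicates)\n", x$n))
  cat(sprintf("  bulk density   %.3f +/- %.3f g/mL\n",
              x$bulk_density["mean"], x$bulk_density["sd"]))
  cat(sprintf("  tapped density %.3f +/- %.3f g/mL\n",
              x$tapped_density["mean"], x$tapped_density["sd"]))
  cat(sprintf("  Carr index     %.1f +/- %.1f %%\n",
              x$carr_index["mean"], x$carr_index["sd"]))
  cat(sprintf("  Hausner ratio  %.2f +/- %.2f\n",
              x$hausner_ratio["mean"], x$hausner_ratio["sd"]))
  cat(sprintf("  flow class     %s\n", x$flow_class))
  invisible(x)
}
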