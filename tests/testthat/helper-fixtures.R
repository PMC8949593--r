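# small in-code fixtures shared across test files

# a tiny Raman-range set: ns spectra of np points on a unit grid
tinySet <- function(ns = 3L, np = 50L, seed = 42L, sampleId = NULL,
                    positionId = NULL) {
  set.seed(seed)
  wn <- seq(1000, by = 1, length.out = np)
  m <- matrix(rnorm(np * ns), np, ns)
  SpectrumSet(wn, m, "RAMAN",
              sampleId = sampleId %||% paste0("s", seq_len(ns)),
              positionId = positionId)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noise-free simulation config (deterministic spectra)
quietConfig <- function(modality, seed = 1L, ...) {
  simulationConfig(modality,
                   noise = noiseModel(additiveSd = 0, multiplicativeSd = 0,
                                      baselineOffsetSd = 0,
                                      baselineSlopeSd = 0),
                   seed = seed, ...)
}

trapzOracle <- function(x, y) {
  # independent quadrature: explicit panel loop
  a <- 0
  for (i in seq_len(length(x) - 1L))
    a <- a + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  a
}
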