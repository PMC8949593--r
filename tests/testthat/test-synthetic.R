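test_that("pseudo-Voigt rendering honours height, FWHM and the blend definition", {
  ax <- seq(980, 1060, by = 0.5)
  # no peaks, no background -> all zero
  empty <- componentSignature("POLYMER", "RAMAN")
  expect_equal(renderSignature(empty, ax), numeric(length(ax)))

  # pure Gaussian: height at center, half height at center +/- FWHM/2
  g <- componentSignature("CRYSTALLINE_DRUG", "RAMAN",
                          peakSpec(1020, 10, 2.0, shapeMix = 0))
  y <- renderSignature(g, ax)
  expect_equal(y[ax == 1020], 2.0)
  expect_equal(y[ax == 1015], 1.0, tolerance = 1e-12)
  expect_equal(y[ax == 1025], 1.0, tolerance = 1e-12)

  # blend 0.5 equals the closed-form mixture, evaluated independently
  v <- componentSignature("CRYSTALLINE_DRUG", "RAMAN",
                          peakSpec(1020, 10, 2.0, shapeMix = 0.5))
  u <- (ax - 1020) / 10
  gauss <- 2.0 * exp(-4 * log(2) * u^2)
  lorentz <- 2.0 / (1 + 4 * u^2)
  expect_equal(renderSignature(v, ax), 0.5 * gauss + 0.5 * lorentz,
               tolerance = 1e-12)
})

test_that("signature constraints reject cross-modality backgrounds", {
  expect_error(componentSignature("POLYMER", "NIR", fluorescenceAmplitude = 1),
               "fluorescenceAmplitude")
  expect_error(componentSignature("POLYMER", "RAMAN", waterBandAmplitude = 1),
               "waterBandAmplitude")
})

test_that("default signatures encode the crystalline/amorphous solid-state contrast", {
  grid <- defaultGrid("NIR")
  sigs <- defaultSignatures("NIR")
  # crystalline C-H first overtone: two resolved maxima in 5700-5900
  y <- renderSignature(sigs$CRYSTALLINE_DRUG, grid)
  win <- grid >= 5700 & grid <= 6000
  yw <- y[win]
  locmax <- which(diff(sign(diff(yw))) == -2) + 1L
  expect_gte(length(locmax), 2L)
  # amorphous: single broad band at 5775, taller there than the crystalline curve
  ya <- renderSignature(sigs$AMORPHOUS_DRUG, grid)
  at <- which.min(abs(grid - 5775))
  expect_gt(ya[at], y[at])
  # water band: present for amorphous, zero outside its bounded support
  expect_gt(sigs$AMORPHOUS_DRUG$water_band_amplitude, 0)
  outside <- grid < 4600 | grid > 5400
  nowater <- sigs$AMORPHOUS_DRUG
  nowater$peaks <- nowater$peaks[0, ]
  wb <- renderSignature(nowater, grid)
  expect_true(all(wb[outside] == 0))
  expect_gt(max(wb[!outside]), 0)

  rsigs <- defaultSignatures("RAMAN")
  rax <- defaultGrid("RAMAN")
  # amorphous peaks share centers, >= 2x width, <= 0.5x height
  expect_equal(rsigs$AMORPHOUS_DRUG$peaks$center,
               rsigs$CRYSTALLINE_DRUG$peaks$center)
  expect_true(all(rsigs$AMORPHOUS_DRUG$peaks$fwhm >=
                  2 * rsigs$CRYSTALLINE_DRUG$peaks$fwhm))
  expect_true(all(rsigs$AMORPHOUS_DRUG$peaks$height <=
                  0.5 * rsigs$CRYSTALLINE_DRUG$peaks$height))
  # the nu(C=C) marker band loses intensity on amorphization
  yc <- renderSignature(rsigs$CRYSTALLINE_DRUG, rax)
  ya <- renderSignature(rsigs$AMORPHOUS_DRUG, rax)
  at <- which(rax == 1618)
  expect_lt(ya[at] - rsigs$AMORPHOUS_DRUG$fluorescence_amplitude *
              exp(-1618 / 600), yc[at])
  expect_gt(rsigs$AMORPHOUS_DRUG$fluorescence_amplitude, 0)
  expect_equal(rsigs$CRYSTALLINE_DRUG$fluorescence_amplitude, 0)
})

test_that("noise-free simulation is exactly linear in composition", {
  cfg <- quietConfig("NIR")
  c1 <- mixtureComposition("a", crystalline = 20, amorphous = 0)
  c2 <- mixtureComposition("b", crystalline = 0, amorphous = 20)
  y1 <- simulateMixture(c1, cfg)
  y2 <- simulateMixture(c2, cfg)
  for (al in c(0.25, 0.5, 0.75)) {
    cm <- mixtureComposition("m", crystalline = 20 * al,
                             amorphous = 20 * (1 - al))
    expect_equal(simulateMixture(cm, cfg), al * y1 + (1 - al) * y2,
                 tolerance = 1e-12)
  }
  # pure polymer reproduces the polymer signature exactly
  cp <- mixtureComposition("p", crystalline = 0, amorphous = 0,
                           polymer = 100, colourant = 0)
  expect_equal(simulateMixture(cp, cfg),
               renderSignature(cfg$signatures$POLYMER, cfg$grid),
               tolerance = 1e-14)
})

test_that("seeding contract: same seed bit-identical, different seeds distinct", {
  cfg <- simulationConfig("RAMAN", seed = 3L)
  comp <- mixtureComposition("a", crystalline = 10, amorphous = 10)
  set.seed(99); y1 <- simulateMixture(comp, cfg)
  set.seed(99); y2 <- simulateMixture(comp, cfg)
  set.seed(100); y3 <- simulateMixture(comp, cfg)
  expect_identical(y1, y2)
  expect_false(identical(y1, y3))

  d1 <- generateCalibrationDesign(simulationConfig("NIR", seed = 5L))
  d2 <- generateCalibrationDesign(simulationConfig("NIR", seed = 5L))
  expect_identical(intensityMatrix(d1$calibration),
                   intensityMatrix(d2$calibration))
})

test_that("the calibration design yields 14 calibration + 4 validation samples", {
  d <- generateCalibrationDesign(simulationConfig("NIR", seed = 2L))
  expect_equal(ncol(d$calibration), 14L)
  expect_equal(ncol(d$validation), 4L)
  ids <- c(sampleIds(d$calibration), sampleIds(d$validation))
  expect_length(unique(ids), 18L)
  expect_length(intersect(sampleIds(d$calibration),
                          sampleIds(d$validation)), 0L)
  # compositions: 6 levels x 3 preparations, each summing to 100
  comp <- d$compositions
  expect_equal(nrow(comp), 18L)
  expect_true(all(abs(comp$crystalline + comp$amorphous +
                      comp$polymer + comp$colourant - 100) < 1e-9))
  expect_true(all(comp$polymer == 77))
  expect_true(all(comp$colourant == 3))
  expect_equal(sort(unique(comp$crystalline)), c(0, 4, 8, 12, 16, 20))
  expect_equal(comp$amorphous, 20 - comp$crystalline)
  # replicate averaging applied: single position-0 spectrum per sample
  expect_true(all(positionIds(d$calibration) == 0L))
  expect_error(generateCalibrationDesign(simulationConfig("NIR"),
                                         nValidation = 18L),
               "smaller than")
})

test_that("disc sets carry the conversion-derived ground truth", {
  cfg <- quietConfig("RAMAN", seed = 4L)
  d <- generateDiscSet(cfg, conversions = c(HPC_L = 1.0), nDiscsPerGrade = 2L)
  expect_true(all(compositions(d)$amorphous == 20))
  d2 <- generateDiscSet(cfg, conversions = c(HPC_L = 0.92, HPC_SL = 0.87,
                                             HPC_SSL = 0.64))
  comp <- compositions(d2)
  truth <- tapply(comp$amorphous, comp$polymer_grade, unique)
  expect_true(truth[["HPC_L"]] > truth[["HPC_SL"]])
  expect_true(truth[["HPC_SL"]] > truth[["HPC_SSL"]])
  expect_true(all(presentations(d2) == "PRINTED_DISC"))
})

test_that("the Raman marker band decreases monotonically with amorphous fraction", {
  cfg <- quietConfig("RAMAN")
  at <- cfg$grid >= 1614 & cfg$grid <= 1618
  heights <- vapply(seq(0, 20, by = 4), function(am) {
    comp <- mixtureComposition("x", crystalline = 20 - am, amorphous = am)
    mean(simulateMixture(comp, cfg)[at])
  }, numeric(1))
  expect_true(all(diff(heights) < 0))
})
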