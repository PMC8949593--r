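#' Run an end-to-end calibration
#'
#' Orchestrates the full modelling workflow for one modality: obtain
#' calibration and internal-validation spectra (either simulated from a
#' [simulationConfig()] or supplied directly), average replicate positions,
#' fit the modality's preprocessing chain on the calibration set only,
#' select the latent-variable count by leave-one-out cross-validation,
#' refit, compute calibration / cross-validation / prediction metrics, and
#' build the 95% score-space admissibility ellipse from the calibration
#' scores. Validation spectra never enter chain fitting or LOOCV folds.
#'
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param simConfig A [simulationConfig()] (exclusive with
#'   `calibration`/`validation`).
#' @param calibration,validation [SpectrumSet-class]s with composition
#'   metadata (exclusive with `simConfig`).
#' @param chain A [preprocessChain()]; defaults to the modality's preset.
#' @param maxLV Largest LV count evaluated by LOOCV (capped at n - 2).
#' @param alpha Ellipse significance level (default 0.05).
#' @return A `CalibrationRun` list: `model` ([PLSModel-class]), `diagModel`
#'   (>= 2 LVs, used for score plots), `cv`, `report` (the
#'   `ValidationReport`), `ellipse`, `chainState`, the input sets, and the
#'   processed calibration set.
#' @export
runCalibration <- function(modality, simConfig = NULL, calibration = NULL,
                           validation = NULL, chain = NULL, maxLV = 6L,
                           alpha = 0.05) {
  modality <- match.arg(modality, .MODALITIES)
  if (is.null(simConfig) == is.null(calibration))
    stop("provide exactly one of simConfig or calibration/validation sets")
  if (!is.null(simConfig)) {
    stopifnot(identical(simConfig$modality, modality))
    design <- generateCalibrationDesign(simConfig)
    cal <- design$calibration
    val <- design$validation
  } else {
    cal <- averageReplicates(calibration)
    val <- if (!is.null(validation)) averageReplicates(validation)
  }
  if (is.null(chain))
    chain <- if (modality == "NIR") nirDefaultChain() else ramanDefaultChain()
  fc <- fitChain(cal, chain)
  comp <- compositions(cal)
  if (is.null(comp) || !"amorphous" %in% colnames(comp))
    stop("calibration set must carry composition metadata (amorphous % w/w)")
  y <- comp$amorphous[match(sampleIds(fc$set), comp$sample_id)]
  X <- t(intensityMatrix(fc$set))
  n <- nrow(X)
  maxLV <- min(as.integer(maxLV), n - 2L)
  cv <- loocv(X, y, maxLV)
  model <- fitPLS(X, y, cv$selected_n_lv, wavenumber = wavenumbers(fc$set),
                  chainState = fc$state)
  diagModel <- if (model@nLV >= 2L) model else
    fitPLS(X, y, 2L, wavenumber = wavenumbers(fc$set), chainState = fc$state)
  calMetrics <- validationMetrics(y, predict(model, X), "CAL")
  predMetrics <- NULL
  if (!is.null(val) && ncol(val) > 0L) {
    vcomp <- compositions(val)
    yv <- vcomp$amorphous[match(sampleIds(val), vcomp$sample_id)]
    pv <- predict(model, applyChain(val, fc$state))
    predMetrics <- validationMetrics(yv, pv, "PRED")
  }
  ellipse <- hotellingEllipse(diagModel, alpha = alpha)
  report <- structure(list(
    r2_cal = calMetrics$r2,
    r2_pred = if (!is.null(predMetrics)) predMetrics$r2 else NA_real_,
    rmsec = calMetrics$rmse,
    rmsecv = cv$rmsecv_by_nlv[cv$selected_n_lv],
    rmsep = if (!is.null(predMetrics)) predMetrics$rmse else NA_real_,
    lv1_percent_x_variance = model@xVarExplained[1L],
    bias = if (!is.null(predMetrics)) predMetrics$bias else NA_real_),
    class = "ValidationReport")
  structure(list(modality = modality, model = model, diagModel = diagModel,
                 cv = cv, report = report, ellipse = ellipse,
                 chainState = fc$state, calibration = cal, validation = val,
                 processedCalibration = fc$set, alpha = alpha,
                 seed = if (!is.null(simConfig)) simConfig$seed else NA_integer_),
            class = "CalibrationRun")
}

#' Predict amorphous content of new samples (e.g. printed discs)
#'
#' Averages replicate positions, replays the run's frozen preprocessing
#' chain, predicts per sample, and flags each sample by the run's 95%
#' score-space ellipse (LV1 vs LV2). When the samples carry a
#' `polymer_grade`, predictions are also summarized per grade as
#' mean +/- sd, ordered by decreasing predicted amorphous content.
#'
#' @param run A `CalibrationRun` from [runCalibration()].
#' @param spectra A [SpectrumSet-class] of new samples on the acquisition
#'   axis used for calibration.
#' @return List with `records` (one row per sample: prediction, T-squared,
#'   ellipse membership, ground truth if available) and `byGrade`
#'   (per-grade mean +/- sd, or `NULL`).
#' @export
runPrediction <- function(run, spectra) {
  stopifnot(inherits(run, "CalibrationRun"))
  avg <- averageReplicates(spectra)
  proc <- applyChain(avg, run$chainState)
  pred <- predict(run$model, proc)
  sc <- projectScores(run$diagModel, proc)[, run$ellipse$lv_pair, drop = FALSE]
  t2 <- t2Statistic(run$ellipse, sc)
  cd <- as.data.frame(colData(avg))
  records <- data.frame(sample_id = cd$sample_id,
                        presentation = cd$presentation,
                        predicted_amorphous = as.numeric(pred),
                        t2 = as.numeric(t2),
                        inside_95_ellipse = as.numeric(t2) <= run$ellipse$t2_limit,
                        stringsAsFactors = FALSE)
  if ("amorphous" %in% colnames(cd))
    records$true_amorphous <- cd$amorphous
  if ("polymer_grade" %in% colnames(cd))
    records$polymer_grade <- cd$polymer_grade
  byGrade <- NULL
  if ("polymer_grade" %in% colnames(records)) {
    sp <- split(records$predicted_amorphous, records$polymer_grade)
    byGrade <- data.frame(
      polymer_grade = names(sp),
      n = vapply(sp, length, integer(1)),
      predicted_amorphous_mean = vapply(sp, mean, numeric(1)),
      predicted_amorphous_sd = vapply(sp, function(v)
        if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
      stringsAsFactors = FALSE)
    if ("true_amorphous" %in% colnames(records))
      byGrade$true_amorphous <- vapply(split(records$true_amorphous,
                                             records$polymer_grade),
                                       mean, numeric(1))
    byGrade <- byGrade[order(-byGrade$predicted_amorphous_mean), ]
    rownames(byGrade) <- NULL
  }
  list(records = records, byGrade = byGrade)
}

#' ICH-style validation report
#'
#' Assembles the validation summary of a calibration run under the
#' ICH Q2(R1) headings: specificity (share of spectral variance captured
#' by LV1), linearity (R-squared over the 0-20% w/w calibration range),
#' accuracy (RMSEC / RMSECV / RMSEP and bias), plus the latent-variable
#' selection trace and the score-ellipse parameters. [writeIchReport()]
#' serializes it to JSON deterministically (byte-identical for identical
#' runs); [validateIchReport()] checks a report against the shipped field
#' schema.
#'
#' @param run A `CalibrationRun`.
#' @return A list of class `IchReport`.
#' @export
ichReport <- function(run) {
  stopifnot(inherits(run, "CalibrationRun"))
  stepNames <- vapply(run$chainState$chain$steps, `[[`, character(1), "name")
  structure(list(
    method = list(modality = run$modality,
                  preprocessing = stepNames,
                  calibration_range_w_w = c(0, 20),
                  n_calibration = nrow(run$model@scores),
                  n_validation = if (!is.null(run$validation))
                    ncol(run$validation) else 0L,
                  seed = run$seed),
    specificity = list(
      lv1_percent_x_variance = run$report$lv1_percent_x_variance),
    linearity = list(r2_cal = run$report$r2_cal,
                     r2_pred = run$report$r2_pred,
                     calibration_range_w_w = c(0, 20)),
    accuracy = list(rmsec = run$report$rmsec, rmsecv = run$report$rmsecv,
                    rmsep = run$report$rmsep, bias = run$report$bias),
    lv_selection = list(rmsecv_by_nlv = run$cv$rmsecv_by_nlv,
                        selected_n_lv = run$cv$selected_n_lv,
                        selection_rule = run$cv$selection_rule),
    score_ellipse = list(alpha = run$ellipse$alpha,
                         t2_limit = run$ellipse$t2_limit,
                         lv_pair = run$ellipse$lv_pair,
                         n_cal = run$ellipse$n_cal)),
    class = "IchReport")
}

#' @rdname ichReport
#' @param report An `IchReport`.
#' @param path Output JSON path.
#' @export
writeIchReport <- function(report, path) {
  stopifnot(inherits(report, "IchReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname ichReport
#' @return `validateIchReport`: `TRUE` (invisibly) if the report carries
#'   every field required by the shipped schema; otherwise an error naming
#'   the missing fields.
#' @export
validateIchReport <- function(report) {
  schema <- jsonlite::read_json(
    system.file("extdata", "ich_report_schema.json", package = "AmorphQuant"),
    simplifyVector = TRUE)
  missing <- character()
  for (sect in names(schema$required)) {
    if (!sect %in% names(report)) {
      missing <- c(missing, sect)
      next
    }
    want <- schema$required[[sect]]
    have <- names(report[[sect]])
    missing <- c(missing, paste0(sect, ".", setdiff(want, have)))
  }
  missing <- missing[!endsWith(missing, ".")]
  if (length(missing))
    stop("report is missing required fields: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
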