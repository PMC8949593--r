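#' Read a set of spectra from CSV
#'
#' The expected layout is one header row; the first column is the wavenumber
#' axis (any header name), and every remaining column is one spectrum whose
#' header encodes sample and scan position as `"<sample_id>__<position>"`
#' (double underscore delimiter; a bare header is taken as position 1).
#' A descending axis (e.g. 12500 down to 3600) is accepted and normalized to
#' ascending, with intensities reversed consistently.
#'
#' @param path CSV file (comma separator, `.` decimal, header row).
#' @param modality `"NIR"` or `"RAMAN"`.
#' @param presentation Presentation recorded for all spectra in the file.
#' @param composition Optional composition `data.frame` (see
#'   [mixtureComposition()]) or path to a JSON sidecar readable by
#'   [readCompositionsJSON()].
#' @return A [SpectrumSet-class]; column order of the file is preserved.
#' @export
readSpectraCSV <- function(path, modality, presentation = "POWDER",
                           composition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) != 1L)
    stop("format error in ", path, ": rows have differing field counts (",
         paste(unique(nf), collapse = ", "), ")")
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (ncol(raw) < 2L) stop("format error: need an axis column plus >= 1 spectrum")
  num <- vector("list", ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !raw[[j]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                   raw[[j]][bad[1L]], bad[1L] + 1L, colnames(raw)[j]))
    num[[j]] <- v
  }
  wn <- num[[1L]]
  m <- do.call(cbind, num[-1L])
  hdr <- colnames(raw)[-1L]
  pos <- rep.int(1L, length(hdr))
  sid <- hdr
  has <- grepl("__[0-9]+$", hdr)
  pos[has] <- as.integer(sub("^__", "", regmatches(hdr, regexpr("__[0-9]+$", hdr))))
  sid[has] <- sub("__[0-9]+$", "", hdr[has])
  if (is.character(composition) && length(composition) == 1L)
    composition <- readCompositionsJSON(composition)
  SpectrumSet(wn, m, modality, sampleId = sid, positionId = pos,
              presentation = presentation, composition = composition)
}

#' Write a SpectrumSet to CSV
#'
#' Values are written at full double precision (17 significant digits) so
#' that a write/read round trip is value-identical to at least 15
#' significant digits.
#'
#' @param x A non-empty [SpectrumSet-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumSet"))
  if (ncol(x) == 0L) stop("cannot write an empty SpectrumSet")
  m <- intensityMatrix(x)
  hdr <- sprintf("%s__%d", sampleIds(x), positionIds(x))
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  lines <- c(paste(c("wavenumber", hdr), collapse = ","),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(fmt(wavenumbers(x)[i]), fmt(m[i, ])), collapse = ","),
               character(1)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Supports AFFN-encoded `##XYDATA=(X++(Y..Y))` and `##XYPOINTS=(XY..XY)`
#' records, honouring `XFACTOR`, `YFACTOR` and `FIRSTX`/`LASTX` ordering.
#' Compressed dialects (SQZ/DIF/DUP/PAC) are out of scope and raise an
#' unsupported-dialect error rather than being silently misread.
#'
#' @param path JCAMP-DX file.
#' @param modality `"NIR"` or `"RAMAN"`.
#' @return A one-spectrum [SpectrumSet-class]; the sample id is the file's
#'   `##TITLE` (or the file name if absent).
#' @export
readJCAMP <- function(path, modality) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    i <- grep(sprintf("^##%s\\s*=", name), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    sub(sprintf("^##%s\\s*=\\s*", name), "", lines[i[1L]], ignore.case = TRUE)
  }
  title <- ldr("TITLE")
  xf <- as.numeric(ldr("XFACTOR") %||% "1")
  yf <- as.numeric(ldr("YFACTOR") %||% "1")
  start <- grep("^##XYDATA|^##XYPOINTS", lines, ignore.case = TRUE)
  if (!length(start)) stop("no XYDATA or XYPOINTS record in ", path)
  kind <- if (grepl("^##XYDATA", lines[start[1L]], ignore.case = TRUE))
    "XYDATA" else "XYPOINTS"
  body <- lines[(start[1L] + 1L):length(lines)]
  endi <- grep("^##", body)
  if (length(endi)) body <- body[seq_len(endi[1L] - 1L)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  ## AFFN only: any alphabetic character signals SQZ/DIF/DUP compression
  if (any(grepl("[A-DF-Za-df-z@%]", body)))
    stop("unsupported JCAMP-DX dialect: compressed (SQZ/DIF/DUP) data are not supported; re-export as AFFN")
  toks <- function(s) as.numeric(strsplit(s, "[,;[:space:]]+")[[1]])
  if (kind == "XYPOINTS") {
    v <- unlist(lapply(body, toks))
    if (length(v) %% 2L != 0L) stop("malformed XYPOINTS record")
    wn <- v[seq(1L, length(v), by = 2L)] * xf
    y <- v[seq(2L, length(v), by = 2L)] * yf
  } else {
    wn <- numeric(0); y <- numeric(0)
    deltax <- as.numeric(ldr("DELTAX") %||% "NA")
    for (s in body) {
      v <- toks(s)
      if (length(v) < 2L) stop("malformed XYDATA line: ", s)
      x0 <- v[1L] * xf
      yy <- v[-1L] * yf
      if (is.na(deltax)) {
        firstx <- as.numeric(ldr("FIRSTX") %||% "NA")
        lastx <- as.numeric(ldr("LASTX") %||% "NA")
        npt <- as.numeric(ldr("NPOINTS") %||% "NA")
        if (anyNA(c(firstx, lastx, npt)))
          stop("XYDATA needs DELTAX or FIRSTX/LASTX/NPOINTS")
        deltax <- (lastx - firstx) / (npt - 1)
      }
      wn <- c(wn, x0 + deltax * (seq_along(yy) - 1L))
      y <- c(y, yy)
    }
  }
  SpectrumSet(wn, y, modality,
              sampleId = title %||% basename(path), positionId = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a composition metadata sidecar (JSON)
#'
#' The sidecar maps `sample_id` to its mixture composition:
#' `{"Cal1": {"crystalline": 20, "amorphous": 0, "polymer": 77,
#' "colourant": 3, "polymer_grade": "HPC_L", "presentation": "POWDER"}, ...}`.
#'
#' @param path JSON file.
#' @return `readCompositionsJSON`: a `data.frame` with one row per sample.
#' @export
readCompositionsJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- names(obj)
  df <- do.call(rbind, lapply(ids, function(id) {
    e <- obj[[id]]
    data.frame(sample_id = id,
               crystalline = as.numeric(e$crystalline),
               amorphous = as.numeric(e$amorphous),
               polymer = as.numeric(e$polymer),
               colourant = as.numeric(e$colourant),
               polymer_grade = as.character(e$polymer_grade %||% "HPC_L"),
               presentation = as.character(e$presentation %||% "POWDER"),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}

#' @rdname readCompositionsJSON
#' @param composition A composition `data.frame` (see [mixtureComposition()]),
#'   optionally with a `presentation` column.
#' @export
writeCompositionsJSON <- function(composition, path) {
  composition <- as.data.frame(composition)
  obj <- lapply(seq_len(nrow(composition)), function(i) {
    e <- as.list(composition[i, setdiff(colnames(composition), "sample_id")])
    e
  })
  names(obj) <- composition$sample_id
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
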