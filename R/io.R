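#' Read a concentration series from delimited text
#'
#' Expects a comma-delimited file with header
#' `time_min,value,unit,temperature_C`. Rows out of time order are
#' sorted with a warning; malformed cells raise errors naming the
#' offending line (header = line 1).
#'
#' @param path File path.
#' @return A [conc_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("time_min", "value", "unit", "temperature_C")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value %s on line %d of %s",
                   col, dQuote(raw[[col]][bad[1L]]), bad[1L] + 1L, path),
           call. = FALSE)
    x
  }
  tt <- num("time_min"); vv <- num("value")
  if (is.unsorted(tt, strictly = TRUE)) {
    o <- order(tt)
    if (anyDuplicated(tt))
      stop("duplicated time points in ", path, call. = FALSE)
    warning("rows of ", path, " were not in time order; sorted", call. = FALSE)
    tt <- tt[o]; vv <- vv[o]
  }
  unit <- unique(raw$unit)
  if (length(unit) != 1L)
    stop("column 'unit' must be constant within one series", call. = FALSE)
  conc_series(tt, vv, unit = unit,
              temperature_C = num("temperature_C")[1L],
              hydrolysis_run = tt[1L] == 0)
}

#' Write a concentration series as delimited text
#'
#' @param series A [conc_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "conc_series"))
  utils::write.csv(
    data.frame(time_min = series$time_min, value = series$value,
               unit = attr(series, "unit"),
               temperature_C = attr(series, "temperature_C")),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration table from delimited text
#'
#' Expects header `analyte,run,level_ug_mL,response`.
#'
#' @param path File path.
#' @return Data frame with columns `analyte`, `run`, `concentration`,
#'   `response`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, strip.white = TRUE)
  need <- c("analyte", "run", "level_ug_mL", "response")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("level_ug_mL", "response")) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
    if (length(bad))
      stop(sprintf("non-numeric '%s' on line %d of %s", col, bad[1L] + 1L, path),
           call. = FALSE)
  }
  data.frame(analyte = as.character(raw$analyte), run = raw$run,
             concentration = as.numeric(raw$level_ug_mL),
             response = as.numeric(raw$response))
}

#' Write a calibration table as delimited text
#'
#' @param table Data frame with columns `analyte`, `run`,
#'   `concentration`, `response` (as produced by
#'   [generate_calibration_set()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(table, path) {
  stopifnot(all(c("analyte", "run", "concentration", "response") %in%
                names(table)))
  utils::write.csv(
    data.frame(analyte = table$analyte, run = table$run,
               level_ug_mL = table$concentration, response = table$response),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a truth manifest
#'
#' JSON serialisation of the generating parameters of a synthetic study,
#' for parameter-recovery tests.
#'
#' @param truth Manifest list (from [generate_full_study()]).
#' @param path File path.
#' @return `write_truth_manifest`: `path` invisibly;
#'   `read_truth_manifest`: the manifest list.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
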