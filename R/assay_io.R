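# Tabular I/O: tidy dose-response and kinetics CSV readers, JSON reports.
#
# CSV dialect: comma-separated, UTF-8, mandatory header, long layout
# (one measurement per row). All concentrations are converted to molar
# and all times to seconds on read.

#' Read a tidy dose-response CSV
#'
#' Expected columns: `ligand,receptor,pathway,dose,signal` plus optional
#' `dose_unit` (default `"M"`) and `replicate` (default `"1"`). Each row is
#' one well/measurement. Rows with `dose = 0` are vehicle (basal) wells;
#' doses are otherwise required to be strictly positive.
#'
#' @param path CSV file path.
#' @param dose_unit fallback unit applied when the file has no
#'   `dose_unit` column.
#' @return A `dose_response_dataset`: a data frame with columns
#'   `ligand, receptor, pathway, dose` (molar), `signal, replicate`, with
#'   any remaining columns preserved as metadata in
#'   `attr(x, "metadata")`.
#' @export
read_dose_response_csv <- function(path, dose_unit = "M") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty dataset: ", path, call. = FALSE)
  required <- c("ligand", "receptor", "pathway", "dose", "signal")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("dose-response CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_numeric_column(raw, "dose", path)
  check_numeric_column(raw, "signal", path)
  unit <- if ("dose_unit" %in% names(raw)) raw$dose_unit else dose_unit
  dose_m <- conc_to_molar(raw$dose, unit)
  if (any(dose_m < 0)) {
    stop("negative dose at data row(s) ",
         paste(which(dose_m < 0), collapse = ", "), call. = FALSE)
  }
  replicate <- if ("replicate" %in% names(raw)) as.character(raw$replicate) else "1"
  out <- data.frame(
    ligand = as.character(raw$ligand),
    receptor = as.character(raw$receptor),
    pathway = as.character(raw$pathway),
    dose = dose_m,
    signal = as.numeric(raw$signal),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  key <- do.call(paste, c(out[c("ligand", "receptor", "pathway", "replicate")],
                          list(format(out$dose, digits = 15), sep = "\r")))
  if (anyDuplicated(key)) {
    stop("duplicate (ligand, receptor, pathway, dose, replicate) key at ",
         "data row(s) ", paste(which(duplicated(key)), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(raw), c(required, "dose_unit", "replicate"))
  attr(out, "metadata") <- if (length(extra)) raw[extra] else list()
  class(out) <- c("dose_response_dataset", "data.frame")
  out
}

check_numeric_column <- function(raw, col, path) {
  v <- raw[[col]]
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(trimws(v)))
    if (length(bad)) {
      stop("non-numeric `", col, "` at data row(s) ",
           paste(bad, collapse = ", "), " of ", path, call. = FALSE)
    }
    raw[[col]] <- num
  }
  if (anyNA(raw[[col]])) {
    stop("missing `", col, "` at data row(s) ",
         paste(which(is.na(raw[[col]])), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a tidy radioligand kinetics CSV
#'
#' Expected columns:
#' `trace_id,trace_type,competitor,competitor_conc,conc_unit,time,time_unit,signal`
#' (`conc_unit`/`time_unit` optional, defaulting to molar and seconds;
#' `competitor`/`competitor_conc` optional for pure association or
#' dissociation experiments). `trace_type` must be `"association"` or
#' `"dissociation"`.
#'
#' @param path CSV file path.
#' @return A `kinetic_dataset`: list of `kinetic_trace` objects, each a
#'   list with `trace_id`, `trace_type`, `competitor`,
#'   `competitor_conc` (molar), `time` (seconds, strictly increasing)
#'   and `signal`.
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("empty kinetics dataset: ", path, call. = FALSE)
  required <- c("trace_id", "trace_type", "time", "signal")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("kinetics CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(raw$trace_type), c("association", "dissociation"))
  if (length(bad_type)) {
    stop("unknown trace_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  check_numeric_column(raw, "time", path)
  check_numeric_column(raw, "signal", path)
  t_unit <- if ("time_unit" %in% names(raw)) raw$time_unit else "s"
  raw$time <- time_to_seconds(raw$time, t_unit)
  if (any(raw$time < 0)) {
    stop("negative time at data row(s) ",
         paste(which(raw$time < 0), collapse = ", "), call. = FALSE)
  }
  if ("competitor_conc" %in% names(raw)) {
    c_unit <- if ("conc_unit" %in% names(raw)) raw$conc_unit else "M"
    raw$competitor_conc <- conc_to_molar(raw$competitor_conc, c_unit)
  } else {
    raw$competitor_conc <- 0
  }
  if (!"competitor" %in% names(raw)) raw$competitor <- NA_character_
  traces <- lapply(split(raw, raw$trace_id), function(df) {
    df <- df[order(df$time), , drop = FALSE]
    if (anyDuplicated(df$time)) {
      stop("duplicate time points within trace `", df$trace_id[1], "`",
           call. = FALSE)
    }
    if (nrow(df) < 5L) {
      stop("trace `", df$trace_id[1], "` has fewer than 5 time points",
           call. = FALSE)
    }
    kinetic_trace(
      trace_id = df$trace_id[1], trace_type = df$trace_type[1],
      competitor = df$competitor[1], competitor_conc = df$competitor_conc[1],
      time = df$time, signal = as.numeric(df$signal)
    )
  })
  structure(unname(traces), class = "kinetic_dataset")
}

#' Construct a kinetic trace
#'
#' @param trace_id,trace_type,competitor,competitor_conc,time,signal see
#'   [read_kinetic_csv()] for field meanings; `time` in seconds,
#'   `competitor_conc` in molar.
#' @return A `kinetic_trace` object.
#' @export
kinetic_trace <- function(trace_id, trace_type, time, signal,
                          competitor = NA_character_, competitor_conc = 0) {
  stopifnot(trace_type %in% c("association", "dissociation"),
            length(time) == length(signal))
  if (is.unsorted(time, strictly = TRUE)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  if (any(time < 0)) stop("trace times must be non-negative", call. = FALSE)
  if (!all(is.finite(signal))) stop("trace signal must be finite", call. = FALSE)
  structure(
    list(trace_id = as.character(trace_id), trace_type = trace_type,
         competitor = competitor, competitor_conc = competitor_conc,
         time = as.numeric(time), signal = as.numeric(signal)),
    class = "kinetic_trace"
  )
}

#' Write an analysis result to JSON (with optional CSV summary)
#'
#' Numeric fields are written at full precision so that a write/read
#' round trip is lossless.
#'
#' @param results any serializable result (list, data frame, fit object).
#' @param path output JSON path.
#' @param csv_path optional path for a flat CSV rendering when `results`
#'   is (coercible to) a data frame.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, csv_path = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir,
                             call. = FALSE)
  results <- strip_classes(results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  if (!is.null(csv_path) && is.data.frame(results)) {
    utils::write.csv(results, csv_path, row.names = FALSE)
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(x, strip_classes))
  x
}

#' Read back a JSON report
#'
#' @param path JSON path written by [write_report()].
#' @return the deserialized object (lists and data frames).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
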