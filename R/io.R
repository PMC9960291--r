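#' @keywords internal
#' Full-precision decimal rendering: 17 significant digits round-trips any
#' IEEE double exactly.
fmt_double <- function(x) sprintf("%.17g", x)

parse_numeric_column <- function(chr, column, path) {
  suppressWarnings(num <- as.numeric(chr))
  bad <- which(is.na(num) & !is.na(chr) & nzchar(chr))
  if (length(bad) > 0) {
    stop(sprintf("parse error in '%s': non-numeric value '%s' in column '%s', data row %d",
                 basename(path), chr[bad[1]], column, bad[1]), call. = FALSE)
  }
  if (anyNA(num)) {
    stop(sprintf("parse error in '%s': missing value in column '%s', data row %d",
                 basename(path), column, which(is.na(num))[1]), call. = FALSE)
  }
  num
}

# Infer fs from a time column; rejects grids whose steps deviate from the
# median step by more than 1 part in 1e3.
infer_fs <- function(time_s, path) {
  dt <- diff(time_s)
  med <- stats::median(dt)
  if (!is.finite(med) || med <= 0) {
    stop(sprintf("sampling error in '%s': non-increasing time column", basename(path)),
         call. = FALSE)
  }
  if (any(abs(dt - med) / med > 1e-3)) {
    stop(sprintf("sampling error in '%s': time steps vary by more than 1/1000 of the median step",
                 basename(path)), call. = FALSE)
  }
  fs <- 1 / med
  # absolute-epoch time columns quantize the step at ~1e-7 relative; snap to
  # integer rates (the only ones these devices use) when that close
  if (abs(fs - round(fs)) / fs < 1e-4) fs <- round(fs)
  fs
}

#' Read a raw accelerometer CSV
#'
#' Two dialects are supported. `"actigraph_raw"` is the vendor-style export:
#' a 10-line header block whose first line declares the sample rate
#' (`"... at <fs> Hz ..."`) and which carries `Start Time` / `Start Date`
#' lines, followed by a column-header line and three data columns
#' (X, Y, Z in g, no time column). `"generic"` is a plain 4-column
#' `time,x,y,z` CSV with time in seconds; the sampling frequency is inferred
#' from the median time step and files whose steps vary by more than 1 part
#' in 10^3 are rejected.
#'
#' @param path Path to the CSV file.
#' @param dialect `"actigraph_raw"` or `"generic"`.
#' @return A [triaxial_signal()] with `units = "g"`.
#' @export
read_accel_csv <- function(path, dialect = c("actigraph_raw", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "actigraph_raw") read_actigraph_raw(path) else read_generic_accel(path)
}

ACTIGRAPH_HEADER_LINES <- 10L

read_actigraph_raw <- function(path) {
  header <- readLines(path, n = ACTIGRAPH_HEADER_LINES + 1L)
  if (length(header) < ACTIGRAPH_HEADER_LINES + 1L || !grepl("Data File Created By", header[1])) {
    stop(sprintf("format error in '%s': missing or garbled vendor header block",
                 basename(path)), call. = FALSE)
  }
  m <- regmatches(header[1], regexec("at ([0-9.]+) Hz", header[1]))[[1]]
  if (length(m) != 2) {
    stop(sprintf("format error in '%s': header does not declare a sample rate",
                 basename(path)), call. = FALSE)
  }
  fs <- as.numeric(m[2])
  start_time <- sub("^Start Time[[:space:]]+", "", grep("^Start Time", header, value = TRUE))
  start_date <- sub("^Start Date[[:space:]]+", "", grep("^Start Date", header, value = TRUE))
  t0 <- 0
  if (length(start_time) == 1 && length(start_date) == 1) {
    parsed <- as.POSIXct(paste(start_date, start_time), tz = "UTC",
                         format = "%d/%m/%Y %H:%M:%S")
    if (!is.na(parsed)) t0 <- as.double(parsed)
  }
  raw <- utils::read.csv(path, skip = ACTIGRAPH_HEADER_LINES, colClasses = "character",
                         check.names = FALSE)
  if (ncol(raw) != 3) {
    stop(sprintf("format error in '%s': expected 3 accelerometer columns, found %d",
                 basename(path), ncol(raw)), call. = FALSE)
  }
  triaxial_signal(
    x = parse_numeric_column(raw[[1]], names(raw)[1], path),
    y = parse_numeric_column(raw[[2]], names(raw)[2], path),
    z = parse_numeric_column(raw[[3]], names(raw)[3], path),
    fs = fs, units = "g", t0 = t0
  )
}

read_generic_accel <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  want <- c("time", "x", "y", "z")
  if (!identical(tolower(names(raw)), want)) {
    stop(sprintf("format error in '%s': generic dialect requires columns time,x,y,z",
                 basename(path)), call. = FALSE)
  }
  time_s <- parse_numeric_column(raw[[1]], "time", path)
  fs <- infer_fs(time_s, path)
  triaxial_signal(
    x = parse_numeric_column(raw[[2]], "x", path),
    y = parse_numeric_column(raw[[3]], "y", path),
    z = parse_numeric_column(raw[[4]], "z", path),
    fs = fs, units = "g", t0 = time_s[1]
  )
}

#' Write a raw accelerometer CSV
#'
#' Inverse of [read_accel_csv()]; numbers are serialized with 17 significant
#' digits so that a write/read round trip reproduces the signal bit for bit.
#'
#' @param sig A [triaxial_signal()] in g.
#' @param path Output path.
#' @param dialect `"actigraph_raw"` or `"generic"`.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(sig, path, dialect = c("actigraph_raw", "generic")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(sig, "triaxial_signal"))
  if (sig$units != "g") stop("accelerometer CSVs are written in g", call. = FALSE)
  if (dialect == "generic") {
    t <- signal_times(sig) + sig$t0
    lines <- c("time,x,y,z",
               paste(fmt_double(t), fmt_double(sig$x), fmt_double(sig$y),
                     fmt_double(sig$z), sep = ","))
    writeLines(lines, path)
    return(invisible(path))
  }
  t0 <- if (sig$t0 == 0) as.POSIXct(0, origin = "1970-01-01", tz = "UTC") else
    as.POSIXct(sig$t0, origin = "1970-01-01", tz = "UTC")
  header <- c(
    sprintf("------------ Data File Created By ActiGraph GT9X Link ActiLife v6.13.3 Firmware v1.7.2 date format dd/MM/yyyy at %s Hz  Filter Normal -----------",
            format(sig$fs)),
    "Serial Number: SYNTH0001",
    sprintf("Start Time %s", format(t0, "%H:%M:%S")),
    sprintf("Start Date %s", format(t0, "%d/%m/%Y")),
    "Epoch Period (hh:mm:ss) 00:00:00",
    sprintf("Download Time %s", format(t0, "%H:%M:%S")),
    sprintf("Download Date %s", format(t0, "%d/%m/%Y")),
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.00     Mode = 12",
    "--------------------------------------------------"
  )
  lines <- c(header,
             "Accelerometer X,Accelerometer Y,Accelerometer Z",
             paste(fmt_double(sig$x), fmt_double(sig$y), fmt_double(sig$z), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a raw force-plate CSV
#'
#' Accepts either a 4-column `time,fx,fy,fz` file (time in seconds, sampling
#' frequency inferred from the median step) or a 3-column `fx,fy,fz` file
#' accompanied by a YAML sidecar `<path>.yml` declaring at least `fs`.
#' Forces are assumed to be reported as positive-upward reaction magnitudes
#' in newtons.
#'
#' @param path Path to the CSV/TSV file (delimiter sniffed from the header).
#' @return A [triaxial_signal()] with `units = "N"`.
#' @export
read_force_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  cols <- tolower(names(raw))
  if (identical(cols, c("time", "fx", "fy", "fz"))) {
    time_s <- parse_numeric_column(raw[[1]], "time", path)
    fs <- infer_fs(time_s, path)
    t0 <- time_s[1]
    fxyz <- raw[2:4]
  } else if (identical(cols, c("fx", "fy", "fz"))) {
    sidecar <- paste0(path, ".yml")
    if (!file.exists(sidecar)) {
      stop(sprintf("format error in '%s': 3-column force file needs a '%s' sidecar declaring fs",
                   basename(path), basename(sidecar)), call. = FALSE)
    }
    cfg <- yaml::read_yaml(sidecar)
    if (is.null(cfg$fs) || !is.numeric(cfg$fs) || cfg$fs <= 0) {
      stop(sprintf("format error in '%s': sidecar must declare a positive numeric fs",
                   basename(sidecar)), call. = FALSE)
    }
    fs <- cfg$fs
    t0 <- if (!is.null(cfg$t0)) as_epoch_seconds(cfg$t0) else 0
    fxyz <- raw
  } else {
    stop(sprintf("format error in '%s': expected columns time,fx,fy,fz or fx,fy,fz",
                 basename(path)), call. = FALSE)
  }
  triaxial_signal(
    x = parse_numeric_column(fxyz[[1]], "fx", path),
    y = parse_numeric_column(fxyz[[2]], "fy", path),
    z = parse_numeric_column(fxyz[[3]], "fz", path),
    fs = fs, units = "N", t0 = t0
  )
}

#' Write a raw force-plate CSV
#'
#' @param sig A [triaxial_signal()] in newtons.
#' @param path Output path.
#' @param time_column Write a `time` column (default) rather than a 3-column
#'   file with a YAML sidecar.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(sig, path, time_column = TRUE) {
  stopifnot(inherits(sig, "triaxial_signal"))
  if (sig$units != "N") stop("force CSVs are written in newtons", call. = FALSE)
  if (time_column) {
    t <- signal_times(sig) + sig$t0
    lines <- c("time,fx,fy,fz",
               paste(fmt_double(t), fmt_double(sig$x), fmt_double(sig$y),
                     fmt_double(sig$z), sep = ","))
    writeLines(lines, path)
  } else {
    lines <- c("fx,fy,fz",
               paste(fmt_double(sig$x), fmt_double(sig$y), fmt_double(sig$z), sep = ","))
    writeLines(lines, path)
    yaml::write_yaml(list(fs = sig$fs, units = "N", t0 = sig$t0), paste0(path, ".yml"))
  }
  invisible(path)
}

SUMMARY_COLUMNS <- c("subject_id", "body_mass_kg", "jump_type", "height_cm",
                     "placement", "vector", "pACC_g", "pAR_gs", "pGRF_N", "pLR_Ns")
SUMMARY_KEY <- c("subject_id", "jump_type", "height_cm", "placement", "vector")

JUMP_TYPES <- c("drop", "box", "continuous")
PLACEMENTS <- c("ankle", "lower_back", "hip")
VECTORS <- c("resultant", "vertical")

#' Write a per-trial summary table
#'
#' One row per subject x jump type x height x placement x vector, holding the
#' trial means of peak acceleration (pACC, g), peak acceleration rate
#' (pAR, g/s), peak ground reaction force (pGRF, N) and peak loading rate
#' (pLR, N/s), plus body mass. The column order is part of the file contract:
#' `subject_id, body_mass_kg, jump_type, height_cm, placement, vector,
#' pACC_g, pAR_gs, pGRF_N, pLR_Ns`.
#'
#' @param rows A data.frame with the columns above (any order; reordered on
#'   write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("summary table must have at least one row", call. = FALSE)
  missing_cols <- setdiff(SUMMARY_COLUMNS, names(rows))
  if (length(missing_cols) > 0) {
    stop(sprintf("summary table is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- rows[SUMMARY_COLUMNS]
  key <- do.call(paste, c(rows[SUMMARY_KEY], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- rows[duplicated(key), SUMMARY_KEY][1, ]
    stop(sprintf("duplication error: more than one row for key (%s)",
                 paste(unlist(dup), collapse = ", ")), call. = FALSE)
  }
  num <- c("body_mass_kg", "height_cm", "pACC_g", "pAR_gs", "pGRF_N", "pLR_Ns")
  out <- rows
  for (cn in num) out[[cn]] <- fmt_double(as.double(rows[[cn]]))
  lines <- c(paste(SUMMARY_COLUMNS, collapse = ","),
             do.call(paste, c(out, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-trial summary table
#'
#' @param path CSV written by [write_summary_table()] (or following its
#'   column contract).
#' @return A data.frame with the canonical column order and numeric loading
#'   columns.
#' @export
read_summary_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), SUMMARY_COLUMNS)) {
    stop(sprintf("format error in '%s': expected columns %s", basename(path),
                 paste(SUMMARY_COLUMNS, collapse = ",")), call. = FALSE)
  }
  out <- data.frame(subject_id = raw$subject_id,
                    body_mass_kg = parse_numeric_column(raw$body_mass_kg, "body_mass_kg", path),
                    jump_type = raw$jump_type,
                    height_cm = parse_numeric_column(raw$height_cm, "height_cm", path),
                    placement = raw$placement,
                    vector = raw$vector,
                    pACC_g = parse_numeric_column(raw$pACC_g, "pACC_g", path),
                    pAR_gs = parse_numeric_column(raw$pAR_gs, "pAR_gs", path),
                    pGRF_N = parse_numeric_column(raw$pGRF_N, "pGRF_N", path),
                    pLR_Ns = parse_numeric_column(raw$pLR_Ns, "pLR_Ns", path),
                    stringsAsFactors = FALSE)
  out
}
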