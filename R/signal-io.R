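#' Read / write ECG signals as self-describing CSV
#'
#' The CSV dialect is one header line `fs=<Hz>` (optionally followed by
#' `channel=<label>`), then one sample per line in millivolts.
#'
#' @param path file path.
#' @return [read_ecg_csv()] returns an [ecg_signal]; [write_ecg_csv()]
#'   returns `path` invisibly.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_ecg_csv(ecg_signal(c(0, 0.5, 1), fs = 360), f)
#' read_ecg_csv(f)
read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty ECG CSV file: ", path, call. = FALSE)
  }
  hdr <- grep("^\\s*[A-Za-z_]+\\s*=", lines)
  hdr <- hdr[hdr == seq_along(hdr)]  # header lines must be a leading block
  kv <- list()
  for (h in hdr) {
    parts <- strsplit(lines[h], "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  if (is.null(kv$fs)) {
    stop("ECG CSV header must declare fs=<Hz>: ", path, call. = FALSE)
  }
  fs <- suppressWarnings(as.numeric(kv$fs))
  if (is.na(fs)) stop("non-numeric fs in header: ", path, call. = FALSE)
  body <- if (length(hdr) > 0L) lines[-hdr] else lines
  if (length(body) == 0L) {
    stop("ECG CSV has no samples: ", path, call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(body))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1] + length(hdr)
    stop("non-numeric sample at line ", bad, " of ", path, call. = FALSE)
  }
  ecg_signal(v, fs, channel = kv$channel %||% "ECG", source = path)
}

#' @rdname read_ecg_csv
#' @param signal an [ecg_signal].
#' @param digits number of significant digits written per sample.
#' @export
write_ecg_csv <- function(signal, path, digits = 9) {
  stopifnot(inherits(signal, "ecg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("fs=%.10g", signal$fs),
               sprintf("channel=%s", signal$channel),
               formatC(signal$samples, digits = digits, format = "g")),
             con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ADC specification for serial-stream input
#'
#' The acquisition front end emits raw analog-to-digital converter codes over
#' a serial line, one integer per text line. A 10-bit converter referenced to
#' 3.3 V with the baseline at mid-scale (code 512) is the default; the
#' millivolt scale is `mv_per_unit = 1000 * v_ref / 2^bits` and
#' `mV = (code - center_code) * mv_per_unit`.
#'
#' @param bits ADC resolution in bits.
#' @param v_ref reference voltage (V).
#' @param center_code code corresponding to 0 mV (must satisfy
#'   `0 <= center_code < 2^bits`).
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(bits = 10L, v_ref = 3.3, center_code = 512L) {
  bits <- as.integer(bits)
  center_code <- as.integer(center_code)
  if (center_code < 0L || center_code >= 2^bits) {
    stop("center_code must satisfy 0 <= center_code < 2^bits", call. = FALSE)
  }
  structure(list(bits = bits, v_ref = v_ref, center_code = center_code,
                 mv_per_unit = 1000 * v_ref / 2^bits),
            class = "adc_spec")
}

#' Read / write an ADC serial text stream
#'
#' One integer code per line, `0 <= code < 2^bits`; codes map affinely to
#' millivolts per [adc_spec()]. Writing clips to the ADC range after
#' rounding, emulating converter saturation.
#'
#' @param path file path.
#' @param adc an [adc_spec()].
#' @param fs sampling rate of the stream (Hz); the text format does not carry
#'   it.
#' @return [read_serial_stream()] returns an [ecg_signal].
#' @export
read_serial_stream <- function(path, adc = adc_spec(), fs = 360) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty serial stream: ", path, call. = FALSE)
  codes <- suppressWarnings(as.integer(lines))
  if (anyNA(codes)) {
    stop("non-integer ADC code at line ", which(is.na(codes))[1], " of ",
         path, call. = FALSE)
  }
  if (any(codes < 0L | codes >= 2^adc$bits)) {
    bad <- which(codes < 0L | codes >= 2^adc$bits)[1]
    stop("ADC code out of range [0, ", 2^adc$bits, ") at line ", bad,
         " of ", path, call. = FALSE)
  }
  ecg_signal((codes - adc$center_code) * adc$mv_per_unit, fs,
             channel = "ADC", source = path)
}

#' @rdname read_serial_stream
#' @param signal an [ecg_signal].
#' @export
write_serial_stream <- function(signal, path, adc = adc_spec()) {
  stopifnot(inherits(signal, "ecg_signal"))
  codes <- round(signal$samples / adc$mv_per_unit) + adc$center_code
  codes <- pmin(pmax(codes, 0), 2^adc$bits - 1)
  writeLines(format(as.integer(codes), scientific = FALSE), path)
  invisible(path)
}
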