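#' Read / write records in the WFDB format-212 dialect
#'
#' Implements the subset of the waveform-database (WFDB) file family used by
#' the MIT-BIH Arrhythmia Database: a text header (`.hea`) naming the
#' signals, a packed 12-bit binary signal file (`.dat`, format 212) and
#' beat-annotation files (`.atr`, MIT annotation format). Millivolt values
#' are reconstructed as `(adc - baseline) / gain`.
#'
#' `record_path` is the record name with or without the `.hea` extension;
#' companion files are resolved next to it.
#'
#' @param record_path path to the record (`foo` or `foo.hea`).
#' @param channel channel to extract: 1-based index or signal description
#'   string.
#' @return [read_wfdb()] returns an [ecg_signal]; [read_wfdb_rpeaks()]
#'   returns an ascending integer vector of 1-based beat-annotation sample
#'   indices.
#' @export
read_wfdb <- function(record_path, channel = 1L) {
  hdr <- read_wfdb_header(record_path)
  dat_path <- file.path(dirname(hdr$path), hdr$signals$file[1])
  if (!file.exists(dat_path)) {
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  }
  if (any(hdr$signals$format != 212L)) {
    stop("only WFDB format 212 is supported (got ",
         paste(unique(hdr$signals$format), collapse = ","), ")", call. = FALSE)
  }
  nsig <- nrow(hdr$signals)
  raw_vals <- read_dat212(dat_path, hdr$nsamples * nsig)
  if (is.character(channel)) {
    ch <- match(channel, hdr$signals$description)
    if (is.na(ch)) {
      stop("unknown channel '", channel, "'; available: ",
           paste(hdr$signals$description, collapse = ", "), call. = FALSE)
    }
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > nsig) {
      stop("channel index out of range 1..", nsig, call. = FALSE)
    }
  }
  vals <- raw_vals[seq(ch, length(raw_vals), by = nsig)]
  g <- hdr$signals$gain[ch]
  b <- hdr$signals$baseline[ch]
  ecg_signal((vals - b) / g, hdr$fs,
             channel = hdr$signals$description[ch], source = hdr$path)
}

#' @rdname read_wfdb
#' @export
read_wfdb_rpeaks <- function(record_path) {
  hdr <- read_wfdb_header(record_path)
  atr_path <- file.path(dirname(hdr$path),
                        paste0(sub("\\.hea$", "", basename(hdr$path)), ".atr"))
  if (!file.exists(atr_path)) {
    stop("annotation file not found: ", atr_path, call. = FALSE)
  }
  ann <- read_atr(atr_path)
  sort(ann$sample[ann$is_beat]) + 1L  # annotations are 0-based on disk
}

#' @rdname read_wfdb
#' @param signals list of [ecg_signal] objects (equal length and fs) to write
#'   as one multi-channel record.
#' @param gain ADC units per millivolt (MIT-BIH convention: 200).
#' @param adczero ADC zero level (MIT-BIH convention: 1024).
#' @export
write_wfdb <- function(signals, record_path, gain = 200, adczero = 1024) {
  if (inherits(signals, "ecg_signal")) signals <- list(signals)
  stopifnot(length(signals) >= 1L,
            all(vapply(signals, inherits, logical(1), "ecg_signal")))
  n <- length(signals[[1]]$samples)
  fs <- signals[[1]]$fs
  if (!all(vapply(signals, function(s) length(s$samples) == n, logical(1))) ||
      !all(vapply(signals, function(s) s$fs == fs, logical(1)))) {
    stop("all channels must share length and fs", call. = FALSE)
  }
  rec <- sub("\\.hea$", "", record_path)
  name <- basename(rec)
  dat <- paste0(name, ".dat")
  adc <- lapply(signals, function(s) {
    v <- round(s$samples * gain) + adczero
    pmin(pmax(v, -2048), 2047)  # 12-bit two's complement range
  })
  hdr_lines <- c(sprintf("%s %d %.10g %d", name, length(signals), fs, n),
                 vapply(seq_along(signals), function(i) {
                   sprintf("%s 212 %.10g(%d)/mV 12 %d %d 0 0 %s",
                           dat, gain, adczero, adczero,
                           as.integer(adc[[i]][1]), signals[[i]]$channel)
                 }, character(1)))
  writeLines(hdr_lines, paste0(rec, ".hea"))
  inter <- integer(n * length(signals))
  for (i in seq_along(signals)) {
    inter[seq(i, length(inter), by = length(signals))] <- as.integer(adc[[i]])
  }
  write_dat212(inter, file.path(dirname(rec), dat))
  invisible(paste0(rec, ".hea"))
}

#' @rdname read_wfdb
#' @param peaks ascending 1-based sample indices of beat annotations.
#' @export
write_wfdb_rpeaks <- function(peaks, record_path) {
  rec <- sub("\\.hea$", "", record_path)
  write_atr(as.integer(peaks) - 1L, paste0(rec, ".atr"))
  invisible(paste0(rec, ".atr"))
}

# ---- internals -------------------------------------------------------------

read_wfdb_header <- function(record_path) {
  path <- if (grepl("\\.hea$", record_path)) record_path
          else paste0(record_path, ".hea")
  if (!file.exists(path)) {
    stop("WFDB header not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L) {
    stop("malformed WFDB header line: ", lines[1], call. = FALSE)
  }
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamples <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(nsamples)) {
    stop("malformed WFDB header: ", path, call. = FALSE)
  }
  if (length(lines) < 1L + nsig) {
    stop("WFDB header declares ", nsig, " signals but lists fewer",
         call. = FALSE)
  }
  sig <- lapply(lines[1L + seq_len(nsig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    # file format gain(baseline)/units adcres adczero initval chksum blk desc
    gm <- regmatches(f[3], regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?(/.*)?$", f[3]))[[1]]
    gain <- as.numeric(gm[2])
    adczero <- if (length(f) >= 5L) suppressWarnings(as.integer(f[5])) else 0L
    baseline <- if (nzchar(gm[4])) as.integer(gm[4]) else adczero %||% 0L
    if (is.na(gain) || gain == 0) gain <- 200  # WFDB default
    if (is.na(baseline)) baseline <- 0L
    list(file = f[1], format = as.integer(f[2]), gain = gain,
         baseline = baseline,
         description = if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ")
                       else "ECG")
  })
  signals <- data.frame(
    file = vapply(sig, `[[`, character(1), "file"),
    format = vapply(sig, `[[`, integer(1), "format"),
    gain = vapply(sig, `[[`, numeric(1), "gain"),
    baseline = vapply(sig, `[[`, numeric(1), "baseline"),
    description = vapply(sig, `[[`, character(1), "description"),
    stringsAsFactors = FALSE)
  list(path = path, nsig = nsig, fs = fs, nsamples = nsamples,
       signals = signals)
}

# format 212: two 12-bit two's-complement samples packed into 3 bytes
read_dat212 <- function(path, nvals) {
  raw <- readBin(path, "raw", n = file.size(path))
  npairs <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(npairs * 3L)]), nrow = 3L)
  s1 <- b[1, ] + bitwShiftL(bitwAnd(b[2, ], 0x0FL), 8L)
  s2 <- b[3, ] + bitwShiftL(bitwShiftR(b[2, ], 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  vals <- as.vector(rbind(s1, s2))
  if (!is.null(nvals)) vals <- vals[seq_len(min(nvals, length(vals)))]
  vals
}

write_dat212 <- function(vals, path) {
  vals <- as.integer(vals)
  if (length(vals) %% 2L == 1L) vals <- c(vals, 0L)  # pad to pairs
  u <- ifelse(vals < 0L, vals + 4096L, vals)         # 12-bit two's complement
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  b1 <- bitwAnd(s1, 0xFFL)
  b2 <- bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
  b3 <- bitwAnd(s2, 0xFFL)
  writeBin(as.raw(as.vector(rbind(b1, b2, b3))), path)
  invisible(path)
}

# MIT annotation format: 2-byte little-endian words; type = word >> 10,
# time increment = word & 0x3FF. Type 0/increment 0 terminates; 59 = SKIP
# (4-byte long interval follows), 60-62 = NUM/SUB/CHN, 63 = AUX.
read_atr <- function(path) {
  raw <- as.integer(readBin(path, "raw", n = file.size(path)))
  nw <- length(raw) %/% 2L
  samples <- integer(0)
  codes <- integer(0)
  t <- 0L
  i <- 1L
  while (i <= nw) {
    lo <- raw[2L * i - 1L]
    hi <- raw[2L * i]
    word <- lo + bitwShiftL(hi, 8L)
    a_type <- bitwShiftR(word, 10L)
    interval <- bitwAnd(word, 0x3FFL)
    i <- i + 1L
    if (a_type == 0L && interval == 0L) break
    if (a_type == 59L) {             # SKIP: next two words hold a long interval
      if (i + 1L > nw) break
      w1 <- raw[2L * i - 1L] + bitwShiftL(raw[2L * i], 8L)
      w2 <- raw[2L * (i + 1L) - 1L] + bitwShiftL(raw[2L * (i + 1L)], 8L)
      t <- t + bitwShiftL(w1, 16L) + w2
      i <- i + 2L
    } else if (a_type >= 60L && a_type <= 62L) {
      # NUM/SUB/CHN modifiers: no time advance
    } else if (a_type == 63L) {      # AUX: interval = byte count (padded even)
      i <- i + (interval + interval %% 2L) %/% 2L
    } else {
      t <- t + interval
      samples <- c(samples, t)
      codes <- c(codes, a_type)
    }
  }
  list(sample = samples, code = codes,
       is_beat = codes >= 1L & codes <= 49L)
}

write_atr <- function(samples0, path, code = 1L) {
  stopifnot(length(samples0) <= 1L || all(diff(samples0) > 0L))
  words <- integer(0)
  t <- 0L
  for (s in samples0) {
    dt <- s - t
    if (dt > 1023L) {                # SKIP record carries the long interval
      words <- c(words, bitwShiftL(59L, 10L),
                 bitwShiftR(dt, 16L), bitwAnd(dt, 0xFFFFL))
      dt <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(code, 10L), dt))
    t <- s
  }
  words <- c(words, 0L)              # EOF word
  b <- as.vector(rbind(bitwAnd(words, 0xFFL), bitwShiftR(words, 8L)))
  writeBin(as.raw(b), path)
  invisible(path)
}
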