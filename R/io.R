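# Recording I/O: CSV with a JSON sidecar (text, exact) and a minimal
# EDF writer/reader (16-bit, one 1-s data record per second).

#' Write a recording to disk
#'
#' CSV format stores samples x channels with a channel-name header plus a
#' JSON sidecar (`<path>.json`) holding sampling rate and metadata; the
#' round trip is sample-exact. EDF stores 16-bit integers with per-channel
#' physical scaling in 1-second data records (trailing partial second
#' dropped); the round trip is exact to within the 16-bit quantization
#' step.
#'
#' @param rec A [recording()].
#' @param path Output path; format chosen by extension (`.csv` / `.edf`).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- as.data.frame(t(rec$data))
    names(df) <- rec$channel_names
    write.csv(df, path, row.names = FALSE)
    meta <- list(fs = rec$fs, channel_names = rec$channel_names,
                 subject_id = rec$subject_id, condition = rec$condition,
                 group = rec$group)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (ext == "edf") {
    write_edf(rec, path)
  } else stop("unsupported extension: use .csv or .edf")
  invisible(path)
}

#' Read a recording from disk
#'
#' Accepts the two formats written by [write_recording()]: CSV plus JSON
#' sidecar, or EDF. Validates sampling rate, channel count and sample
#' finiteness.
#'
#' @param path Path to a `.csv` (with `<path>.json` sidecar) or `.edf`
#'   file.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop(sprintf("missing JSON sidecar %s (required field: fs)", sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("sidecar is missing the required field 'fs'")
    df <- read.csv(path, check.names = FALSE)
    if (!is.null(meta$channel_names) &&
        length(meta$channel_names) != ncol(df))
      stop(sprintf("channel-count mismatch: %d columns vs %d names",
                   ncol(df), length(meta$channel_names)))
    recording(t(as.matrix(df)), meta$fs,
              channel_names = if (is.null(meta$channel_names)) names(df)
                              else meta$channel_names,
              subject_id = meta$subject_id %||% NA_character_,
              condition = meta$condition %||% NA_character_,
              group = meta$group %||% NA_character_)
  } else if (ext == "edf") {
    read_edf(path)
  } else stop("unsupported extension: use .csv or .edf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

# Minimal EDF writer: 16-bit samples, one data record per second, metadata
# packed into the local-recording-identification field.
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- round(fs)
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s EDF data record")
  dat <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  phys_min <- apply(dat, 1, min)
  phys_max <- apply(dat, 1, max)
  flat <- phys_max - phys_min <= 0
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)
  wr(sprintf("%s", rec$subject_id), 80)
  wr(sprintf("meta subject=%s condition=%s group=%s", rec$subject_id,
             rec$condition, rec$group), 80)
  wr("01.01.20", 8)
  wr("00.00.00", 8)
  wr(sprintf("%d", 256 + ns * 256), 8)
  wr("", 44)
  wr(sprintf("%d", n_rec), 8)
  wr("1", 8)
  wr(sprintf("%d", ns), 4)
  for (i in seq_len(ns)) wr(rec$channel_names[i], 16)
  for (i in seq_len(ns)) wr("simulated", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%d", dig_min), 8)
  for (i in seq_len(ns)) wr(sprintf("%d", dig_max), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(sprintf("%d", fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((dat[i, cols] - phys_min[i]) * scale[i] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8) # version
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8) # date, time
  as.numeric(rd(8)) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!is.finite(ns) || ns < 1) stop("malformed EDF: bad signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1] / rec_dur

  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[i]) stop("malformed EDF: truncated data record")
      phys <- (dig - dig_min[i]) / (dig_max[i] - dig_min[i]) *
        (phys_max[i] - phys_min[i]) + phys_min[i]
      dat[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  meta <- c(subject = NA_character_, condition = NA_character_,
            group = NA_character_)
  m <- regmatches(rec_id, regexec(
    "subject=(\\S+) condition=(\\S+) group=(\\S+)", rec_id))[[1]]
  if (length(m) == 4) meta[] <- m[2:4]
  to_na <- function(x) if (is.na(x) || x == "NA") NA_character_ else x
  recording(dat, fs, channel_names = labels,
            subject_id = if (nzchar(subject_id)) subject_id else NA_character_,
            condition = to_na(meta[["condition"]]),
            group = to_na(meta[["group"]]))
}
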