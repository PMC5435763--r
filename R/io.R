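#' Read one channel of an EDF file
#'
#' Minimal reader for standard 16-bit EDF (European Data Format)
#' polysomnography files: parses the ASCII header, locates the requested
#' channel by label, and returns its samples converted to physical units at
#' the file's native rate. No resampling is performed.
#'
#' @param path path to an EDF file.
#' @param channel channel label to extract (matched against the EDF signal
#'   labels after whitespace trimming).
#' @return A [recording()] in the file's physical units.
#' @export
read_edf_signal <- function(path, channel) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  if (version != "0") stop("malformed EDF header: bad version field")
  hdr_txt(80); hdr_txt(80)             # patient / recording id
  hdr_txt(8); hdr_txt(8)               # start date / time
  header_bytes <- suppressWarnings(as.integer(hdr_txt(8)))
  hdr_txt(44)
  n_records <- suppressWarnings(as.integer(hdr_txt(8)))
  rec_dur <- suppressWarnings(as.numeric(hdr_txt(8)))
  ns <- suppressWarnings(as.integer(hdr_txt(4)))
  if (is.na(ns) || ns < 1 || is.na(n_records) || is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header")
  field <- function(width) vapply(seq_len(ns), function(i) hdr_txt(width), "")
  labels <- field(16)
  field(80)                            # transducer
  units <- field(8)
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                            # prefiltering
  spr <- as.integer(field(8))          # samples per record
  field(32)
  if (!is.na(header_bytes) && header_bytes != 256L * (ns + 1L))
    stop("malformed EDF header: inconsistent header size")
  k <- which(labels == trimws(channel))
  if (!length(k))
    stop(sprintf("channel not found: '%s' (file has: %s)", channel,
                 paste(labels, collapse = ", ")))
  k <- k[1]
  out <- numeric(n_records * spr[k])
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2,
                      signed = TRUE, endian = "little")
      if (s == k) {
        out[pos + seq_len(spr[k])] <- vals
        pos <- pos + spr[k]
      }
    }
  }
  gain <- (pmax[k] - pmin[k]) / (dmax[k] - dmin[k])
  recording(pmin[k] + (out - dmin[k]) * gain, rate = spr[k] / rec_dur,
            channel = trimws(channel))
}

#' Write recordings to a standard EDF file
#'
#' 16-bit EDF writer used to export synthetic polysomnography in the same
#' dialect [read_edf_signal()] ingests. Samples are quantized into the
#' signed 16-bit digital range over a symmetric physical range covering the
#' data.
#'
#' @param recs a [recording()] or list of recordings sharing one duration.
#' @param path output path.
#' @param physical_range symmetric physical range in uV; defaults to the
#'   smallest power-of-ten-ish range covering all samples.
#' @param record_duration EDF data-record length in seconds.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recs, path, physical_range = NULL, record_duration = 1) {
  if (inherits(recs, "recording")) recs <- list(recs)
  ns <- length(recs)
  durs <- vapply(recs, duration, 0)
  if (max(durs) - min(durs) > 1e-9) stop("all channels must share one duration")
  n_records <- floor(durs[1] / record_duration)
  if (n_records < 1) stop("recording shorter than one data record")
  spr <- vapply(recs, function(r) r$rate * record_duration, 0)
  if (any(abs(spr - round(spr)) > 1e-9))
    stop("rate * record_duration must be an integer for EDF export")
  spr <- as.integer(round(spr))
  if (is.null(physical_range))
    physical_range <- max(1, ceiling(max(abs(unlist(lapply(recs, `[[`, "samples"))))))
  pmin <- -physical_range; pmax <- physical_range
  dmin <- -32768L; dmax <- 32767L
  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    paste0(x, strrep(" ", w - nchar(x)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("", 44)
  wr(n_records, 8); wr(format(record_duration), 8); wr(ns, 4)
  for (r in recs) wr(r$channel, 16)
  for (r in recs) wr("", 80)
  for (r in recs) wr("uV", 8)
  for (r in recs) wr(format(pmin), 8)
  for (r in recs) wr(format(pmax), 8)
  for (r in recs) wr(dmin, 8)
  for (r in recs) wr(dmax, 8)
  for (r in recs) wr("", 80)
  for (i in seq_len(ns)) wr(spr[i], 8)
  for (r in recs) wr("", 32)
  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- lapply(recs, function(r) {
    d <- round((r$samples - pmin) / gain) + dmin
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (rec_i in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      idx <- ((rec_i - 1L) * spr[s] + 1L):(rec_i * spr[s])
      writeBin(dig[[s]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a plain-text spindle annotation file
#'
#' One event per non-comment line: onset and duration in seconds separated
#' by whitespace (the dialect used by open spindle-annotation releases).
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path annotation file path.
#' @param dialect `"dreams_text"` or `"generic_tsv"`; both accept
#'   whitespace-separated onset/duration pairs.
#' @return An [event_list()].
#' @export
read_annotations <- function(path, dialect = c("dreams_text", "generic_tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  onset <- numeric(0); dur <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "[\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals[1:2])))
      stop(sprintf("cannot parse annotation line %d: '%s'", i, lines[i]))
    if (vals[2] <= 0)
      stop(sprintf("non-positive duration on line %d: '%s'", i, lines[i]))
    onset <- c(onset, vals[1]); dur <- c(dur, vals[2])
  }
  o <- order(onset)
  event_list(onset = onset[o], duration = dur[o])
}

#' Write a plain-text spindle annotation file
#'
#' @param events an [event_list()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  lines <- c("# onset(s) duration(s)",
             sprintf("%.4f %.4f", events$onset, events$duration))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text hypnogram
#'
#' Format: a header line `epoch_length <seconds>` followed by one stage
#' label per line.
#'
#' @param path hypnogram file path.
#' @return A [stage_series()].
#' @export
read_hypnogram <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || !grepl("^epoch_length\\s", lines[1]))
    stop("hypnogram must start with an 'epoch_length <seconds>' header line")
  el <- as.numeric(strsplit(lines[1], "\\s+")[[1]][2])
  stage_series(lines[-1], epoch_length = el)
}

#' Write a plain-text hypnogram
#'
#' @param stages a [stage_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(stages, path) {
  writeLines(c(sprintf("epoch_length %g", stages$epoch_length), stages$stages), path)
  invisible(path)
}
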