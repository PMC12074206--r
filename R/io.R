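## Recording and configuration I/O.
##
## Two on-disk recording formats:
##  * delimited text: a "# fs_hz=<rate>" comment line followed by a CSV with
##    one "side_region" column per channel (values in uV);
##  * EDF (European Data Format): one signal per channel, physical dimension
##    uV, written as a single data record spanning the whole run. EDF stores
##    16-bit integers, so round trips are exact only to the quantisation step
##    (physical range / 65535).

.parseChannelNames <- function(nms) {
  parts <- strsplit(nms, "_", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop("channel names must be 'side_region', got: ",
         paste(nms[bad], collapse = ", "))
  data.frame(side = vapply(parts, `[`, character(1), 1L),
             region = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Write / read an EmgRecording
#'
#' The format is chosen from the file extension: `.edf` for EDF, anything
#' else (`.csv`, `.txt`) for delimited text.
#'
#' @param rec an [EmgRecording-class].
#' @param path output (input) file path.
#' @return `writeRecording()` returns `path` invisibly; `readRecording()`
#'   returns an [EmgRecording-class].
#' @examples
#' rec <- EmgRecording(matrix(rnorm(600), 100, 6), fs_hz = 2000)
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "EmgRecording"))
  if (tolower(tools::file_ext(path)) == "edf") .writeEDF(rec, path)
  else .writeRecordingText(rec, path)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  if (tolower(tools::file_ext(path)) == "edf") .readEDF(path)
  else .readRecordingText(path)
}

.writeRecordingText <- function(rec, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", rec@fs_hz), con)
  close(con); on.exit()
  dt <- data.table::as.data.table(rec@samples)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

.readRecordingText <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("#\\s*fs_hz=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) < 2L)
    stop("malformed recording header (expected '# fs_hz=...'): ", path)
  fs <- as.numeric(m[2])
  dt <- data.table::fread(path, skip = 1L, header = TRUE)
  mat <- as.matrix(dt)
  if (!is.numeric(mat) || anyNA(mat))
    stop("recording file contains non-numeric or missing samples: ", path)
  EmgRecording(mat, fs_hz = fs, channels = .parseChannelNames(colnames(mat)))
}

## ---- minimal EDF support -------------------------------------------------

.fmt8 <- function(x) {
  for (d in c(7, 6, 5, 4, 3)) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8L) break
  }
  sprintf("%-8s", s)
}

.padStr <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = -width)   # left-justified, space padded
}

.writeEDF <- function(rec, path) {
  m <- rec@samples
  n <- nrow(m); ns <- ncol(m)
  labels <- colnames(m)
  pmin <- apply(m, 2, min); pmax <- apply(m, 2, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(.padStr("0", 8), con, eos = NULL)
  writeChar(.padStr("X X X X", 80), con, eos = NULL)          # patient id
  writeChar(.padStr("Startdate X synthetic facialEMG", 80), con, eos = NULL)
  writeChar(.padStr("01.01.00", 8), con, eos = NULL)
  writeChar(.padStr("00.00.00", 8), con, eos = NULL)
  writeChar(.padStr(as.character(256L + 256L * ns), 8), con, eos = NULL)
  writeChar(.padStr("", 44), con, eos = NULL)
  writeChar(.padStr("1", 8), con, eos = NULL)                  # n records
  writeChar(.fmt8(n / rec@fs_hz), con, eos = NULL)             # duration (s)
  writeChar(.padStr(as.character(ns), 4), con, eos = NULL)

  wAll <- function(vals, width)
    for (v in vals) writeChar(.padStr(v, width), con, eos = NULL)
  wAll(labels, 16)
  wAll(rep("synthetic sEMG", ns), 80)                          # transducer
  wAll(rep("uV", ns), 8)
  for (v in pmin) writeChar(.fmt8(v), con, eos = NULL)
  for (v in pmax) writeChar(.fmt8(v), con, eos = NULL)
  wAll(rep(as.character(dmin), ns), 8)
  wAll(rep(as.character(dmax), ns), 8)
  wAll(rep("BP 10-250 Hz conditioning applies downstream", ns), 80)
  wAll(rep(as.character(n), ns), 8)                            # samples/record
  wAll(rep("", ns), 32)

  for (j in seq_len(ns)) {
    d <- round((m[, j] - pmin[j]) / (pmax[j] - pmin[j]) *
                 (dmax - dmin) + dmin)
    writeBin(as.integer(d), con, size = 2L, endian = "little")
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)            # ids, date, time
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width),
                                character(1))
  labels <- rdv(16)
  rdv(80)                                 # transducer
  rdv(8)                                  # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                                 # prefiltering
  nspr <- as.integer(rdv(8))
  rdv(32)

  chunks <- vector("list", ns)
  for (j in seq_len(ns)) chunks[[j]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, integer(), n = nspr[j], size = 2L, signed = TRUE,
                   endian = "little")
      chunks[[j]][[r]] <- (d - dmin[j]) / (dmax[j] - dmin[j]) *
        (pmax[j] - pmin[j]) + pmin[j]
    }
  }
  mat <- do.call(cbind, lapply(chunks, function(ch) unlist(ch)))
  fs <- nspr[1] / duration
  EmgRecording(mat, fs_hz = fs, channels = .parseChannelNames(labels))
}

## ---- run configuration ---------------------------------------------------

#' Read or write a run configuration
#'
#' Configurations are flat nested lists serialised as JSON or YAML (chosen
#' by extension). `readRunConfig()` merges the file's entries over
#' [defaultRunConfig()], so partial configurations are valid.
#'
#' @param path configuration file (`.json`, `.yaml`/`.yml`).
#' @param config a configuration list.
#' @return `readRunConfig()` returns the merged configuration list;
#'   `writeRunConfig()` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  .mergeConfig(defaultRunConfig(), cfg)
}

## recursive merge that only descends into named lists; unnamed lists
## (e.g. the movements sequence) are replaced wholesale
.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]])) && !is.null(names(override[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                digits = NA, pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(config, path),
    stop("unsupported config format: .", ext))
  invisible(path)
}
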