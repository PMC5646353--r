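#' Write a recording to BrainVision files
#'
#' Writes the `.vhdr` text header, an (empty) `.vmrk` marker file and the
#' binary `.eeg` data file (multiplexed IEEE 32-bit float, unit scaling).
#' Only the subset of the format needed to round-trip recordings produced by
#' this package is emitted.
#'
#' @param rec an [eeg_recording()].
#' @param path base path; the three extensions are appended/replaced.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  base <- sub("\\.(vhdr|eeg|vmrk)$", "", path)
  vhdr <- paste0(base, ".vhdr")
  vmrk <- paste0(base, ".vmrk")
  eegf <- paste0(base, ".eeg")

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", basename(eegf)),
    paste0("MarkerFile=", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    # BrainVision stores the sampling interval in microseconds
    paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 12)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)),
            rec$channel_labels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               paste0("DataFile=", basename(eegf)),
               "[Marker Infos]"), vmrk)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision recording
#'
#' Reads multiplexed or vectorized binary BrainVision data referenced from a
#' `.vhdr` header (IEEE float 32 or signed 16-bit integer with per-channel
#' resolution scaling).
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return An [eeg_recording()] (reference state `"recorded"`).
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE, encoding = "latin1")
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("missing BrainVision header field: ", key)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  n_chan <- as.integer(get1("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get1("SamplingInterval"))
  fmt <- get1("BinaryFormat")
  orient <- toupper(get1("DataOrientation"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(ch_parts, `[`, character(1), 1L)
  resol <- vapply(ch_parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1, numeric(1))
  eegf <- file.path(dirname(vhdr), get1("DataFile"))

  sz <- file.info(eegf)$size
  if (fmt == "IEEE_FLOAT_32") {
    n_val <- sz / 4L
    raw <- readBin(eegf, "numeric", n = n_val, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n_val <- sz / 2L
    raw <- readBin(eegf, "integer", n = n_val, size = 2L, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  n_samp <- length(raw) %/% n_chan
  raw <- raw[seq_len(n_samp * n_chan)]
  d <- if (orient == "MULTIPLEXED") {
    matrix(raw, nrow = n_chan)
  } else {
    t(matrix(raw, ncol = n_chan))
  }
  d <- d * resol
  eeg_recording(d, labels, fs, reference = "recorded")
}
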