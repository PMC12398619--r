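#' Write a continuous recording in BrainVision Core Data Format
#'
#' Writes the text header (`.vhdr`), marker file (`.vmrk`, pulse markers as
#' `Stimulus,S  1`) and binary IEEE float32 multiplexed data (`.eeg`).
#'
#' @param rec a [continuous_recording()].
#' @param basename path without extension; the three files are written next
#'   to each other.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "continuous_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eeg <- paste0(basename, ".eeg")
  nch <- nrow(rec$data)
  stem <- basename(basename)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    # SamplingInterval in microseconds
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), rec$channel_names))
  writeLines(hdr, vhdr)
  mk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", stem, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000",
    sprintf("Mk%d=Stimulus,S  1,%d,1,0",
            seq_along(rec$pulse_samples) + 1L, rec$pulse_samples))
  writeLines(mk, vmrk)
  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: channels fastest -> column-major of channels x samples
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

#' Read a BrainVision recording
#'
#' Minimal reader for the subset of the format written by
#' [write_brainvision()]: binary IEEE float32 or INT_16 multiplexed data,
#' with `Stimulus` markers taken as pulse markers.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return a [continuous_recording()].
#' @export
read_brainvision <- function(vhdr) {
  if (!file.exists(vhdr)) stop("no such header file: ", vhdr)
  lines <- readLines(vhdr, warn = FALSE)
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("corrupt BrainVision header ", vhdr,
                           ": missing ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  nch <- as.integer(get1("NumberOfChannels"))
  srate <- 1e6 / as.numeric(get1("SamplingInterval"))
  fmt <- get1("BinaryFormat")
  if (!identical(get1("DataOrientation"), "MULTIPLEXED"))
    stop("only MULTIPLEXED orientation is supported")
  chl <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", chl), ",")
  ch_names <- vapply(parts, `[`, "", 1)
  resol <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  dir <- dirname(vhdr)
  eeg <- file.path(dir, get1("DataFile"))
  vmrk <- file.path(dir, get1("MarkerFile"))
  n_bytes <- file.size(eeg)
  con <- file(eeg, "rb")
  on.exit(close(con))
  if (identical(fmt, "IEEE_FLOAT_32")) {
    raw <- readBin(con, "numeric", n = n_bytes / 4, size = 4,
                   endian = "little")
  } else if (identical(fmt, "INT_16")) {
    raw <- readBin(con, "integer", n = n_bytes / 2, size = 2, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  data <- matrix(raw, nrow = nch) * resol
  mk_lines <- grep("^Mk[0-9]+=Stimulus,", readLines(vmrk, warn = FALSE),
                   value = TRUE)
  pulse <- as.integer(vapply(strsplit(mk_lines, ","), `[`, "", 3))
  continuous_recording(data, srate, ch_names, sort(pulse))
}
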