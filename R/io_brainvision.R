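# BrainVision triplet (.vhdr/.vmrk/.eeg) support. The header and marker
# files are INI-style text; the data file holds IEEE float32 samples in
# multiplexed channel order. Signals are stored in microvolts (unit
# resolution 1), so the float32 round-trip error is far below the 0.1 uV
# amplifier resolution.

bv_marker_code <- function(code) {
  # marker codes are preserved verbatim in the description field
  c("Stimulus", code)
}

#' Write a recording as a BrainVision triplet
#'
#' Creates `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` (multiplexed IEEE
#' float32, microvolts). Event codes are preserved verbatim as marker
#' descriptions.
#'
#' @param rec An [eeg_recording()].
#' @param stem Output path without extension.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, stem) {
  vhdr <- paste0(stem, ".vhdr")
  vmrk <- paste0(stem, ".vmrk")
  eeg <- paste0(stem, ".eeg")
  base <- basename(stem)
  n_ch <- nrow(rec$data)
  interval_us <- 1e6 / rec$sampling_rate_hz

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_ch),
    sprintf("SamplingInterval=%.6f", interval_us),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_ch), rec$channel_labels)
  )
  writeLines(hdr, vhdr, useBytes = TRUE)

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,00000000000000000000"
  )
  if (nrow(rec$events) > 0) {
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L,
                          rec$events$code, rec$events$sample))
  }
  writeLines(mrk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

# minimal INI section parser for BrainVision text files
bv_parse_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character(0)
    } else if (!is.null(current)) {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  sections
}

bv_kv <- function(section) {
  kv <- strsplit(section, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), ""),
           vapply(kv, `[[`, "", 1))
}

#' Read a BrainVision recording
#'
#' @param vhdr_path Path to the `.vhdr` header.
#' @return An [eeg_recording()] in microvolts with the marker stream mapped
#'   to the event table.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) {
    abort(sprintf("No such header file: %s", vhdr_path),
          class = "oddlock_format_error")
  }
  sec <- bv_parse_ini(readLines(vhdr_path, warn = FALSE, encoding = "UTF-8"))
  common <- bv_kv(sec[["Common Infos"]])
  binary <- bv_kv(sec[["Binary Infos"]])
  if (!identical(unname(binary[["BinaryFormat"]]), "IEEE_FLOAT_32")) {
    abort(sprintf("Unsupported BinaryFormat `%s` in %s.",
                  binary[["BinaryFormat"]], vhdr_path),
          class = "oddlock_format_error")
  }
  if (!identical(unname(common[["DataOrientation"]]), "MULTIPLEXED")) {
    abort("Only MULTIPLEXED BrainVision data are supported.",
          class = "oddlock_format_error")
  }
  n_ch <- as.integer(common[["NumberOfChannels"]])
  sfreq <- 1e6 / as.numeric(common[["SamplingInterval"]])
  ch_info <- bv_kv(sec[["Channel Infos"]])
  parts <- strsplit(unname(ch_info), ",", fixed = TRUE)
  labels <- vapply(parts, `[[`, "", 1)
  resol <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, numeric(1))

  eeg_path <- file.path(dirname(vhdr_path), common[["DataFile"]])
  if (!file.exists(eeg_path)) {
    abort(sprintf("Header %s references missing data file %s.",
                  vhdr_path, eeg_path), class = "oddlock_format_error")
  }
  n_vals <- file.size(eeg_path) / 4
  con <- file(eeg_path, "rb")
  raw <- readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
  close(con)
  data <- matrix(raw, nrow = n_ch) * resol

  events <- empty_events()
  mrk_path <- file.path(dirname(vhdr_path), common[["MarkerFile"]] %||% "")
  if (!is.null(common[["MarkerFile"]]) && file.exists(mrk_path)) {
    msec <- bv_parse_ini(readLines(mrk_path, warn = FALSE,
                                   encoding = "UTF-8"))
    mk <- bv_kv(msec[["Marker Infos"]] %||% character(0))
    if (length(mk) > 0) {
      mp <- strsplit(unname(mk), ",", fixed = TRUE)
      type <- vapply(mp, `[[`, "", 1)
      keep <- type != "New Segment"
      if (any(keep)) {
        events <- tibble(
          sample = as.integer(vapply(mp[keep], `[[`, "", 3)),
          code = vapply(mp[keep], `[[`, "", 2)
        )
      }
    }
  } else {
    warn("No marker file found; recording has an empty event list.")
  }
  eeg_recording(data, sfreq, labels, events)
}
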