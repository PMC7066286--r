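# EDF+ support. Continuous EDF+ ("EDF+C") with 1 s data records, 16-bit
# samples scaled to a physical range of +/-3276.8 uV, i.e. a quantization
# step of exactly 0.1 uV — the amplifier resolution the format is meant to
# carry. Events travel in the standard "EDF Annotations" signal as
# time-stamped annotation lists (TALs).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

EDF_PHYS_MAX <- 3276.7
EDF_PHYS_MIN <- -3276.8

#' Write a recording as EDF+
#'
#' Continuous EDF+ with 1 s records; signals are quantized to 0.1 uV steps
#' (16-bit over +/-3276.8 uV). Events are written verbatim into the
#' `EDF Annotations` signal.
#'
#' @param rec An [eeg_recording()]; the sampling rate must be an integer
#'   number of samples per second.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sfreq <- rec$sampling_rate_hz
  if (sfreq != round(sfreq)) {
    abort("EDF writing requires an integer sampling rate.",
          class = "oddlock_format_error")
  }
  n_ch <- nrow(rec$data)
  n_rec <- ceiling(ncol(rec$data) / sfreq)
  n_pad <- n_rec * sfreq - ncol(rec$data)
  data <- cbind(rec$data, matrix(0, n_ch, n_pad))

  # annotations: one timestamp TAL per record plus the events of that
  # second; TALs are NUL-terminated ("...\x14" then a zero byte)
  onset_s <- (rec$events$sample - 1) / sfreq
  tals <- split(sprintf("+%.4f\x14%s\x14", onset_s, rec$events$code),
                floor(onset_s))
  ann_rec <- lapply(seq_len(n_rec) - 1L, function(r) {
    parts <- c(sprintf("+%d\x14\x14", r),
               tals[[as.character(r)]] %||% character(0))
    unlist(lapply(parts, function(p) c(charToRaw(p), as.raw(0))))
  })
  ann_bytes <- max(16L, max(vapply(ann_rec, length, 1L)))
  if (ann_bytes %% 2L == 1L) ann_bytes <- ann_bytes + 1L
  ann_samples <- ann_bytes %/% 2L

  ns_total <- n_ch + 1L
  header_bytes <- 256L * (ns_total + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(x) writeChar(x, con, eos = NULL, useBytes = TRUE)
  wchar(edf_pad("0", 8))
  wchar(edf_pad("X X X X", 80))                       # local patient id
  wchar(edf_pad("Startdate 01-JAN-2000 X X X", 80))   # local recording id
  wchar(edf_pad("01.01.00", 8))
  wchar(edf_pad("00.00.00", 8))
  wchar(edf_pad(header_bytes, 8))
  wchar(edf_pad("EDF+C", 44))
  wchar(edf_pad(n_rec, 8))
  wchar(edf_pad("1", 8))                              # record duration s
  wchar(edf_pad(ns_total, 4))
  labels <- c(rec$channel_labels, "EDF Annotations")
  for (lb in labels) wchar(edf_pad(lb, 16))
  for (i in seq_len(ns_total)) wchar(edf_pad("", 80)) # transducer
  wchar(paste(vapply(c(rep("uV", n_ch), ""), edf_pad, "", width = 8),
              collapse = ""))
  wchar(paste(vapply(c(rep(EDF_PHYS_MIN, n_ch), -1), edf_pad, "",
                     width = 8), collapse = ""))
  wchar(paste(vapply(c(rep(EDF_PHYS_MAX, n_ch), 1), edf_pad, "",
                     width = 8), collapse = ""))
  wchar(paste(vapply(c(rep(-32768L, n_ch), -32768L), edf_pad, "",
                     width = 8), collapse = ""))
  wchar(paste(vapply(c(rep(32767L, n_ch), 32767L), edf_pad, "",
                     width = 8), collapse = ""))
  for (i in seq_len(ns_total)) wchar(edf_pad("", 80)) # prefiltering
  wchar(paste(vapply(c(rep(sfreq, n_ch), ann_samples), edf_pad, "",
                     width = 8), collapse = ""))
  for (i in seq_len(ns_total)) wchar(edf_pad("", 32)) # reserved

  scale <- (32767 - (-32768)) / (EDF_PHYS_MAX - EDF_PHYS_MIN)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * sfreq + 1):(r * sfreq)
    for (ci in seq_len(n_ch)) {
      phys <- pmin(pmax(data[ci, idx], EDF_PHYS_MIN), EDF_PHYS_MAX)
      dig <- as.integer(round((phys - EDF_PHYS_MIN) * scale) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
    ann <- ann_rec[[r]]
    writeBin(c(ann, raw(ann_bytes - length(ann))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ recording
#'
#' Supports the continuous EDF+ layout written by [write_edf()] (uniform
#' sampling rate across EEG signals; annotations signal optional).
#'
#' @param path Path to the `.edf` file.
#' @return An [eeg_recording()] in microvolts.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such EDF file: %s", path),
          class = "oddlock_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function(n) {
    trimws(rawToChar(readBin(con, "raw", n)))
  }
  rstr(8)                            # version
  rstr(80); rstr(80); rstr(8); rstr(8)
  header_bytes <- as.integer(rstr(8))
  rstr(44)
  n_rec <- as.integer(rstr(8))
  rec_dur <- as.numeric(rstr(8))
  ns <- as.integer(rstr(4))
  labels <- vapply(seq_len(ns), function(i) rstr(16), "")
  for (i in seq_len(ns)) rstr(80)
  units <- vapply(seq_len(ns), function(i) rstr(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rstr(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rstr(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rstr(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rstr(8), ""))
  for (i in seq_len(ns)) rstr(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rstr(8), ""))
  for (i in seq_len(ns)) rstr(32)

  is_ann <- labels == "EDF Annotations"
  eeg_idx <- which(!is_ann)
  if (length(unique(spr[eeg_idx])) != 1) {
    abort("Signals with differing sampling rates are not supported.",
          class = "oddlock_format_error")
  }
  sfreq <- spr[eeg_idx[1]] / rec_dur
  n_ch <- length(eeg_idx)
  data <- matrix(0, n_ch, n_rec * spr[eeg_idx[1]])
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (si in seq_len(ns)) {
      if (is_ann[si]) {
        bytes <- readBin(con, "raw", spr[si] * 2)
        # TALs are NUL-separated; keep each as its own string
        splits <- cumsum(bytes == as.raw(0))
        grp <- c(0, splits[-length(splits)])
        tal <- vapply(split(bytes[bytes != as.raw(0)],
                            grp[bytes != as.raw(0)]),
                      rawToChar, "")
        ann_text <- c(ann_text, tal[nzchar(tal)])
      } else {
        dig <- readBin(con, "integer", spr[si], size = 2, endian = "little")
        phys <- phys_min[si] + (dig - dig_min[si]) *
          (phys_max[si] - phys_min[si]) / (dig_max[si] - dig_min[si])
        ci <- match(si, eeg_idx)
        data[ci, ((r - 1) * spr[si] + 1):(r * spr[si])] <- phys
      }
    }
  }
  events <- empty_events()
  if (length(ann_text) > 0) {
    parsed <- purrr::map_dfr(ann_text, function(tl) {
      parts <- strsplit(tl, "\x14", fixed = TRUE)[[1]]
      onset <- suppressWarnings(
        as.numeric(sub("^\\+", "", strsplit(parts[1], "\x15",
                                            fixed = TRUE)[[1]][1])))
      desc <- if (length(parts) >= 2) parts[2] else ""
      tibble(onset = onset, code = desc)
    })
    parsed <- parsed[!is.na(parsed$onset) & parsed$code != "", ]
    if (nrow(parsed) > 0) {
      events <- tibble(sample = as.integer(round(parsed$onset * sfreq)) + 1L,
                       code = parsed$code)
    }
  }
  if (nrow(events) == 0) {
    warn("EDF file carries no event annotations; event list is empty.")
  }
  eeg_recording(data, sfreq, labels[eeg_idx], events)
}
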