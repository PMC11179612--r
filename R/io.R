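# Plain-text recording I/O: one directory per recording with channels.csv
# (time_s, bp, mcav_left, mcav_right, ecg, etco2) and meta.json
# (sample_rate, annotations, brachial).

#' Read a raw recording from a directory
#'
#' Expects `channels.csv` with columns `time_s, bp, mcav_left, mcav_right,
#' ecg, etco2` and `meta.json` with `sample_rate`, `annotations` (list of
#' task_id / onset_s / duration_s) and optional `brachial` (systolic,
#' diastolic).
#'
#' @param dir recording directory.
#' @return a [raw_recording()].
#' @export
read_recording <- function(dir) {
  ch <- utils::read.csv(file.path(dir, "channels.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ann <- meta$annotations
  if (is.null(ann) || !length(ann)) {
    ann <- data.frame(task_id = character(0), onset_s = numeric(0),
                      duration_s = numeric(0))
  }
  raw_recording(meta$sample_rate,
                list(bp = ch$bp, mcav_left = ch$mcav_left,
                     mcav_right = ch$mcav_right, ecg = ch$ecg,
                     etco2 = ch$etco2),
                annotations = as.data.frame(ann),
                brachial = meta$brachial)
}

#' Write a raw recording to a directory
#'
#' @param rec a [raw_recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(rec$channels$bp)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$sample_rate,
                   rec$channels)
  utils::write.csv(df, file.path(dir, "channels.csv"), row.names = FALSE)
  meta <- list(sample_rate = rec$sample_rate,
               annotations = rec$annotations,
               brachial = rec$brachial)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
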