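#' Construct a waveform record
#'
#' A waveform record is the unit of ingestion: a tibble with columns `time`
#' (seconds, starting at 0) and `value` (mmHg for ABP, arbitrary units for
#' PPG), carrying the sampling rate and signal kind as attributes.
#'
#' @param samples Numeric vector of amplitudes, in sample order.
#' @param fs Sampling rate in Hz (must be > 0). Bedside recordings this
#'   package targets are nominally 256 Hz.
#' @param kind Signal kind, `"ABP"` or `"PPG"`.
#' @param label Free-text label for the record.
#' @return A tibble of class `waveform_record` with columns `time`, `value`.
#' @examples
#' rec <- waveform_record(80 + 20 * sin(2 * pi * 1.2 * seq(0, 4, by = 1/256)),
#'                        fs = 256, kind = "ABP")
#' wf_fs(rec)
#' @export
waveform_record <- function(samples, fs, kind = c("ABP", "PPG"), label = "") {
  kind <- match.arg(kind)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) abort("`samples` must not contain missing values.")
  out <- tibble(
    time  = (seq_along(samples) - 1) / fs,
    value = samples
  )
  structure(out,
            fs = fs, kind = kind, label = label,
            class = c("waveform_record", class(out)))
}

#' @rdname waveform_record
#' @param record A `waveform_record`.
#' @export
wf_fs <- function(record) attr(record, "fs")

#' @rdname waveform_record
#' @export
wf_kind <- function(record) attr(record, "kind")

#' Read a single-channel waveform from CSV
#'
#' Accepts one numeric value per row, with an optional header line
#' (auto-detected by a non-numeric first row) and an optional leading time
#' column; when two columns are present the second is taken as the samples.
#' Comma-separated, `.` decimal.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz.
#' @inheritParams waveform_record
#' @return A [waveform_record()].
#' @export
read_waveform <- function(path, fs, kind = c("ABP", "PPG"), label = basename(path)) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, ",", fixed = TRUE)[[1]]
  has_header <- length(fields) > 0 &&
    anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE, strip.white = TRUE)
  value_col <- if (ncol(df) >= 2L) 2L else 1L
  raw <- df[[value_col]]
  num <- suppressWarnings(as.numeric(raw))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    abort(paste0("Non-numeric sample in ", path, " at data row ", bad,
                 ": '", raw[bad], "'"))
  }
  waveform_record(num, fs = fs, kind = kind, label = label)
}

#' Write a waveform record to CSV
#'
#' Writes `time,value` columns; [read_waveform()] round-trips the values to
#' text-representation precision.
#'
#' @param record A `waveform_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(record, path) {
  readr::write_csv(as_tibble(record)[, c("time", "value")], path)
  invisible(path)
}

#' Slice a record into non-overlapping analysis windows
#'
#' Cuts the record into consecutive windows of `window_seconds` (default the
#' 4-second analysis window used throughout the pipeline); a trailing partial
#' window is discarded.
#'
#' @param record A `waveform_record`.
#' @param window_seconds Window length in seconds (> 0).
#' @return A tibble with one row per window: `window_id`, `start_index`
#'   (1-based sample offset into the record), `n`, and a `samples` list-column.
#'   Zero rows when the record is shorter than one window.
#' @export
cut_windows <- function(record, window_seconds = 4) {
  if (!is.numeric(window_seconds) || window_seconds <= 0) {
    abort("`window_seconds` must be > 0.")
  }
  fs <- wf_fs(record)
  x <- record$value
  len <- round(window_seconds * fs)
  k <- floor(length(x) / len)
  if (k < 1L) {
    return(tibble(window_id = integer(), start_index = integer(),
                  n = integer(), samples = list()))
  }
  starts <- (seq_len(k) - 1L) * len + 1L
  tibble(
    window_id   = seq_len(k),
    start_index = starts,
    n           = len,
    samples     = map(starts, function(s) x[s:(s + len - 1L)])
  )
}

#' Read and write landmark annotation tables
#'
#' Annotation CSVs have columns `landmark_type` (one of SPO, SPP, DN, DPP,
#' DPE) and `sample_index` (1-based). Used both for detector output and for
#' reference marks in evaluation.
#'
#' @param path CSV path.
#' @return A tibble with columns `landmark_type`, `sample_index`, sorted and
#'   strictly increasing within each type.
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("landmark_type", "sample_index") %in% names(df))) {
    abort("Annotation CSV needs columns landmark_type, sample_index.")
  }
  bad <- setdiff(unique(df$landmark_type), LANDMARK_TYPES)
  if (length(bad)) abort(paste0("Unknown landmark type(s): ",
                                paste(bad, collapse = ", ")))
  df |>
    mutate(sample_index = as.integer(.data$sample_index)) |>
    arrange(.data$landmark_type, .data$sample_index) |>
    dplyr::distinct()
}

#' @rdname read_annotations
#' @param annotations Tibble with columns `landmark_type`, `sample_index`.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations[, c("landmark_type", "sample_index")], path)
  invisible(path)
}

#' @export
autoplot.waveform_record <- function(object, annotations = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "time (s)",
      y = if (wf_kind(object) == "ABP") "pressure (mmHg)" else "PPG (a.u.)",
      title = attr(object, "label")
    )
  if (!is.null(annotations) && nrow(annotations)) {
    fs <- wf_fs(object)
    ann <- annotations |>
      mutate(time  = (.data$sample_index - 1) / fs,
             value = object$value[.data$sample_index])
    p <- p + ggplot2::geom_point(
      data = ann,
      ggplot2::aes(colour = .data$landmark_type),
      size = 1.8
    ) + ggplot2::labs(colour = "landmark")
  }
  p
}
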