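#' ROI time-series container
#'
#' Holds one subject's region-by-sample signal matrix together with region
#' labels, the sampling rate and subject metadata. Rows are regions, columns
#' are time points.
#'
#' @param data numeric matrix, regions x samples; all values must be finite.
#' @param region_labels character vector of unique region names, one per row.
#'   Defaults to `R1, R2, ...`.
#' @param sampling_rate_hz positive sampling rate in Hz (default 500).
#' @param subject_id subject identifier string.
#' @param group group label (e.g. `"HC"` or `"TLE"`); empty string if unknown.
#'
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(data, region_labels = NULL, sampling_rate_hz = 500,
                           subject_id = "subject", group = "") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("signal matrix must be numeric", call. = FALSE)
  bad <- which(!is.finite(data))
  if (length(bad)) {
    r <- ((bad[1] - 1L) %% nrow(data)) + 1L
    c <- ((bad[1] - 1L) %/% nrow(data)) + 1L
    stop(sprintf("non-finite value at row %d, column %d", r, c), call. = FALSE)
  }
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(data)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(data))
    stop(sprintf("%d region labels for %d rows", length(region_labels),
                 nrow(data)), call. = FALSE)
  if (anyDuplicated(region_labels))
    stop("region labels must be unique", call. = FALSE)
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive", call. = FALSE)
  dimnames(data) <- NULL
  structure(list(data = data, region_labels = region_labels,
                 sampling_rate_hz = sampling_rate_hz,
                 subject_id = as.character(subject_id),
                 group = as.character(group)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> %s%s: %d regions x %d samples @ %g Hz\n",
              x$subject_id,
              if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz))
  invisible(x)
}

#' Read an ROI time-series matrix from delimited text
#'
#' Reads a rectangular tab-separated matrix (rows = regions, columns =
#' samples). Ragged rows, non-numeric cells and non-finite values are
#' rejected with the offending row/column location.
#'
#' @param path path to the TSV matrix file.
#' @param labels_path optional path to a one-region-name-per-line text file;
#'   its length must equal the row count.
#' @param sampling_rate_hz sampling rate to attach (default 500).
#' @param subject_id,group metadata passed through to [roi_timeseries()].
#' @return An `roi_ts` object.
#' @export
read_roi_timeseries <- function(path, labels_path = NULL,
                                sampling_rate_hz = 500,
                                subject_id = basename(path), group = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0) stop("empty file: ", path, call. = FALSE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged input: row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]), call. = FALSE)
  }
  raw <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                     colClasses = "character", quote = ""))
  m <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(!is.finite(m))
  if (length(bad)) {
    r <- ((bad[1] - 1L) %% nrow(m)) + 1L
    c <- ((bad[1] - 1L) %/% nrow(m)) + 1L
    stop(sprintf("non-numeric or non-finite cell '%s' at row %d, column %d",
                 raw[r, c], r, c), call. = FALSE)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- readLines(labels_path)
    labels <- labels[nzchar(labels)]
    if (length(labels) != nrow(m))
      stop(sprintf("label file has %d names but matrix has %d rows",
                   length(labels), nrow(m)), call. = FALSE)
  }
  roi_timeseries(m, labels, sampling_rate_hz, subject_id, group)
}

#' Write an ROI time series as tab-separated text
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces doubles exactly.
#'
#' @param ts an `roi_ts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  lines <- apply(ts$data, 1L, function(r) paste(sprintf("%.17g", r),
                                                collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Segment a recording into consecutive non-overlapping epochs
#'
#' The trailing partial epoch, if any, is discarded. At the default 500 Hz
#' sampling rate a 2 s epoch has 1000 samples.
#'
#' @param ts an `roi_ts` object.
#' @param epoch_seconds epoch duration in seconds; `epoch_seconds *
#'   sampling_rate_hz` must be a positive integer.
#' @return A list of `roi_ts` epochs, subject ids suffixed `_ep<k>`.
#' @export
segment_epochs <- function(ts, epoch_seconds = 2) {
  stopifnot(inherits(ts, "roi_ts"))
  len <- epoch_seconds * ts$sampling_rate_hz
  if (len <= 0 || abs(len - round(len)) > 1e-9)
    stop("epoch_seconds x sampling rate must be a positive integer",
         call. = FALSE)
  len <- as.integer(round(len))
  n_ep <- ncol(ts$data) %/% len
  if (n_ep < 1)
    stop(sprintf("series has %d samples, shorter than one %d-sample epoch",
                 ncol(ts$data), len), call. = FALSE)
  lapply(seq_len(n_ep), function(k) {
    roi_timeseries(ts$data[, ((k - 1L) * len + 1L):(k * len), drop = FALSE],
                   ts$region_labels, ts$sampling_rate_hz,
                   paste0(ts$subject_id, "_ep", k), ts$group)
  })
}

#' Select the representative signal by maximal total power
#'
#' Among candidate signals of equal length for one region, returns the one
#' with the largest sum of squared values; ties go to the lowest index.
#'
#' @param candidates a list of equal-length numeric vectors (or a matrix with
#'   one candidate per row).
#' @return The winning numeric vector, with attribute `"index"`.
#' @export
select_representative <- function(candidates) {
  if (is.matrix(candidates))
    candidates <- lapply(seq_len(nrow(candidates)), function(i) candidates[i, ])
  if (length(candidates) == 0)
    stop("no candidate signals supplied", call. = FALSE)
  lens <- lengths(candidates)
  if (length(unique(lens)) > 1)
    stop("candidate signals must have equal length", call. = FALSE)
  power <- vapply(candidates, function(x) sum(x^2), numeric(1))
  i <- which.max(power)  # which.max takes the first maximum: lowest index
  structure(candidates[[i]], index = i)
}

#' Z-score each region's signal
#'
#' Centers and scales every row to mean 0 and standard deviation 1 using the
#' population convention (divide by n, not n - 1), as conditioning before
#' autoregressive fits.
#'
#' @param ts an `roi_ts` object; no row may be constant.
#' @return A standardized `roi_ts`.
#' @export
zscore <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$data
  mu <- rowMeans(x)
  xc <- x - mu
  sd_pop <- sqrt(rowMeans(xc^2))
  if (any(sd_pop == 0)) {
    bad <- which(sd_pop == 0)[1]
    stop(sprintf("region '%s' (row %d) is constant and cannot be z-scored",
                 ts$region_labels[bad], bad), call. = FALSE)
  }
  ts$data <- xc / sd_pop
  ts
}
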