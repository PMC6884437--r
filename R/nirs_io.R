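#' Construct a NIRS session object
#'
#' A session holds a multi-channel NIRS recording as a numeric matrix
#' (time in rows, channels in columns) together with its sampling rate,
#' channel metadata (label and source-detector distance), and the sample
#' index at which the resting period ends and the task period begins.
#'
#' @param samples numeric matrix, time x channel. Column names, if present,
#'   must agree with `channels$label`.
#' @param fs sampling rate in Hz (default 10, the rate of typical wearable
#'   forehead optical topography devices).
#' @param channels data frame with columns `label` (unique short strings,
#'   e.g. "L1","L3","R1","R3") and `distance` (source-detector distance in
#'   cm, > 0). If `NULL`, labels "C1".."Ck" with 3.0 cm distances are used.
#' @param rest_end sample index where rest ends; samples `1..rest_end` are
#'   rest, `rest_end+1..N` are task.
#' @param subject_id,condition free-text tags.
#' @param min_rest_s minimum rest duration in seconds required for the
#'   session to be usable downstream (the baseline window length; default 20).
#'
#' @return an object of class `nirs_session`.
#' @seealso [read_session()], [write_session()], [select_channel()]
#' @export
nirs_session <- function(samples, fs = 10, channels = NULL, rest_end,
                         subject_id = "", condition = "", min_rest_s = 20) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) == 0L || ncol(samples) == 0L)
    stop("session sample matrix is empty")
  if (is.null(channels)) {
    channels <- data.frame(label = paste0("C", seq_len(ncol(samples))),
                           distance = 3.0, stringsAsFactors = FALSE)
  }
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  colnames(samples) <- channels$label
  s <- structure(
    list(samples = samples, fs = fs, channels = channels,
         rest_end = as.integer(rest_end),
         subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "nirs_session")
  validate_session(s, min_rest_s = min_rest_s)
}

#' Validate a NIRS session
#'
#' Checks all session invariants: positive sampling rate, unique channel
#' labels with positive distances, a rest/task split strictly inside the
#' recording, rest at least as long as the baseline window, and no
#' non-finite sample values.
#'
#' @param s a `nirs_session`.
#' @param min_rest_s required minimum rest duration in seconds.
#' @return `s`, invisibly usable, after passing all checks.
#' @export
validate_session <- function(s, min_rest_s = 20) {
  stopifnot(inherits(s, "nirs_session"))
  if (!is.numeric(s$fs) || length(s$fs) != 1L || s$fs <= 0)
    stop("sampling rate fs must be a single positive number")
  ch <- s$channels
  if (!all(c("label", "distance") %in% names(ch)))
    stop("channel metadata needs 'label' and 'distance' columns")
  if (anyDuplicated(ch$label))
    stop("channel labels must be unique within a session")
  if (any(ch$distance <= 0))
    stop("source-detector distances must be positive")
  if (nrow(ch) != ncol(s$samples))
    stop("channel metadata rows (", nrow(ch), ") do not match sample columns (",
         ncol(s$samples), ")")
  n <- nrow(s$samples)
  if (s$rest_end <= 0L || s$rest_end >= n)
    stop("rest_end (", s$rest_end, ") must lie strictly inside 1..", n)
  bad <- which(!is.finite(s$samples), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite sample value at row ", bad[1L, 1L],
         ", channel '", ch$label[bad[1L, 2L]], "'")
  rest_s <- s$rest_end / s$fs
  if (rest_s < min_rest_s)
    stop("rest period (", rest_s, " s) is shorter than the baseline window (",
         min_rest_s, " s); session unusable for cognitive-load estimation")
  s
}

#' @export
print.nirs_session <- function(x, ...) {
  n <- nrow(x$samples)
  cat("NIRS session", if (nzchar(x$subject_id)) paste0("[", x$subject_id, "]"),
      if (nzchar(x$condition)) paste0("(", x$condition, ")"), "\n")
  cat(sprintf("  %d samples x %d channels @ %g Hz (%.1f s rest + %.1f s task)\n",
              n, ncol(x$samples), x$fs,
              x$rest_end / x$fs, (n - x$rest_end) / x$fs))
  cat("  channels:",
      paste(sprintf("%s (%.1f cm)", x$channels$label, x$channels$distance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a NIRS session file
#'
#' The session dialect is delimited text (comma or tab, auto-detected) with
#' a `#`-prefixed key=value header declaring at least `fs_hz`, `rest_end`
#' and `channels` (comma-separated `label:distance_cm` pairs), optionally
#' `subject` and `condition`, followed by one row per sample and one column
#' per channel.
#'
#' @param path file to read.
#' @param min_rest_s minimum rest duration in seconds (default 20).
#' @return a validated [nirs_session()].
#' @export
read_session <- function(path, min_rest_s = 20) {
  if (!file.exists(path)) stop("no such session file: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0L || any(diff(hdr_idx) != 1L) || hdr_idx[1L] != 1L)
    stop("format error: session file must start with a '#' header block")
  hdr <- sub("^#\\s*", "", lines[hdr_idx])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
  get_field <- function(key, required = TRUE) {
    i <- match(key, trimws(keys))
    if (is.na(i)) {
      if (required) stop("format error: missing header field '", key, "'")
      return(NA_character_)
    }
    trimws(vals[i])
  }
  fs <- as.numeric(get_field("fs_hz"))
  rest_end <- as.integer(get_field("rest_end"))
  ch_str <- get_field("channels")
  subject <- get_field("subject", required = FALSE)
  condition <- get_field("condition", required = FALSE)
  if (!is.finite(fs) || is.na(rest_end)) stop("format error: fs_hz/rest_end not numeric")
  ch_pairs <- strsplit(strsplit(ch_str, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  channels <- data.frame(
    label = vapply(ch_pairs, `[`, "", 1L),
    distance = as.numeric(vapply(ch_pairs, `[`, "", 2L)),
    stringsAsFactors = FALSE)

  body <- lines[-hdr_idx]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("format error: session file has no data rows")
  sep <- if (grepl("\t", body[1L], fixed = TRUE)) "\t" else ","
  parts <- strsplit(body, sep, fixed = TRUE)
  ncols <- length(parts[[1L]])
  mat <- matrix(NA_real_, nrow = length(parts), ncol = ncols)
  for (i in seq_along(parts)) {
    row <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(row) != ncols || anyNA(row) || any(!is.finite(row))) {
      j <- which(is.na(suppressWarnings(as.numeric(parts[[i]]))) |
                   !is.finite(suppressWarnings(as.numeric(parts[[i]]))))[1L]
      stop("validation error: non-numeric or non-finite value at data row ", i,
           ", column ", if (is.na(j)) ncols else j)
    }
    mat[i, ] <- row
  }
  nirs_session(mat, fs = fs, channels = channels, rest_end = rest_end,
               subject_id = if (is.na(subject)) "" else subject,
               condition = if (is.na(condition)) "" else condition,
               min_rest_s = min_rest_s)
}

#' Write a NIRS session file
#'
#' Writes the session in the dialect read by [read_session()]. Sample
#' values are printed with 17 significant digits so the read/write round
#' trip reproduces the sample matrix bit-exactly.
#'
#' @param session a `nirs_session`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "nirs_session"))
  if (nrow(session$samples) == 0L) stop("refusing to write an empty session")
  hdr <- c(
    sprintf("# fs_hz=%.10g", session$fs),
    sprintf("# rest_end=%d", session$rest_end),
    paste0("# channels=",
           paste(sprintf("%s:%.10g", session$channels$label,
                         session$channels$distance), collapse = ",")),
    if (nzchar(session$subject_id)) paste0("# subject=", session$subject_id),
    if (nzchar(session$condition)) paste0("# condition=", session$condition))
  body <- apply(session$samples, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write session to '", path,
                                           "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Extract one channel split into rest and task segments
#'
#' @param session a `nirs_session`.
#' @param label channel label, e.g. `"L3"` (the 3 cm left channel usually
#'   carries the cortical signal; 1 cm channels mostly sample skin).
#' @return list with numeric vectors `rest` (samples `1..rest_end`) and
#'   `task` (samples `rest_end+1..N`). Concatenating the two reproduces
#'   the channel column exactly.
#' @export
select_channel <- function(session, label) {
  stopifnot(inherits(session, "nirs_session"))
  i <- match(label, session$channels$label)
  if (is.na(i))
    stop("unknown channel label '", label, "'; available: ",
         paste(session$channels$label, collapse = ", "))
  col <- session$samples[, i]
  list(rest = col[seq_len(session$rest_end)],
       task = col[(session$rest_end + 1L):nrow(session$samples)])
}
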