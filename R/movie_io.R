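# Image stacks, ROI masks and traces: the containers everything else operates on.
#
# A movie is stored as a T x Y x X numeric array in camera units with the
# acquisition metadata (frame interval, pixel size, camera black level,
# optional stimulus frame) attached.  Pixel coordinates are (frame, row, col),
# 1-based as usual in R; physical distances always go through `pixel_size`.

#' Construct a movie stack
#'
#' Bundles a T x Y x X numeric array of camera counts with its acquisition
#' metadata.  All downstream operations that return a stack propagate this
#' metadata unchanged.
#'
#' @param data numeric array with `dim = c(T, Y, X)` (time first).  A matrix is
#'   interpreted as a single-frame movie.
#' @param frame_interval seconds per frame (> 0).
#' @param pixel_size micrometres per pixel (> 0).
#' @param black_level camera black offset, in camera counts (>= 0).
#' @param t0_stimulus optional frame index (1-based) of stimulus onset.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, frame_interval, pixel_size = 1,
                        black_level = 0, t0_stimulus = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a T x Y x X array (or a single-frame matrix)")
  if (!all(is.finite(data))) stop("movie data must be finite")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a positive scalar (seconds/frame)")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a positive scalar (um/pixel)")
  if (!is.numeric(black_level) || length(black_level) != 1L || black_level < 0)
    stop("`black_level` must be a non-negative scalar (camera counts)")
  storage.mode(data) <- "double"
  structure(list(data = data,
                 frame_interval = as.numeric(frame_interval),
                 pixel_size = as.numeric(pixel_size),
                 black_level = as.numeric(black_level),
                 t0_stimulus = t0_stimulus),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames of %d x %d px\n", d[1], d[2], d[3]))
  cat(sprintf("  frame interval %.4g s (%.4g frames/s), pixel %.3g um, black %.4g\n",
              x$frame_interval, 1 / x$frame_interval, x$pixel_size,
              x$black_level))
  if (!is.null(x$t0_stimulus))
    cat(sprintf("  stimulus at frame %d (t = %.3f s)\n", x$t0_stimulus,
                (x$t0_stimulus - 1) * x$frame_interval))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

# frame times (seconds, first frame at 0)
frame_times <- function(stack) {
  (seq_len(dim(stack$data)[1]) - 1) * stack$frame_interval
}

#' Construct an ROI mask
#'
#' @param mask logical Y x X matrix with at least one `TRUE` pixel.
#' @param label optional text label.
#' @return logical matrix of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "") {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) {
    if (!is.numeric(mask)) stop("`mask` must be logical or numeric 0/1")
    mask <- mask != 0
  }
  if (!any(mask)) stop("ROI mask has no TRUE pixel")
  structure(mask, label = label, class = c("roi_mask", "matrix", "array"))
}

# validate mask against a stack; accepts plain logical matrices too
check_mask <- function(mask, stack) {
  m <- unclass(mask)
  if (!is.matrix(m) || !identical(dim(m), dim(stack$data)[2:3]))
    stop("mask shape does not match the movie's Y x X frame shape")
  if (!is.logical(m)) m <- m != 0
  if (!any(m)) stop("mask has no TRUE pixel")
  m
}

#' Construct a time-series trace
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values numeric values, same length as `times`.
#' @param units text unit label (e.g. `"dF/F0"`, `"SD (A.U.)"`).
#' @return object of class `puff_trace`.
#' @export
puff_trace <- function(times, values, units = "") {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 units = units),
            class = "puff_trace")
}

#' @export
print.puff_trace <- function(x, ...) {
  cat(sprintf("<puff_trace> %d samples over %.3f s%s\n", length(x$times),
              diff(range(x$times)),
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
plot.puff_trace <- function(x, ...,
                            xlab = "time (s)",
                            ylab = if (nzchar(x$units)) x$units else "value",
                            type = "l") {
  graphics::plot(x$times, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# trace sampling interval; errors if non-uniform beyond tolerance
trace_dt <- function(trace, tol = 1e-6) {
  dt <- diff(trace$times)
  if (length(dt) == 0L) stop("trace has fewer than 2 samples")
  if (diff(range(dt)) > tol * mean(dt)) stop("trace is not uniformly sampled")
  mean(dt)
}

#' Read a TIFF movie from disk
#'
#' Reads a single- or multi-page greyscale TIFF (16-bit integer camera output
#' or 32-bit float) into a [movie_stack].  Integer data are promoted to double
#' without any value change (no 0..1 rescaling).
#'
#' @param path TIFF file path.
#' @inheritParams movie_stack
#' @return a [movie_stack].
#' @export
read_movie <- function(path, frame_interval, pixel_size = 1,
                       black_level = 0, t0_stimulus = NULL) {
  if (!file.exists(path)) stop("cannot read movie: no such file: ", path)
  # as.is = TRUE returns raw integer counts for integer TIFFs but is not
  # supported for float pages; float data come back unscaled with as.is = FALSE
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) {
                      if (grepl("floating point", conditionMessage(e)))
                        return(tiff::readTIFF(path, all = TRUE))
                      stop("unreadable TIFF '", path, "': ",
                           conditionMessage(e))
                    })
  if (!is.list(pages)) pages <- list(pages)
  shp <- lapply(pages, dim)
  if (any(vapply(shp, length, 1L) != 2L))
    stop("only single-channel greyscale TIFF pages are supported")
  if (length(unique(vapply(shp, paste, "", collapse = "x"))) != 1L)
    stop("TIFF pages have ragged shapes; a movie must have uniform frames")
  Y <- shp[[1]][1]; X <- shp[[1]][2]; T_ <- length(pages)
  dat <- array(0, dim = c(T_, Y, X))
  for (t in seq_len(T_)) dat[t, , ] <- pages[[t]]
  movie_stack(dat, frame_interval, pixel_size, black_level, t0_stimulus)
}

#' Write a stack to disk as 32-bit float TIFF
#'
#' Values (including negatives, e.g. shot-noise-corrected SD stacks) are stored
#' as IEEE single-precision floats, so `read_movie(write_stack(x))` reproduces
#' the single-precision values exactly.  Non-finite values (the invalid edge
#' frames of SD stacks) are stored as NaN.
#'
#' @param stack a [movie_stack], [sd_stack], or T x Y x X array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  dat <- if (is.list(stack) && !is.null(stack$data)) stack$data else stack
  if (is.matrix(dat)) dat <- array(dat, dim = c(1L, nrow(dat), ncol(dat)))
  if (!is.array(dat) || length(dim(dat)) != 3L || length(dat) == 0L)
    stop("`stack` must be a non-empty T x Y x X array or stack object")
  write_float_tiff(dat, path)
  invisible(path)
}

# Minimal multi-page greyscale float32 TIFF writer (little-endian, one strip
# per page, SampleFormat = IEEE float).  The installed TIFF bindings read
# float data fine but only write values in [0,1], which would destroy
# corrected SD stacks; writing the container directly keeps the round trip
# exact to float32 precision.
write_float_tiff <- function(dat, path) {
  d <- dim(dat); T_ <- d[1]; Y <- d[2]; X <- d[3]
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)  # 3=SHORT, 4=LONG
  }
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  page_bytes <- Y * X * 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  data_off <- 8L + (seq_len(T_) - 1L) * (page_bytes + ifd_size)
  ifd_off <- data_off + page_bytes
  writeChar("II", con, nchars = 2, eos = NULL); w2(42L); w4(ifd_off[1])
  for (t in seq_len(T_)) {
    writeBin(as.vector(t(dat[t, , ])), con, size = 4, endian = "little")
    w2(n_entries)
    entry(256L, 4L, 1L, X)             # ImageWidth
    entry(257L, 4L, 1L, Y)             # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[t])   # StripOffsets
    entry(277L, 3L, 1L, 1L)            # SamplesPerPixel
    entry(278L, 4L, 1L, Y)             # RowsPerStrip
    entry(279L, 4L, 1L, page_bytes)    # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    w4(if (t < T_) ifd_off[t + 1L] else 0L)  # offset of next page's IFD
  }
  invisible(path)
}

#' Read an ROI mask from an 8-bit TIFF (non-zero = inside)
#'
#' @param path TIFF path.
#' @param label optional label.
#' @return a [roi_mask].
#' @export
read_mask <- function(path, label = "") {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  roi_mask(m != 0, label)
}

#' Save traces to CSV
#'
#' Writes one or more traces sharing a time base to a CSV file with header
#' `time_s,<name>,...` at full precision.
#'
#' @param traces a named list of [puff_trace] objects (or a single trace).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_traces <- function(traces, path) {
  if (inherits(traces, "puff_trace")) traces <- list(trace = traces)
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "puff_trace")))
    stop("`traces` must be a (list of) puff_trace object(s)")
  nms <- names(traces)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- names(traces) <- paste0("trace", seq_along(traces))
  if (anyDuplicated(nms)) stop("trace names collide: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  t0 <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(t0) || max(abs(tr$times - t0)) > 1e-9)
      stop("traces do not share a common time base")
  }
  df <- data.frame(time_s = t0, lapply(traces, `[[`, "values"),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces back from a CSV written by [save_traces()]
#'
#' @param path CSV path.
#' @param units unit label to attach to each trace.
#' @return named list of [puff_trace] objects.
#' @export
read_traces <- function(path, units = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("not a trace CSV (no time_s column)")
  cols <- setdiff(names(df), "time_s")
  out <- lapply(cols, function(nm) puff_trace(df$time_s, df[[nm]], units))
  names(out) <- cols
  out
}
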