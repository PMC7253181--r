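# Signal-conditioning primitives shared by the fluctuation pipelines:
# camera black subtraction, truncated-Gaussian spatial blur, temporal
# Butterworth band/high-pass filtering, and running boxcar moments.

#' Filter parameter set
#'
#' Defaults are the values the SD pipeline is tuned with: spatial Gaussian
#' sigma 2 px (~1 um at 0.53 um/px), temporal band 3--20 Hz, and a 20-frame
#' boxcar (160 ms at 125 frames/s).
#'
#' @param spatial_sigma Gaussian blur sigma in pixels (> 0).
#' @param band_low,band_high temporal band edges in Hz (0 < low < high).
#' @param butter_order Butterworth order per band edge (integer >= 1).
#' @param zero_phase apply the temporal filter forward-backward (zero phase,
#'   default) so SD transients stay aligned with the fluorescence trace; set
#'   `FALSE` for single-pass causal filtering.
#' @param window_frames boxcar window length in frames (>= 2).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(spatial_sigma = 2, band_low = 3, band_high = 20,
                          butter_order = 2, zero_phase = TRUE,
                          window_frames = 20) {
  if (spatial_sigma <= 0) stop("`spatial_sigma` must be > 0")
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high")
  if (butter_order < 1) stop("`butter_order` must be >= 1")
  if (window_frames < 2) stop("`window_frames` must be >= 2")
  structure(list(spatial_sigma = spatial_sigma, band_low = band_low,
                 band_high = band_high, butter_order = as.integer(butter_order),
                 zero_phase = isTRUE(zero_phase),
                 window_frames = as.integer(window_frames)),
            class = "filter_params")
}

#' Read / write filter parameters as YAML
#' @param params a [filter_params] object.
#' @param path YAML file path.
#' @return `write_filter_params` returns `path` invisibly;
#'   `read_filter_params` returns a [filter_params].
#' @export
write_filter_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_filter_params
#' @export
read_filter_params <- function(path) {
  do.call(filter_params, yaml::read_yaml(path))
}

#' Subtract the camera black offset
#'
#' @param stack a [movie_stack] (or numeric array).
#' @param black_level offset to subtract; defaults to the stack's own
#'   `black_level`.  Negative results are kept: they are noise about zero.
#' @return same type as `stack`, with `black_level` reset to 0 on stacks.
#' @export
subtract_black <- function(stack, black_level = NULL) {
  if (inherits(stack, "movie_stack")) {
    bl <- if (is.null(black_level)) stack$black_level else black_level
    if (bl < 0) stop("`black_level` must be >= 0")
    out <- stack
    out$data <- stack$data - bl
    out$black_level <- 0
    return(out)
  }
  bl <- if (is.null(black_level)) 0 else black_level
  if (bl < 0) stop("`black_level` must be >= 0")
  stack - bl
}

# 1-D Gaussian kernel truncated at `truncate` sigma and renormalized to sum 1
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  r <- floor(truncate * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# dense 1-D convolution operator with reflective (mirror-without-repeat)
# boundary; rows map source pixels to target pixels
reflect_conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  if (n < 2 && r > 0) stop("blur kernel exceeds frame dimension")
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + seq(-r, r)
    # reflect about 1 and n (mirror without repeating the edge pixel),
    # folding as often as the kernel radius requires
    while (any(src < 1L | src > n)) {
      src <- ifelse(src < 1L, 2L - src, src)
      src <- ifelse(src > n, 2L * n - src, src)
    }
    for (j in seq_along(src)) M[i, src[j]] <- M[i, src[j]] + kernel[j]
  }
  M
}

#' Spatial Gaussian blur of every frame
#'
#' Convolves each frame independently with a separable 2-D Gaussian truncated
#' at 4 sigma, using reflective borders, so frame sums are conserved away from
#' the edges.
#'
#' @param stack a [movie_stack], T x Y x X array, or single Y x X matrix.
#' @param sigma_px Gaussian sigma in pixels.
#' @param truncate kernel support radius in units of sigma (default 4).
#' @return same type as the input.
#' @export
spatial_blur <- function(stack, sigma_px, truncate = 4) {
  if (sigma_px <= 0) stop("`sigma_px` must be > 0")
  if (inherits(stack, "movie_stack") &&
      sigma_px > min(dim(stack$data)[2:3]))
    stop("blur sigma exceeds frame dimension")
  if (is.matrix(stack) && sigma_px > min(dim(stack)))
    stop("blur sigma exceeds frame dimension")
  if (is.array(stack) && length(dim(stack)) == 3L &&
      sigma_px > min(dim(stack)[2:3]))
    stop("blur sigma exceeds frame dimension")
  if (inherits(stack, "movie_stack")) {
    out <- stack
    out$data <- spatial_blur(stack$data, sigma_px, truncate)
    return(out)
  }
  was_mat <- is.matrix(stack)
  dat <- if (was_mat) array(stack, dim = c(1L, nrow(stack), ncol(stack)))
         else stack
  d <- dim(dat); T_ <- d[1]; Y <- d[2]; X <- d[3]
  k <- gaussian_kernel_1d(sigma_px, truncate)
  By <- reflect_conv_matrix(Y, k)
  Bx <- reflect_conv_matrix(X, k)
  a <- aperm(dat, c(2, 3, 1))       # Y x X x T
  dim(a) <- c(Y, X * T_)
  a <- By %*% a
  dim(a) <- c(Y, X, T_)
  a <- aperm(a, c(2, 1, 3))         # X x Y x T
  dim(a) <- c(X, Y * T_)
  a <- Bx %*% a
  dim(a) <- c(X, Y, T_)
  out <- aperm(a, c(3, 2, 1))       # T x Y x X
  if (was_mat) out[1, , ] else out
}

# --- temporal IIR machinery -------------------------------------------------

# One causal pass of an ARMA filter down each column, started from the
# steady state for the column's first value (so a constant input yields
# exactly its DC response, with no startup step transient).
iir_filter_cols <- function(filt, x) {
  b <- filt$b; a <- filt$a
  g0 <- sum(b) / sum(a)  # DC gain
  out <- apply(x, 2, function(col) {
    as.numeric(signal::filter(b, a, col,
                              init.x = rep(col[1], length(b) - 1),
                              init.y = rep(col[1] * g0, length(a) - 1)))
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = ncol(x))
  out
}

# Odd (point-reflected) padding stabilizes filtfilt edges for signals with
# non-zero ends.  The pad must outlast the filter's own ringdown, so its
# length is set from the slowest pole: |pole|^p < 1e-6.
pad_len <- function(filt, n) {
  r <- max(Mod(polyroot(rev(filt$a))))
  p <- if (r < 1 && r > 0) ceiling(log(1e-6) / log(r)) else 9L * length(filt$b)
  min(n - 1L, max(p, 3L * length(filt$b)))
}

apply_temporal_filter <- function(x, filt, zero_phase) {
  was_vec <- is.null(dim(x))
  m <- if (was_vec) matrix(x, ncol = 1) else x
  n <- nrow(m)
  p <- pad_len(filt, n)
  top <- 2 * matrix(m[1, ], p, ncol(m), byrow = TRUE) -
    m[p + 1L - seq_len(p) + 1L, , drop = FALSE]
  bot <- 2 * matrix(m[n, ], p, ncol(m), byrow = TRUE) -
    m[n - seq_len(p), , drop = FALSE]
  mp <- rbind(top, m, bot)
  y <- iir_filter_cols(filt, mp)
  if (zero_phase) {
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
    y <- iir_filter_cols(filt, y)
    y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  }
  y <- y[p + seq_len(n), , drop = FALSE]
  if (was_vec) as.numeric(y) else y
}

# dispatch helper: run `fun` (matrix T x N -> matrix) over a stack, trace,
# matrix or vector, preserving the container
map_time_series <- function(x, fun) {
  if (inherits(x, "movie_stack") || inherits(x, "sd_stack")) {
    d <- dim(x$data)
    m <- x$data; dim(m) <- c(d[1], d[2] * d[3])
    m <- fun(m)
    dim(m) <- d
    out <- x; out$data <- m
    return(out)
  }
  if (inherits(x, "puff_trace")) {
    out <- x; out$values <- as.numeric(fun(matrix(x$values, ncol = 1)))
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x); m <- x; dim(m) <- c(d[1], d[2] * d[3])
    m <- fun(m); dim(m) <- d
    return(m)
  }
  fun(x)
}

butter_checked <- function(order, w, type, fs) {
  if (any(w >= 1)) stop("cutoff frequency at or above Nyquist (", fs / 2,
                        " Hz)")
  if (any(w <= 0)) stop("cutoff frequency must be > 0")
  signal::butter(order, w, type = type)
}

#' Temporal Butterworth band-pass filter
#'
#' Filters each pixel (or the trace) along time with a digital Butterworth
#' band-pass.  With `zero_phase = TRUE` (default) the filter is applied
#' forward and backward, giving zero phase delay and a squared magnitude
#' response.  Edges are handled by odd-reflection padding.
#'
#' @param x [movie_stack], [puff_trace], T x Y x X array, T x N matrix or
#'   numeric vector (time along the first dimension).
#' @param band_low,band_high cutoff frequencies (Hz), `0 < low < high < fs/2`.
#' @param fs sampling rate (Hz).  Taken from the stack/trace when omitted.
#' @param order filter order per band edge.
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return same type as `x`.
#' @export
temporal_bandpass <- function(x, band_low = 3, band_high = 20, fs = NULL,
                              order = 2, zero_phase = TRUE) {
  fs <- infer_fs(x, fs)
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high")
  filt <- butter_checked(order, c(band_low, band_high) / (fs / 2), "pass", fs)
  check_length(x, 3 * order + 1)
  map_time_series(x, function(m) apply_temporal_filter(m, filt, zero_phase))
}

#' Temporal high-pass filter
#'
#' Single-corner Butterworth high-pass along time; used to strip the slow
#' global fluorescence rise (1 Hz corner) before spectral analysis.
#'
#' @inheritParams temporal_bandpass
#' @param cutoff corner frequency (Hz).
#' @return same type as `x`.
#' @export
temporal_highpass <- function(x, cutoff = 1, fs = NULL, order = 2,
                              zero_phase = TRUE) {
  fs <- infer_fs(x, fs)
  filt <- butter_checked(order, cutoff / (fs / 2), "high", fs)
  check_length(x, 3 * order + 1)
  map_time_series(x, function(m) apply_temporal_filter(m, filt, zero_phase))
}

infer_fs <- function(x, fs) {
  if (!is.null(fs)) return(fs)
  if (inherits(x, "movie_stack") || inherits(x, "sd_stack"))
    return(1 / x$frame_interval)
  if (inherits(x, "puff_trace")) return(1 / trace_dt(x))
  stop("`fs` must be supplied for plain arrays/vectors")
}

check_length <- function(x, nmin) {
  n <- if (inherits(x, "movie_stack") || inherits(x, "sd_stack"))
    dim(x$data)[1]
  else if (inherits(x, "puff_trace")) length(x$values)
  else if (is.array(x) && length(dim(x)) == 3L) dim(x)[1]
  else if (is.matrix(x)) nrow(x) else length(x)
  if (n <= nmin) stop("time series too short (", n, " samples) for this filter")
  invisible(n)
}

#' Running boxcar mean and variance
#'
#' For every pixel and every window position, the mean and the population
#' variance (mean of squares minus square of mean) over a `window_frames`-long
#' boxcar.  Output frames are aligned to the window centre; frames whose
#' window would be incomplete are `NA`.
#'
#' For an even window `w`, the value at frame `t` covers frames
#' `t - w/2 + 1 .. t + w/2`; valid frames are `w/2 .. T - w/2`.
#'
#' @param x stack, array, matrix or vector, time along the first axis.
#' @param window_frames boxcar length in frames (>= 2).
#' @return list with elements `mean` and `variance`, each shaped like the
#'   input data.
#' @export
running_moments <- function(x, window_frames) {
  w <- as.integer(window_frames)
  if (w < 2) stop("`window_frames` must be >= 2")
  fun <- function(m) {
    T_ <- nrow(m)
    if (w > T_) stop("`window_frames` (", w, ") exceeds record length (",
                     T_, ")")
    cs <- apply(m, 2, cumsum)
    cs2 <- apply(m * m, 2, cumsum)
    if (is.null(dim(cs))) { cs <- matrix(cs, ncol = ncol(m));
                            cs2 <- matrix(cs2, ncol = ncol(m)) }
    nwin <- T_ - w + 1L
    idx_hi <- seq_len(nwin) + w - 1L
    wsum  <- cs[idx_hi, , drop = FALSE] -
      rbind(0, cs)[idx_hi - w + 1L, , drop = FALSE]
    wsum2 <- cs2[idx_hi, , drop = FALSE] -
      rbind(0, cs2)[idx_hi - w + 1L, , drop = FALSE]
    mu <- wsum / w
    va <- pmax(wsum2 / w - mu * mu, 0)  # clamp FP negatives
    centre <- seq_len(nwin) + (w - 1L) %/% 2L
    M <- matrix(NA_real_, T_, ncol(m)); V <- M
    M[centre, ] <- mu; V[centre, ] <- va
    list(mean = M, variance = V)
  }
  if (inherits(x, "movie_stack") || inherits(x, "sd_stack")) {
    d <- dim(x$data); m <- x$data; dim(m) <- c(d[1], d[2] * d[3])
    r <- fun(m)
    dim(r$mean) <- d; dim(r$variance) <- d
    return(r)
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x); m <- x; dim(m) <- c(d[1], d[2] * d[3])
    r <- fun(m)
    dim(r$mean) <- d; dim(r$variance) <- d
    return(r)
  }
  if (is.matrix(x)) return(fun(x))
  r <- fun(matrix(x, ncol = 1))
  list(mean = as.numeric(r$mean), variance = as.numeric(r$variance))
}
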