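# Input encoders: rate (Poisson/Bernoulli) coding of static intensity images
# and time-binning of DVS-style event streams.

#' Poisson-encode a static intensity image into a spike tensor
#'
#' The standard discrete-time reading of Poisson rate coding: per pixel and
#' per timestep an independent Bernoulli draw succeeds with probability equal
#' to the pixel intensity. Deterministic given `(image, t_steps, seed)`.
#'
#' @param image Numeric vector, matrix or array of intensities in `[0, 1]`.
#' @param t_steps Encoding horizon T (number of timesteps, >= 1).
#' @param seed Integer seed; the draw is made on an isolated RNG stream so the
#'   caller's RNG state is untouched.
#'
#' @return A binary spike tensor: a `[t_steps x n_pixels]` matrix (pixels in
#'   column-major order of `image`), with the original image dimensions kept
#'   in the `"image_dim"` attribute.
#' @examples
#' img <- matrix(c(0, 1, 0.5, 0.2), 2, 2)
#' s <- poisson_encode(img, t_steps = 10, seed = 1)
#' colMeans(s)
#' @export
poisson_encode <- function(image, t_steps, seed) {
  p <- as.numeric(image)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("All intensities must lie in [0, 1].")
  }
  stopifnot(t_steps >= 1)
  n <- length(p)
  out <- withr::with_seed(as.integer(seed), {
    u <- matrix(stats::runif(t_steps * n), nrow = t_steps, ncol = n)
    (u < rep(p, each = t_steps)) * 1
  })
  # intensity-1 pixels must be all-one: runif is in (0,1) so u < 1 always holds
  attr(out, "image_dim") <- if (is.null(dim(image))) length(p) else dim(image)
  out
}

#' Construct an event stream
#'
#' An event stream is a tibble of DVS-like records with columns `t` (time,
#' in `[0, duration)`), `x` (column, 0-based), `y` (row, 0-based) and `p`
#' (polarity, 0 or 1).
#'
#' @param t,x,y,p Event record columns (equal length).
#' @return A tibble with class `event_stream`.
#' @export
event_stream <- function(t = numeric(), x = integer(), y = integer(),
                         p = integer()) {
  es <- tibble::tibble(t = as.numeric(t), x = as.integer(x),
                       y = as.integer(y), p = as.integer(p))
  if (nrow(es) && !all(es$p %in% c(0L, 1L))) {
    rlang::abort("Polarity `p` must be 0 or 1.")
  }
  class(es) <- c("event_stream", class(es))
  es
}

#' Bin an event stream into a spike tensor
#'
#' Discretizes events into `t_bins` uniform, half-open time intervals
#' `[k * duration / t_bins, (k + 1) * duration / t_bins)`, with polarity
#' separated in the channel dimension; the final instant `t == duration` maps
#' to the last bin. Each event lands in exactly one `(bin, channel, y, x)`
#' cell. By default cells are binary occupancy (counts clipped to 1) so
#' downstream layers receive spikes; `mode = "count"` keeps raw counts.
#'
#' @param stream An [event_stream()] (or data frame with columns t, x, y, p).
#' @param t_bins Number of time bins T (>= 1).
#' @param height,width Frame dimensions; `y` must lie in `0:(height-1)` and
#'   `x` in `0:(width-1)`.
#' @param duration Recording duration. Defaults to `max(t)` (or 1 for an
#'   empty stream).
#' @param mode `"binary"` (default) or `"count"`.
#'
#' @return A `[t_bins x 2 x height x width]` array; channel 1 holds polarity
#'   0, channel 2 polarity 1.
#' @examples
#' es <- event_stream(t = 0.5, x = 2, y = 1, p = 1)
#' dim(bin_events(es, t_bins = 4, height = 3, width = 4, duration = 1))
#' @export
bin_events <- function(stream, t_bins, height, width, duration = NULL,
                       mode = c("binary", "count")) {
  mode <- match.arg(mode)
  stopifnot(t_bins >= 1, height >= 1, width >= 1)
  out <- array(0, dim = c(t_bins, 2L, height, width))
  if (nrow(stream) == 0L) {
    return(out)
  }
  bad <- stream$x < 0 | stream$x >= width | stream$y < 0 | stream$y >= height
  if (any(bad)) {
    i <- which(bad)[1L]
    rlang::abort(sprintf(
      "Event %d out of bounds: (t=%g, x=%d, y=%d, p=%d) for a %dx%d frame.",
      i, stream$t[i], stream$x[i], stream$y[i], stream$p[i], height, width
    ))
  }
  if (is.null(duration)) duration <- max(stream$t)
  if (duration <= 0) duration <- 1
  if (any(stream$t < 0 | stream$t > duration)) {
    rlang::abort("Event times must lie within [0, duration].")
  }
  bin <- pmin(floor(stream$t / duration * t_bins), t_bins - 1) + 1
  idx <- cbind(bin, stream$p + 1L, stream$y + 1L, stream$x + 1L)
  # accumulate counts cell-by-cell (duplicate indices must add, not overwrite)
  flat <- (idx[, 1] - 1) + t_bins * ((idx[, 2] - 1) +
    2 * ((idx[, 3] - 1) + height * (idx[, 4] - 1))) + 1
  counts <- tabulate(flat, nbins = length(out))
  out[] <- counts
  if (mode == "binary") out <- pmin(out, 1)
  out
}

#' Read / write event streams as CSV
#'
#' Plain-text interchange for event streams: a CSV with header `t,x,y,p`.
#'
#' @param stream An [event_stream()].
#' @param path File path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   an [event_stream()].
#' @export
write_events <- function(stream, path) {
  readr::write_csv(tibble::as_tibble(unclass(stream))[c("t", "x", "y", "p")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t = readr::col_double(), x = readr::col_integer(),
    y = readr::col_integer(), p = readr::col_integer()
  ), progress = FALSE)
  event_stream(df$t, df$x, df$y, df$p)
}
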