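#' Construct an AER event stream
#'
#' An event stream is the universal input currency of the package: an ordered
#' set of address events \code{(t, x, y, p)} on a \code{width} x \code{height}
#' pixel array. Timestamps \code{t} are integer microseconds, addresses are
#' 0-based with \code{x} increasing rightward and \code{y} increasing downward
#' (image convention), and polarity \code{p} is +1 for ON (brightening) and
#' -1 for OFF (darkening).
#'
#' @param events data.frame with columns \code{t}, \code{x}, \code{y},
#'   \code{p} (any order; extra columns dropped). May have zero rows.
#' @param width,height sensor array dimensions in pixels.
#' @param sort sort events by timestamp (stable) if they are not already
#'   non-decreasing.
#' @return An object of class \code{"event_stream"}: a list with elements
#'   \code{width}, \code{height} and \code{events}.
#' @examples
#' ev <- data.frame(t = c(0L, 5L), x = c(3L, 4L), y = c(2L, 2L), p = c(1L, -1L))
#' s <- event_stream(ev, width = 8, height = 8)
#' n_events(s)
#' @export
event_stream <- function(events, width, height, sort = TRUE) {
  stopifnot(width >= 1, height >= 1)
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(t = integer(0), x = integer(0),
                         y = integer(0), p = integer(0))
  }
  req <- c("t", "x", "y", "p")
  if (!all(req %in% names(events)))
    stop("events must have columns t, x, y, p")
  events <- events[req]
  events$t <- as.integer(round(events$t))
  events$x <- as.integer(events$x)
  events$y <- as.integer(events$y)
  events$p <- as.integer(events$p)
  if (any(events$t < 0)) stop("negative timestamp")
  bad <- events$x < 0 | events$x >= width | events$y < 0 | events$y >= height
  if (any(bad))
    stop(sprintf("event address out of bounds at row %d: (%d, %d) on %dx%d",
                 which(bad)[1], events$x[which(bad)[1]], events$y[which(bad)[1]],
                 width, height))
  if (!all(events$p %in% c(-1L, 1L))) stop("polarity must be +1 or -1")
  if (sort && is.unsorted(events$t)) {
    events <- events[order(events$t), , drop = FALSE]  # stable in R
  }
  rownames(events) <- NULL
  structure(list(width = as.integer(width), height = as.integer(height),
                 events = events),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("AER event stream: %d events on a %dx%d array\n",
              nrow(x$events), x$width, x$height))
  if (nrow(x$events) > 0) {
    cat(sprintf("  time span: %d..%d us; ON %d / OFF %d\n",
                min(x$events$t), max(x$events$t),
                sum(x$events$p == 1L), sum(x$events$p == -1L)))
  }
  invisible(x)
}

#' @rdname event_stream
#' @param stream an \code{event_stream}.
#' @export
n_events <- function(stream) nrow(stream$events)

#' Read and write event streams as CSV
#'
#' The on-disk format is a plain CSV with header \code{t,x,y,p}: integer
#' microsecond timestamps and polarity coded +1/-1. Round trips are lossless.
#'
#' @param path file path.
#' @param width,height sensor dimensions (not stored in the file).
#' @return \code{read_events_csv} returns an \code{event_stream};
#'   \code{write_events_csv} returns \code{path} invisibly.
#' @export
read_events_csv <- function(path, width, height) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, colClasses = "integer"),
                 error = function(e) stop("malformed event CSV '", path, "': ",
                                          conditionMessage(e)))
  if (nrow(df) > 0 && anyNA(df))
    stop("malformed row ", which(apply(is.na(df), 1, any))[1] + 1L,
         " in ", path)
  event_stream(df, width, height)
}

#' @rdname read_events_csv
#' @param stream an \code{event_stream}.
#' @export
write_events_csv <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  write.csv(stream$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a jAER AEDAT 2.0 recording
#'
#' Minimal reader for the jAER ".aedat" 2.0 format: an ASCII header of lines
#' starting with \code{#}, followed by big-endian 32-bit (address, timestamp)
#' pairs. The default bit layout is the DVS128 convention: polarity in bit 0,
#' x in bits 1-7, y in bits 8-14. Raw DVS x addresses increase leftward, so x
#' is flipped to the package's rightward convention.
#'
#' @param path file path.
#' @param width,height sensor dimensions (DVS128: 128 x 128).
#' @param x_shift,x_mask,y_shift,y_mask,p_shift bit layout of the address word.
#' @return An \code{event_stream}.
#' @export
read_events_aedat <- function(path, width = 128, height = 128,
                              x_shift = 1L, x_mask = 0x7fL,
                              y_shift = 8L, y_mask = 0x7fL,
                              p_shift = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # skip '#' header lines (each terminated by \r\n or \n)
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0L || !startsWith(line, "#")) {
      seek(con, pos)
      break
    }
  }
  raw <- readBin(con, "integer", n = file.size(path), size = 4,
                 endian = "big", signed = TRUE)
  if (length(raw) %% 2L != 0L) raw <- raw[-length(raw)]
  if (length(raw) == 0L)
    return(event_stream(NULL, width, height))
  addr <- raw[seq(1, length(raw), by = 2)]
  ts <- raw[seq(2, length(raw), by = 2)]
  x_raw <- bitwAnd(bitwShiftR(addr, x_shift), x_mask)
  y <- bitwAnd(bitwShiftR(addr, y_shift), y_mask)
  pol <- bitwAnd(bitwShiftR(addr, p_shift), 1L)
  event_stream(data.frame(t = ts, x = width - 1L - x_raw, y = y,
                          p = ifelse(pol == 1L, 1L, -1L)),
               width, height)
}

#' Encoding configuration for image-derived event streams
#'
#' Bundles the parameters of the image-to-events conversion: the column
#' differencing interval, the encoding method and its parameters, and the
#' timing model used by [assign_timestamps()].
#'
#' @param method \code{"one_per_pixel"} (each supra-threshold pixel emits one
#'   event) or \code{"gray_level"} (0-16 events proportional to gray level).
#' @param threshold gray-unit threshold for \code{one_per_pixel}.
#' @param max_events_per_pixel event count corresponding to gray 255 under
#'   \code{gray_level} encoding.
#' @param difference_interval column offset of the differencing step.
#' @param column_dt microseconds between successive column emissions.
#' @param seed integer seed for the intra-column event shuffle.
#' @return A list of class \code{"encoding_config"}.
#' @export
encoding_config <- function(method = c("one_per_pixel", "gray_level"),
                            threshold = 10, max_events_per_pixel = 16L,
                            difference_interval = 3L, column_dt = 1L,
                            seed = 1L) {
  method <- match.arg(method)
  stopifnot(threshold > 0, max_events_per_pixel >= 1,
            difference_interval >= 1, column_dt > 0)
  structure(list(method = method, threshold = threshold,
                 max_events_per_pixel = as.integer(max_events_per_pixel),
                 difference_interval = as.integer(difference_interval),
                 column_dt = as.integer(column_dt), seed = as.integer(seed)),
            class = "encoding_config")
}

#' Column differencing of a grayscale image
#'
#' Emulates the intensity change seen by an event camera as an object sweeps
#' horizontally: each column is replaced by the difference between the column
#' \code{interval} positions to its right and itself, so output column c is
#' input column (c + interval) minus input column c. The last \code{interval}
#' columns, which have no partner, are set to 0 so the image size is
#' unchanged.
#'
#' @param image numeric matrix (rows = y, columns = x), gray values.
#' @param interval column offset, default 3.
#' @return A signed matrix of the same dimensions.
#' @export
difference_image <- function(image, interval = 3L) {
  stopifnot(is.matrix(image), interval >= 1)
  w <- ncol(image)
  if (interval >= w) stop("interval must be smaller than image width")
  out <- matrix(0, nrow(image), w)
  idx <- seq_len(w - interval)
  out[, idx] <- image[, idx + interval] - image[, idx]
  out
}

#' Encode a signed difference image as events
#'
#' Two encodings are supported. \code{encode_one_per_pixel}: each pixel whose
#' value exceeds \code{+threshold} emits a single ON event and each below
#' \code{-threshold} a single OFF event. \code{encode_gray_level}: each pixel
#' of magnitude g in 0..255 emits \code{round(g * 16/255)} events of the
#' sign-matching polarity (so gray 255 yields 16 events), all at the same
#' address. Halves round away from zero. Timestamps are then assigned by
#' [assign_timestamps()].
#'
#' @param dimage signed numeric matrix (output of [difference_image()]).
#' @param config an [encoding_config()].
#' @return An \code{event_stream}.
#' @export
encode_one_per_pixel <- function(dimage, config = encoding_config()) {
  stopifnot(is.matrix(dimage))
  on_idx <- which(dimage > config$threshold, arr.ind = TRUE)
  off_idx <- which(dimage < -config$threshold, arr.ind = TRUE)
  addr <- data.frame(
    x = c(on_idx[, 2], off_idx[, 2]) - 1L,
    y = c(on_idx[, 1], off_idx[, 1]) - 1L,
    p = rep(c(1L, -1L), c(nrow(on_idx), nrow(off_idx))))
  assign_timestamps(addr, ncol(dimage), nrow(dimage), config)
}

#' @rdname encode_one_per_pixel
#' @export
encode_gray_level <- function(dimage, config = encoding_config("gray_level")) {
  stopifnot(is.matrix(dimage))
  if (any(abs(dimage) > 255)) stop("gray magnitudes must lie in [0, 255]")
  g <- abs(dimage)
  # round half away from zero (base round() is half-to-even)
  n <- floor(g * config$max_events_per_pixel / 255 + 0.5)
  idx <- which(n > 0, arr.ind = TRUE)
  reps <- n[idx]
  addr <- data.frame(
    x = rep(idx[, 2] - 1L, reps),
    y = rep(idx[, 1] - 1L, reps),
    p = rep(ifelse(dimage[idx] > 0, 1L, -1L), reps))
  assign_timestamps(addr, ncol(dimage), nrow(dimage), config)
}

#' Assign column-sweep timestamps to address events
#'
#' Image-derived events carry no natural timestamps. This model emulates an
#' object sweeping right to left across the array: all events of column x are
#' emitted at time \code{(width - 1 - x) * column_dt}, so the rightmost column
#' fires first. Within a column the emission order is shuffled with the
#' config seed, emulating the arbiter's arbitrary ordering of simultaneous
#' requests.
#'
#' @param addresses data.frame with columns \code{x}, \code{y}, \code{p}.
#' @param width,height array dimensions.
#' @param config an [encoding_config()] (uses \code{column_dt} and
#'   \code{seed}).
#' @return A time-sorted \code{event_stream}.
#' @export
assign_timestamps <- function(addresses, width, height,
                              config = encoding_config()) {
  stopifnot(config$column_dt > 0)
  if (nrow(addresses) == 0L)
    return(event_stream(NULL, width, height))
  addresses$t <- (width - 1L - addresses$x) * config$column_dt
  perm <- with_seed(config$seed, sample.int(nrow(addresses)))
  addresses <- addresses[perm, , drop = FALSE]
  event_stream(addresses, width, height)  # stable sort keeps shuffle in-column
}

#' Zero-pad an image onto a larger square canvas
#'
#' A 28 x 28 sample rotated by 45 degrees needs a canvas of side
#' ceiling(28 * sqrt(2)) = 40 to avoid clipping, so all samples are placed at
#' the center of a 40 x 40 zero background before any rotation.
#'
#' @param image numeric matrix, \code{from} x \code{from}.
#' @param from,to input and output side lengths.
#' @return A \code{to} x \code{to} matrix with \code{image} centered.
#' @export
pad_to_canvas <- function(image, from = 28L, to = 40L) {
  if (!is.matrix(image) || nrow(image) != from || ncol(image) != from)
    stop(sprintf("expected a %dx%d image", from, from))
  off <- (to - from) %/% 2L
  out <- matrix(0, to, to)
  out[off + seq_len(from), off + seq_len(from)] <- image
  out
}

# Rotate 0-based pixel addresses about the canvas center ((W-1)/2, (H-1)/2)
# by `angle_deg`, nearest-neighbor rounding. The rotation sense is the one
# that carries motion along -x into motion at deviation angle `angle_deg`
# (clockwise off the -x axis, y pointing down): x' = x cosA + y sinA,
# y' = -x sinA + y cosA in centered coordinates. Returns a data.frame
# (x, y), possibly out of bounds; callers drop or mark those.
rotate_addresses <- function(x, y, angle_deg, width, height) {
  a <- angle_deg * pi / 180
  cx <- (width - 1) / 2
  cy <- (height - 1) / 2
  u <- x - cx
  v <- y - cy
  data.frame(x = as.integer(round(u * cos(a) + v * sin(a) + cx)),
             y = as.integer(round(-u * sin(a) + v * cos(a) + cy)))
}

#' Rotate an event stream about the canvas center
#'
#' Each event address is rotated about the canvas center
#' \code{((W-1)/2, (H-1)/2)} with nearest-neighbor rounding; events landing
#' outside the array are dropped. Timestamps and polarities are unchanged.
#' The rotation sense matches the deviation-angle convention: rotating a
#' stream recorded at the reference orientation (motion toward -x) by
#' \code{angle_deg} yields the address pattern of a sample moving at
#' deviation angle \code{angle_deg}.
#'
#' @param stream an \code{event_stream} on a square canvas.
#' @param angle_deg rotation angle in degrees.
#' @return An \code{event_stream}.
#' @export
rotate_events <- function(stream, angle_deg) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$events
  if (nrow(ev) == 0L) return(stream)
  r <- rotate_addresses(ev$x, ev$y, angle_deg, stream$width, stream$height)
  keep <- r$x >= 0 & r$x < stream$width & r$y >= 0 & r$y < stream$height
  ev$x <- r$x
  ev$y <- r$y
  event_stream(ev[keep, , drop = FALSE], stream$width, stream$height,
               sort = FALSE)
}

#' Rotate a grayscale image about its center
#'
#' Inverse-mapped nearest-neighbor rotation on the same center and rotation
#' convention as [rotate_events()]: output pixel (x, y) takes the value of
#' the input pixel found by rotating (x, y) by \code{-angle_deg}. Pixels
#' mapping outside the input are 0.
#'
#' @param image numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @return A matrix of the same dimensions.
#' @export
rotate_image <- function(image, angle_deg) {
  h <- nrow(image); w <- ncol(image)
  grid <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  src <- rotate_addresses(grid$x, grid$y, -angle_deg, w, h)
  ok <- src$x >= 0 & src$x < w & src$y >= 0 & src$y < h
  out <- matrix(0, h, w)
  out[cbind(grid$y + 1L, grid$x + 1L)[ok, , drop = FALSE]] <-
    image[cbind(src$y + 1L, src$x + 1L)[ok, , drop = FALSE]]
  out
}

#' Convert a grayscale image to an event stream
#'
#' Convenience wrapper chaining [pad_to_canvas()] (if the image is 28 x 28),
#' [difference_image()], and the encoding selected in \code{config}.
#'
#' @param image numeric matrix of gray values.
#' @param config an [encoding_config()].
#' @return An \code{event_stream}.
#' @export
image_to_events <- function(image, config = encoding_config()) {
  if (nrow(image) == 28L && ncol(image) == 28L)
    image <- pad_to_canvas(image)
  d <- difference_image(image, config$difference_interval)
  if (config$method == "one_per_pixel") encode_one_per_pixel(d, config)
  else encode_gray_level(d, config)
}
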