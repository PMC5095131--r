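#' Gabor convolution kernel
#'
#' Builds one even-phase (cosine) Gabor kernel of side \code{s} pixels tuned
#' to orientation \code{theta}. With centered offsets (x', y') and the
#' rotated frame X = x' cos(theta) + y' sin(theta),
#' Y = -x' sin(theta) + y' cos(theta), the raw weight is
#' exp(-(X^2 + gamma^2 Y^2) / (2 sigma^2)) * cos(2 pi X / lambda).
#' The matrix is then shifted to zero mean and scaled to unit L2 norm so
#' response magnitudes are comparable across kernel sizes.
#'
#' The envelope and wavelength follow the standard cortical S1
#' parameterization, sigma = 0.0036 s^2 + 0.35 s + 0.18 and
#' lambda = sigma / 0.8, extended down to sizes 3 and 5; gamma = 0.3.
#'
#' @param s kernel side, odd, one of 3, 5, 7, 9.
#' @param theta orientation in degrees, one of 0, 45, 90, 135. 0 degrees
#'   responds to edges along x (the carrier varies along x).
#' @param gamma aspect ratio of the Gaussian envelope.
#' @return An s x s numeric matrix (rows = y offsets, columns = x offsets)
#'   with attributes \code{s}, \code{theta}, \code{sigma}, \code{lambda}.
#' @examples
#' k <- make_gabor_kernel(7, 90)
#' all.equal(sum(k), 0)
#' @export
make_gabor_kernel <- function(s, theta, gamma = 0.3) {
  if (!(s %in% c(3L, 5L, 7L, 9L))) stop("kernel size must be 3, 5, 7 or 9")
  if (!(theta %in% c(0, 45, 90, 135))) stop("theta must be 0, 45, 90 or 135")
  sigma <- 0.0036 * s^2 + 0.35 * s + 0.18
  lambda <- sigma / 0.8
  r <- (s - 1L) / 2L
  off <- seq(-r, r)
  xs <- matrix(off, s, s, byrow = TRUE)   # x offset varies along columns
  ys <- matrix(off, s, s)                 # y offset varies along rows
  a <- theta * pi / 180
  X <- xs * cos(a) + ys * sin(a)
  Y <- -xs * sin(a) + ys * cos(a)
  w <- exp(-(X^2 + gamma^2 * Y^2) / (2 * sigma^2)) * cos(2 * pi * X / lambda)
  w <- w - mean(w)
  w <- w / sqrt(sum(w^2))
  structure(w, s = s, theta = theta, sigma = sigma, lambda = lambda)
}

#' The 16-kernel S1 filter bank
#'
#' All combinations of four scales (3, 5, 7, 9 pixels) and four orientations
#' (0, 45, 90, 135 degrees). Kernel order is scale-fastest: (s=3, 0deg),
#' (s=5, 0deg), ..., (s=9, 135deg). Per event polarity each kernel feeds its
#' own feature map, giving 32 maps in total.
#'
#' @param scales,thetas kernel sizes and orientations.
#' @return A list of class \code{"gabor_bank"}; elements are
#'   [make_gabor_kernel()] matrices, with attributes \code{scales} and
#'   \code{thetas} giving the per-kernel labels.
#' @export
gabor_bank <- function(scales = c(3L, 5L, 7L, 9L), thetas = c(0, 45, 90, 135)) {
  grid <- expand.grid(s = scales, theta = thetas)
  bank <- mapply(make_gabor_kernel, grid$s, grid$theta, SIMPLIFY = FALSE)
  structure(bank, scales = grid$s, thetas = grid$theta, class = "gabor_bank")
}

#' Export a kernel bank as a flat table
#'
#' One row per kernel weight: \code{s, theta, dy, dx, w}, for inspection and
#' regression testing.
#'
#' @param bank a [gabor_bank()].
#' @return A data.frame.
#' @export
bank_to_table <- function(bank) {
  do.call(rbind, lapply(bank, function(k) {
    s <- attr(k, "s"); r <- (s - 1L) / 2L
    off <- seq(-r, r)
    data.frame(s = s, theta = attr(k, "theta"),
               dy = rep(off, s), dx = rep(off, each = s), w = as.vector(k))
  }))
}

#' S1 feature-map stack
#'
#' Mutable container for the 32 S1 response maps (4 scales x 4 orientations
#' x 2 polarities) with the bookkeeping needed by the forgetting mechanism:
#' every cell decays linearly toward zero at \code{leak} response-units per
#' second of elapsed stream time, and stops at zero. Maps 1-16 accumulate ON
#' events, maps 17-32 OFF events; within a polarity the kernel order is that
#' of [gabor_bank()].
#'
#' \code{s1_new_stack} creates an empty stack; [s1_apply_event()] and
#' [s1_decay()] mutate it in place (it is an environment). For whole streams
#' use the fast path [s1_response()].
#'
#' @param width,height canvas size in pixels.
#' @param bank a [gabor_bank()].
#' @param leak decay rate in response-units per second (paper value 5e4).
#' @return An environment of class \code{"s1_stack"} with fields \code{maps}
#'   (H x W x 32 array), \code{time} (current time, us), \code{bank},
#'   \code{leak}, \code{width}, \code{height}.
#' @export
s1_new_stack <- function(width, height, bank = gabor_bank(), leak = 5e4) {
  st <- new.env(parent = emptyenv())
  st$maps <- array(0, dim = c(height, width, 2L * length(bank)))
  st$time <- 0
  st$bank <- bank
  st$leak <- leak
  st$width <- as.integer(width)
  st$height <- as.integer(height)
  class(st) <- "s1_stack"
  st
}

#' Apply the linear forgetting decay to a feature stack
#'
#' Advances the stack clock to \code{t_now} (microseconds), shrinking every
#' cell's magnitude by \code{leak * dt} (dt in seconds) with a floor at zero;
#' values never change sign. Stepping the decay through intermediate times is
#' exactly equivalent to one decay over the total interval, so a single
#' whole-stack sweep at each time advance reproduces per-cell lazy decay.
#'
#' @param stack an [s1_new_stack()] environment.
#' @param t_now target time in microseconds; must be >= the stack clock.
#' @return The stack, invisibly.
#' @export
s1_decay <- function(stack, t_now) {
  if (t_now < stack$time) stop("time must be monotone non-decreasing")
  dec <- stack$leak * (t_now - stack$time) * 1e-6
  if (dec > 0) {
    m <- stack$maps
    stack$maps <- sign(m) * pmax(abs(m) - dec, 0)
    stack$time <- t_now
  }
  invisible(stack)
}

#' Route one event through the S1 filter bank
#'
#' Decays the stack to the event time, then adds every kernel of the bank,
#' centered at the event address and clipped at the canvas borders, to the
#' feature map of matching (scale, orientation, polarity).
#'
#' @param stack an [s1_new_stack()] environment.
#' @param t,x,y,p event fields (us, 0-based address, +1/-1).
#' @return The stack, invisibly.
#' @export
s1_apply_event <- function(stack, t, x, y, p) {
  s1_decay(stack, t)
  base <- if (p == 1L) 0L else length(stack$bank)
  for (k in seq_along(stack$bank)) {
    km <- stack$bank[[k]]
    s <- nrow(km)
    r <- (s - 1L) %/% 2L
    xs <- (x - r):(x + r)
    ys <- (y - r):(y + r)
    okx <- xs >= 0 & xs < stack$width
    oky <- ys >= 0 & ys < stack$height
    if (!any(okx) || !any(oky)) next
    stack$maps[ys[oky] + 1L, xs[okx] + 1L, base + k] <-
      stack$maps[ys[oky] + 1L, xs[okx] + 1L, base + k] +
      km[oky, okx, drop = FALSE]
  }
  invisible(stack)
}

#' S1 response maps for a whole event stream
#'
#' Fast path: runs the event-driven convolution with forgetting over all
#' events of a time-sorted stream (compiled loop) and returns the 32 maps
#' decayed to the final event time. Identical to feeding each event through
#' [s1_apply_event()].
#'
#' @param stream an [event_stream()].
#' @param bank a [gabor_bank()].
#' @param leak decay rate in response-units per second.
#' @return An H x W x 32 array; ON maps 1-16, OFF maps 17-32, kernel order
#'   as in the bank.
#' @export
s1_response <- function(stream, bank = gabor_bank(), leak = 5e4) {
  ev <- stream$events
  v <- s1_accumulate_cpp(ev$t, ev$x, ev$y, ev$p,
                         stream$width, stream$height, bank, leak)
  array(v, dim = c(stream$height, stream$width, 2L * length(bank)))
}
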