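#' Build the 8-class address lookup table
#'
#' For each orientation class m in 1..8 the LUT maps every grid address to
#' the address obtained by rotating it about the canvas center by
#' -45 (m - 1) degrees (nearest-neighbor rounding), i.e. the rotation that
#' carries a class-m-moving sample's addresses back to the reference
#' orientation. Targets falling outside the canvas are dropped. Class 1 is
#' the identity; classes 3, 5 and 7 (multiples of 90 degrees) are exact
#' permutations of the grid.
#'
#' @param width,height canvas size in pixels.
#' @return A list of class \code{"address_lut"} with 8 elements; element m
#'   is a list of two H x W integer matrices \code{x2}, \code{y2} (0-based
#'   target addresses indexed by \code{[y + 1, x + 1]}, \code{NA} = drop).
#' @export
build_address_lut <- function(width, height) {
  stopifnot(width > 0, height > 0)
  grid <- expand.grid(x = 0:(width - 1), y = 0:(height - 1))
  lut <- lapply(1:8, function(m) {
    r <- rotate_addresses(grid$x, grid$y, -45 * (m - 1), width, height)
    drop <- r$x < 0 | r$x >= width | r$y < 0 | r$y >= height
    r$x[drop] <- NA_integer_
    r$y[drop] <- NA_integer_
    idx <- cbind(grid$y + 1L, grid$x + 1L)
    x2 <- matrix(NA_integer_, height, width); x2[idx] <- r$x
    y2 <- matrix(NA_integer_, height, width); y2[idx] <- r$y
    list(x2 = x2, y2 = y2)
  })
  structure(lut, width = as.integer(width), height = as.integer(height),
            class = "address_lut")
}

#' Apply a class-m LUT to raw addresses
#'
#' @param lut an [build_address_lut()] object.
#' @param m orientation class 1..8.
#' @param x,y 0-based addresses.
#' @return data.frame \code{x}, \code{y} with \code{NA} for dropped
#'   addresses.
#' @export
lut_map <- function(lut, m, x, y) {
  idx <- cbind(y + 1L, x + 1L)
  data.frame(x = lut[[m]]$x2[idx], y = lut[[m]]$y2[idx])
}

#' Serialize an address LUT to CSV
#'
#' Format: \code{class,x,y,x2,y2} with dropped targets written as
#' \code{-1,-1}, for inspection and bit-exact regression tests.
#'
#' @param lut an [build_address_lut()] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_address_lut <- function(lut, path) {
  w <- attr(lut, "width"); h <- attr(lut, "height")
  grid <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  rows <- do.call(rbind, lapply(1:8, function(m) {
    r <- lut_map(lut, m, grid$x, grid$y)
    r$x[is.na(r$x)] <- -1L
    r$y[is.na(r$y)] <- -1L
    data.frame(class = m, x = grid$x, y = grid$y, x2 = r$x, y2 = r$y)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Reorder orientation maps for a detected class
#'
#' When a sample is rotated by 45 (m - 1) degrees, its line features move
#' between orientation maps: the canonical orientation theta_c of the
#' reference frame is fed by the observed map theta_obs =
#' (theta_c + 45 ((m - 1) mod 4)) mod 180 (line orientations are
#' 180-degree periodic, so classes 5..8 reorder exactly like 1..4). This
#' relabels each peak's theta accordingly; scale and value are unchanged.
#'
#' @param peaks a [peak_set()].
#' @param m orientation class 1..8.
#' @return A [peak_set()] with remapped orientation labels.
#' @export
reorder_maps <- function(peaks, m) {
  stopifnot(m %in% 1:8)
  shift <- 45 * ((m - 1) %% 4)
  out <- as.data.frame(peaks)
  out$theta <- (out$theta - shift) %% 180
  peak_set(out, attr(peaks, "width"), attr(peaks, "height"))
}

#' Remap C1 peaks back to the reference orientation
#'
#' Applies [reorder_maps()] and then maps each peak's spatial address
#' through the class-m LUT. Peaks whose target falls off the canvas are
#' dropped; if two peaks land on the same (s, theta, x, y) the larger value
#' is kept.
#'
#' @param peaks a [peak_set()].
#' @param m orientation class 1..8.
#' @param lut an [build_address_lut()] for the same canvas.
#' @return A [peak_set()]; never larger than the input.
#' @export
remap_peaks <- function(peaks, m, lut) {
  stopifnot(m %in% 1:8)
  out <- as.data.frame(reorder_maps(peaks, m))
  if (nrow(out) > 0L) {
    r <- lut_map(lut, m, out$x, out$y)
    out$x <- r$x
    out$y <- r$y
    out <- out[!is.na(out$x) & !is.na(out$y), , drop = FALSE]
    out <- collapse_max(out)
    out <- out[order(out$s, out$theta, out$y, out$x), , drop = FALSE]
  }
  peak_set(out, attr(peaks, "width"), attr(peaks, "height"))
}
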