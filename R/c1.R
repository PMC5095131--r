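#' Local MAX pooling of an S1 map
#'
#' Returns the cells that dominate their own s x s neighborhood (clipped at
#' the borders): cells with a positive value that is >= every value in the
#' window. When several cells of one window tie for its maximum, only the
#' one with the lexicographically smallest (y, x) survives, which makes the
#' output deterministic on plateaus.
#'
#' @param map numeric H x W matrix.
#' @param s odd neighborhood side (the size of the kernel that produced the
#'   map).
#' @return A data.frame with columns \code{x}, \code{y} (0-based) and
#'   \code{value}, ordered by (y, x).
#' @export
max_pool <- function(map, s) {
  stopifnot(is.matrix(map), s %% 2 == 1)
  h <- nrow(map); w <- ncol(map)
  r <- (s - 1L) %/% 2L
  # window max by separable running max over +-r shifts
  shift <- function(m, dy, dx) {
    out <- matrix(-Inf, nrow(m), ncol(m))
    ys <- seq_len(nrow(m)) + dy
    xs <- seq_len(ncol(m)) + dx
    oky <- ys >= 1 & ys <= nrow(m)
    okx <- xs >= 1 & xs <= ncol(m)
    out[oky, okx] <- m[ys[oky], xs[okx]]
    out
  }
  rowmax <- map
  for (d in seq_len(r)) rowmax <- pmax(rowmax, shift(map, d, 0), shift(map, -d, 0))
  winmax <- rowmax
  for (d in seq_len(r)) winmax <- pmax(winmax, shift(rowmax, 0, d), shift(rowmax, 0, -d))
  cand <- which(map > 0 & map >= winmax, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cy <- cand[i, 1]; cx <- cand[i, 2]
    win <- map[max(1, cy - r):min(h, cy + r), max(1, cx - r):min(w, cx + r),
               drop = FALSE]
    ties <- which(win == map[cy, cx], arr.ind = TRUE)
    ty <- ties[, 1] + max(1, cy - r) - 1L
    tx <- ties[, 2] + max(1, cx - r) - 1L
    first <- order(ty, tx)[1]
    keep[i] <- (ty[first] == cy && tx[first] == cx)
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(x = cand[, 2] - 1L, y = cand[, 1] - 1L,
                    value = map[cand])
  out[order(out$y, out$x), , drop = FALSE]
}

#' Construct a peak set
#'
#' A peak set holds the C1 responses that survive MAX pooling, threshold
#' comparison and ON/OFF superposition: rows of (s, theta, x, y, value) over
#' the 16 (scale, orientation) maps.
#'
#' @param peaks data.frame with columns \code{s}, \code{theta}, \code{x},
#'   \code{y}, \code{value}.
#' @param width,height canvas size.
#' @return A data.frame of class \code{"peak_set"} with attributes
#'   \code{width} and \code{height}.
#' @export
peak_set <- function(peaks, width, height) {
  if (is.null(peaks) || nrow(peaks) == 0L)
    peaks <- data.frame(s = integer(0), theta = numeric(0), x = integer(0),
                        y = integer(0), value = numeric(0))
  peaks <- peaks[c("s", "theta", "x", "y", "value")]
  rownames(peaks) <- NULL
  structure(peaks, width = as.integer(width), height = as.integer(height),
            class = c("peak_set", "data.frame"))
}

#' Threshold comparison for peak responses
#'
#' Keeps only peaks strictly greater than the threshold ("superior to the
#' threshold" read as strict), filtering out weak responses and background
#' noise.
#'
#' @param peaks a [peak_set()] or compatible data.frame.
#' @param c1_threshold response-unit threshold (paper value 0.1).
#' @return The filtered peak set.
#' @export
threshold_filter <- function(peaks, c1_threshold = 0.1) {
  stopifnot(c1_threshold >= 0)
  out <- peaks[peaks$value > c1_threshold, , drop = FALSE]
  peak_set(out, attr(peaks, "width"), attr(peaks, "height"))
}

# Collapse duplicate (s, theta, x, y) rows keeping the largest value.
collapse_max <- function(df) {
  if (nrow(df) < 2L) return(df)
  key <- paste(df$s, df$theta, df$x, df$y)
  df <- df[order(key, -df$value), , drop = FALSE]
  df[!duplicated(paste(df$s, df$theta, df$x, df$y)), , drop = FALSE]
}

#' Superpose ON and OFF peak sets
#'
#' Surviving peaks from the two polarities are merged per (scale,
#' orientation) map, reducing 32 maps to 16. If both polarities produce a
#' peak at the same (s, theta, x, y) the larger value is kept (C1 is a MAX
#' stage; summing would double-count an edge seen by both polarities).
#'
#' @param on_peaks,off_peaks peak sets from matching canvases.
#' @return A [peak_set()].
#' @export
superpose <- function(on_peaks, off_peaks) {
  w <- attr(on_peaks, "width") %||% attr(off_peaks, "width")
  h <- attr(on_peaks, "height") %||% attr(off_peaks, "height")
  both <- rbind(as.data.frame(on_peaks), as.data.frame(off_peaks))
  out <- collapse_max(both)
  out <- out[order(out$s, out$theta, out$y, out$x), , drop = FALSE]
  peak_set(out, w, h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Keep the strongest peaks
#'
#' Selects the \code{top_k} largest values across all 16 maps (fewer if
#' fewer exist). Ties at the cutoff are broken by (s, theta, y, x)
#' lexicographic order so selection is deterministic.
#'
#' @param peaks a [peak_set()].
#' @param top_k maximum number of surviving peaks (paper ceiling 100).
#' @return A [peak_set()] with at most \code{top_k} rows.
#' @export
select_top_k <- function(peaks, top_k = 100L) {
  stopifnot(top_k >= 1)
  ord <- order(-peaks$value, peaks$s, peaks$theta, peaks$y, peaks$x)
  out <- peaks[ord[seq_len(min(top_k, nrow(peaks)))], , drop = FALSE]
  out <- out[order(out$s, out$theta, out$y, out$x), , drop = FALSE]
  peak_set(out, attr(peaks, "width"), attr(peaks, "height"))
}

#' Extract C1 peak responses from S1 maps
#'
#' Full C1 stage: per-map MAX pooling with a neighborhood equal to the
#' kernel size, strict thresholding, ON/OFF superposition into 16 maps, and
#' top-k selection.
#'
#' @param maps H x W x 32 array from [s1_response()].
#' @param bank the [gabor_bank()] that produced the maps.
#' @param c1_threshold response threshold (default 0.1).
#' @param top_k maximum surviving peaks (default 100).
#' @return A [peak_set()].
#' @export
c1_extract <- function(maps, bank = gabor_bank(), c1_threshold = 0.1,
                       top_k = 100L) {
  scales <- attr(bank, "scales")
  thetas <- attr(bank, "thetas")
  n <- length(bank)
  pool_one <- function(m_idx, k) {
    pk <- max_pool(maps[, , m_idx], scales[k])
    if (nrow(pk) == 0L) return(NULL)
    data.frame(s = scales[k], theta = thetas[k], x = pk$x, y = pk$y,
               value = pk$value)
  }
  w <- dim(maps)[2]; h <- dim(maps)[1]
  on_df <- do.call(rbind, lapply(seq_len(n), function(k) pool_one(k, k)))
  off_df <- do.call(rbind, lapply(seq_len(n), function(k) pool_one(n + k, k)))
  on_pk <- threshold_filter(peak_set(on_df, w, h), c1_threshold)
  off_pk <- threshold_filter(peak_set(off_df, w, h), c1_threshold)
  select_top_k(superpose(on_pk, off_pk), top_k)
}

#' Extract features from an event stream
#'
#' Convenience wrapper: event-driven S1 convolution with forgetting
#' ([s1_response()]) followed by C1 pooling ([c1_extract()]).
#'
#' @param stream an [event_stream()].
#' @param bank a [gabor_bank()].
#' @param leak S1 decay rate (response-units per second).
#' @param c1_threshold,top_k C1 parameters.
#' @return A [peak_set()].
#' @export
extract_peaks <- function(stream, bank = gabor_bank(), leak = 5e4,
                          c1_threshold = 0.1, top_k = 100L) {
  c1_extract(s1_response(stream, bank, leak), bank, c1_threshold, top_k)
}
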