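# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals.

# Dense 2-D correlation of an event-count image with a kernel: response at
# (y, x) is the sum of kernel weights deposited there by every event, i.e.
# R[y, x] = sum_{events e} K[y - e.y + r + 1, x - e.x + r + 1].
oracle_correlate <- function(counts, kernel) {
  h <- nrow(counts); w <- ncol(counts)
  s <- nrow(kernel); r <- (s - 1) / 2
  out <- matrix(0, h, w)
  for (ey in seq_len(h)) for (ex in seq_len(w)) {
    n <- counts[ey, ex]
    if (n == 0) next
    for (ky in seq_len(s)) for (kx in seq_len(s)) {
      yy <- ey + ky - r - 1
      xx <- ex + kx - r - 1
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w)
        out[yy, xx] <- out[yy, xx] + n * kernel[ky, kx]
    }
  }
  out
}

# Window-scan local-maximum oracle: a cell survives if its value is positive,
# >= everything in its clipped s x s window, and it is the first (smallest
# (y, x)) among equal-valued cells of that window.
oracle_max_pool <- function(map, s) {
  h <- nrow(map); w <- ncol(map); r <- (s - 1) / 2
  keep <- NULL
  for (cy in seq_len(h)) for (cx in seq_len(w)) {
    v <- map[cy, cx]
    if (v <= 0) next
    ys <- max(1, cy - r):min(h, cy + r)
    xs <- max(1, cx - r):min(w, cx + r)
    win <- map[ys, xs, drop = FALSE]
    if (any(win > v)) next
    ties <- which(win == v, arr.ind = TRUE)
    ty <- ys[ties[, 1]]; tx <- xs[ties[, 2]]
    o <- order(ty, tx)
    if (ty[o[1]] == cy && tx[o[1]] == cx)
      keep <- rbind(keep, c(cx - 1, cy - 1, v))
  }
  if (is.null(keep))
    return(data.frame(x = integer(0), y = integer(0), value = numeric(0)))
  df <- data.frame(x = keep[, 1], y = keep[, 2], value = keep[, 3])
  df[order(df$y, df$x), ]
}

# Quadrant-aware arctangent oracle for the deviation angle: clockwise angle
# (y down) between the vector and the -x axis, in [0, 360).
oracle_angle <- function(dx, dy) (atan2(dy, -dx) * 180 / pi) %% 360

# Interval-membership oracle for the 8-way angle partition: class m covers
# [45(m-1) - 22.5, 45(m-1) + 22.5) with wraparound, boundaries belonging to
# the higher class.
oracle_class <- function(an) {
  centers <- 45 * (0:7)
  for (m in 1:8) {
    lo <- centers[m] - 22.5
    hi <- centers[m] + 22.5
    a <- an
    if (lo < 0 && a >= 360 + lo) a <- a - 360
    if (a >= lo && a < hi) return(m)
  }
  stop("unclassified angle ", an)
}

# Forward nearest-neighbor rotation of a one-hot image about the pixel-center
# canvas midpoint, returning the rotated hot address (or NULL if clipped).
oracle_rotate_onehot <- function(x, y, angle_deg, w, h) {
  a <- angle_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  u <- x - cx; v <- y - cy
  x2 <- round(u * cos(a) + v * sin(a) + cx)
  y2 <- round(-u * sin(a) + v * cos(a) + cy)
  if (x2 < 0 || x2 >= w || y2 < 0 || y2 >= h) return(NULL)
  c(x2, y2)
}

# A bimodal two-cloud event stream with known polarity centers: `n` events
# per polarity drawn from round(N(mu, sd)), interleaved in time.
cloud_stream <- function(mu_on, mu_off, n = 1500, sd = 2, canvas = 40,
                         seed = 1) {
  set.seed(seed)
  clip <- function(z) pmin(pmax(round(z), 0), canvas - 1)
  ev <- data.frame(
    t = rep(seq_len(n), each = 2),
    x = as.vector(rbind(clip(rnorm(n, mu_on[1], sd)),
                        clip(rnorm(n, mu_off[1], sd)))),
    y = as.vector(rbind(clip(rnorm(n, mu_on[2], sd)),
                        clip(rnorm(n, mu_off[2], sd)))),
    p = rep(c(1L, -1L), n))
  event_stream(ev, canvas, canvas)
}

peak_key <- function(p) paste(p$s, p$theta, p$x, p$y)
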