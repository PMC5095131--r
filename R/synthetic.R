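#' Render a test glyph
#'
#' Deterministic binary masks used as stand-in objects for moving-target
#' recognition tests: simple stroke glyphs whose line content differs
#' across the four Gabor orientations.
#'
#' @param shape one of \code{"bar"} (vertical line), \code{"cross"},
#'   \code{"ell"}, \code{"tee"}, \code{"ring"} (square outline).
#' @param size side length in pixels. The default is even so that on an
#'   even-sided canvas the glyph's pixel offsets from its center are
#'   half-integers, which rotate exactly onto the pixel grid at multiples
#'   of 90 degrees about the canvas center ((W-1)/2, (H-1)/2).
#' @param thickness stroke thickness in pixels. The default 2 emulates the
#'   stroke width of handwritten-digit samples and gives the ON and OFF
#'   event clouds a nonzero spatial separation along the motion.
#' @return A \code{size} x \code{size} 0/1 matrix.
#' @export
render_glyph <- function(shape = c("bar", "cross", "ell", "tee", "ring"),
                         size = 16L, thickness = 2L) {
  shape <- match.arg(shape)
  stopifnot(size >= 3, thickness >= 1, thickness < size)
  m <- matrix(0L, size, size)
  mid <- (size - thickness) %/% 2L + 1L     # centered stroke band anchor
  th <- function(at) at + seq_len(thickness) - 1L
  switch(shape,
         bar = { m[, th(mid)] <- 1L },
         cross = { m[, th(mid)] <- 1L; m[th(mid), ] <- 1L },
         ell = { m[, th(1L)] <- 1L; m[th(size - thickness + 1L), ] <- 1L },
         tee = { m[th(1L), ] <- 1L; m[, th(mid)] <- 1L },
         ring = {
           m[c(th(1L), th(size - thickness + 1L)), ] <- 1L
           m[, c(th(1L), th(size - thickness + 1L))] <- 1L
         })
  m
}

#' Motion specification for the synthetic generator
#'
#' @param angle deviation angle of motion in degrees (0 = reference
#'   orientation, motion toward -x); the glyph itself is rotated by the
#'   same angle, emulating an object moving along its own forward
#'   direction.
#' @param speed pixels per millisecond. The default 1000 px/ms gives one
#'   microsecond per pixel step, keeping the whole crossing within the
#'   memory horizon of the S1 forgetting mechanism (leak 5e4 /s clears a
#'   unit response in 20 us).
#' @param noise_rate background noise events per second (Poisson, uniform
#'   addresses and polarities).
#' @param jitter_px the trajectory is offset perpendicular to the motion by
#'   an integer number of pixels drawn uniformly from
#'   -floor(jitter_px)..floor(jitter_px), giving seeded sample-to-sample
#'   variability while keeping 90-degree-multiple streams exactly
#'   rotation-equivariant.
#' @param seed integer seed; streams are byte-identical for equal seeds.
#' @return A list of class \code{"motion_spec"}.
#' @export
motion_spec <- function(angle = 0, speed = 1000, noise_rate = 0,
                        jitter_px = 0, seed = 1L) {
  stopifnot(speed > 0, noise_rate >= 0, jitter_px >= 0)
  structure(list(angle = angle, speed = speed, noise_rate = noise_rate,
                 jitter_px = jitter_px, seed = as.integer(seed)),
            class = "motion_spec")
}

#' Generate a moving-glyph AER event stream
#'
#' Idealized event-camera response to a rigid glyph translating across the
#' canvas at constant speed: at each one-pixel step of the trajectory,
#' every pixel switching background -> foreground emits one event and every
#' pixel switching back emits one event of the opposite polarity
#' (threshold-free DVS idealization). For a dark object on a light
#' background the leading edge darkens pixels, so newly covered pixels emit
#' OFF and newly uncovered pixels emit ON; a light object is the reverse.
#' Background noise events are added at \code{noise_rate} with the
#' stream's seed.
#'
#' Two trajectory extents are available. \code{"cropped"} (default) starts
#' with the glyph just off-canvas and stops when it sits flush against the
#' far border, still fully in view - emulating recordings cropped to the
#' in-view segment of a pass, the form in which crossing samples are
#' consumed downstream (both the forgetting mechanism and the polarity
#' trackers read out at the final event, so the sample should still be on
#' the canvas then). \code{"full"} continues until the glyph has left the
#' canvas entirely, so every cover event has a matching uncover event and
#' ON/OFF counts balance exactly; its trailing exit phase emits only
#' uncover events, which biases the final polarity centers and feature
#' maps toward the border.
#'
#' @param shape glyph shape id (see [render_glyph()]).
#' @param motion a [motion_spec()].
#' @param canvas canvas side in pixels.
#' @param size glyph side in pixels.
#' @param thickness stroke thickness (see [render_glyph()]).
#' @param contrast \code{"dark_object"} or \code{"light_object"}.
#' @param crossing trajectory extent, \code{"cropped"} or \code{"full"}.
#' @return An [event_stream()] with attribute \code{ground_truth}: a list
#'   \code{label}, \code{angle}, \code{class} (orientation class of the
#'   angle), \code{contrast}, \code{trajectory} (data.frame of step times
#'   and glyph centers).
#' @export
generate_stream <- function(shape, motion = motion_spec(), canvas = 40L,
                            size = 16L, thickness = 2L,
                            contrast = c("dark_object", "light_object"),
                            crossing = c("cropped", "full")) {
  contrast <- match.arg(contrast)
  crossing <- match.arg(crossing)
  mask <- render_glyph(shape, size, thickness)
  fg <- which(mask == 1L, arr.ind = TRUE)
  c0 <- (size + 1) / 2
  a <- motion$angle * pi / 180
  # glyph pixel offsets from the glyph center, rotated by the motion angle
  # (same rotation sense as rotate_events: reference motion -x maps to
  # deviation angle `angle`); for even `size` these are half-integers, so
  # added to the half-integer canvas center they land exactly on the pixel
  # grid at 90-degree multiples - rounding happens only when cells are
  # formed in occupancy()
  dx0 <- fg[, 2] - c0
  dy0 <- fg[, 1] - c0
  off <- unique(cbind(dx0 * cos(a) + dy0 * sin(a),
                      -dx0 * sin(a) + dy0 * cos(a)))
  dir <- c(-cos(a), sin(a))
  perp <- c(sin(a), cos(a))
  half <- ceiling(size * sqrt(2) / 2) + 1
  # start beyond the canvas corner so the glyph is fully off-canvas at both
  # ends of the trajectory for any motion angle
  n_steps <- as.integer(2 * (ceiling(canvas * sqrt(2) / 2) + half))
  k_mid <- n_steps / 2                     # step at which the glyph is centered
  ctr <- c((canvas - 1) / 2, (canvas - 1) / 2)
  dt_us <- 1000 / motion$speed

  with_seed(motion$seed, {
    # integer-valued perpendicular jitter keeps 90-degree-multiple streams
    # exactly rotation-equivariant across samples
    joff <- if (motion$jitter_px > 0) {
      j <- floor(motion$jitter_px)
      sample(seq(-j, j), 1)
    } else 0
    center_at <- function(k) ctr + dir * (k - k_mid) + perp * joff
    occupancy <- function(k) {
      pos <- center_at(k)
      px <- round(off[, 1] + pos[1])
      py <- round(off[, 2] + pos[2])
      ok <- px >= 0 & px < canvas & py >= 0 & py < canvas
      px[ok] + canvas * py[ok]   # linear cell ids
    }
    pol_cover <- if (contrast == "dark_object") -1L else 1L
    if (crossing == "cropped") {
      fully_in <- vapply(0:n_steps, function(k) {
        pos <- center_at(k)
        px <- round(off[, 1] + pos[1])
        py <- round(off[, 2] + pos[2])
        all(px >= 0, px < canvas, py >= 0, py < canvas)
      }, logical(1))
      if (!any(fully_in)) stop("glyph never fits the canvas")
      n_steps <- max(which(fully_in)) - 1L   # stop flush at the far border
    }
    ks <- 0:n_steps
    ctrs <- vapply(ks, center_at, numeric(2))
    traj <- data.frame(k = ks, t = round(ks * dt_us),
                       cx = ctrs[1, ], cy = ctrs[2, ])
    prev <- occupancy(0)
    evs <- vector("list", n_steps)
    for (k in seq_len(n_steps)) {
      cur <- occupancy(k)
      covered <- setdiff(cur, prev)
      uncovered <- setdiff(prev, cur)
      cells <- c(covered, uncovered)
      if (length(cells) > 0) {
        evs[[k]] <- data.frame(
          t = as.integer(round(k * dt_us)),
          x = cells %% canvas, y = cells %/% canvas,
          p = rep(c(pol_cover, -pol_cover),
                  c(length(covered), length(uncovered))))
      }
      prev <- cur
    }
    ev <- do.call(rbind, evs[!vapply(evs, is.null, logical(1))])
    t_end <- round(n_steps * dt_us)
    if (motion$noise_rate > 0) {
      n_noise <- rpois(1, motion$noise_rate * t_end * 1e-6)
      if (n_noise > 0) {
        ev <- rbind(ev, data.frame(
          t = as.integer(floor(runif(n_noise, 0, t_end + 1))),
          x = as.integer(floor(runif(n_noise, 0, canvas))),
          y = as.integer(floor(runif(n_noise, 0, canvas))),
          p = sample(c(-1L, 1L), n_noise, replace = TRUE)))
      }
    }
    stream <- event_stream(ev, canvas, canvas)
    attr(stream, "ground_truth") <- list(
      label = shape, angle = motion$angle %% 360,
      class = classify_orientation(motion$angle %% 360),
      contrast = contrast, trajectory = traj)
    stream
  })
}

#' Generate a labeled dataset of moving-glyph streams
#'
#' Balanced factorial design: one stream per (shape, angle, replicate),
#' each with its own seed (drawn from the master seed) driving the
#' trajectory jitter and noise, so replicates differ while labels and
#' angles are exact.
#'
#' @param shapes character vector of glyph shapes (the classes).
#' @param n_per_class replicates per (shape, angle) cell.
#' @param angles numeric vector of motion angles in degrees.
#' @param canvas,size,thickness,speed,noise_rate,jitter_px,contrast,crossing
#'   passed to [generate_stream()] / [motion_spec()].
#' @param seed master seed.
#' @return A list of class \code{"aer_dataset"}: \code{streams} (list),
#'   \code{labels} (factor), \code{angles} (numeric).
#' @export
make_dataset <- function(shapes = c("cross", "ell", "tee", "ring"),
                         n_per_class = 3L, angles = 0, canvas = 40L,
                         size = 16L, thickness = 2L, speed = 1000,
                         noise_rate = 5e5, jitter_px = 1,
                         contrast = "dark_object", crossing = "cropped",
                         seed = 1L) {
  grid <- expand.grid(rep = seq_len(n_per_class), angle = angles,
                      shape = shapes, stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(2^31 - 1, nrow(grid)))
  streams <- lapply(seq_len(nrow(grid)), function(i)
    generate_stream(grid$shape[i],
                    motion_spec(angle = grid$angle[i], speed = speed,
                                noise_rate = noise_rate,
                                jitter_px = jitter_px, seed = seeds[i]),
                    canvas = canvas, size = size, thickness = thickness,
                    contrast = contrast, crossing = crossing))
  structure(list(streams = streams,
                 labels = factor(grid$shape, levels = sort(unique(shapes))),
                 angles = grid$angle),
            class = "aer_dataset")
}
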