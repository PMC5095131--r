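#' Tracker parameters for the Gaussian blob orientation detector
#'
#' The detector runs two bivariate-Gaussian trackers, one per event
#' polarity. An incoming event at address u is accepted when its probability
#' density under the tracker's current N(mu, Sigma) exceeds a threshold
#' delta; delta is taken adaptively as the density of a point at Mahalanobis
#' distance \code{mahal_accept} from the center, so acceptance is the
#' scale-free condition (u - mu)' Sigma^-1 (u - mu) < mahal_accept^2.
#' Accepted events update the tracker by convex weighting:
#' mu <- alpha1 mu + (1 - alpha1) u and
#' Sigma <- alpha2 Sigma + (1 - alpha2) (u - mu_old)(u - mu_old)', after
#' which Sigma's eigenvalues are floored at sigma_min^2 to keep it positive
#' definite.
#'
#' @param alpha1 center memory weight in (0, 1); close to 1 means slow,
#'   stable centers.
#' @param alpha2 covariance memory weight in (0, 1).
#' @param mahal_accept acceptance radius in Mahalanobis units (defines the
#'   density threshold delta adaptively).
#' @param sigma0 initial standard deviation (pixels) of the isotropic
#'   starting covariance.
#' @param sigma_min floor on the per-axis standard deviation (pixels).
#' @return A list of class \code{"tracker_params"}.
#' @export
tracker_params <- function(alpha1 = 0.99, alpha2 = 0.99, mahal_accept = 3,
                           sigma0 = 10, sigma_min = 1) {
  stopifnot(alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1,
            mahal_accept > 0, sigma0 > 0, sigma_min > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 mahal_accept = mahal_accept, sigma0 = sigma0,
                 sigma_min = sigma_min),
            class = "tracker_params")
}

#' Create a Gaussian blob tracker
#'
#' @param mu0 initial center (x, y) in pixels; defaults to the canvas center
#'   when created through [detect_orientation()].
#' @param params a [tracker_params()].
#' @param polarity +1 (ON) or -1 (OFF); recorded for bookkeeping.
#' @return A list of class \code{"gaussian_tracker"} with fields \code{mu}
#'   (length-2), \code{Sigma} (2 x 2), \code{n} (accepted-event count),
#'   \code{polarity}.
#' @export
gaussian_tracker <- function(mu0, params = tracker_params(), polarity = 1L) {
  structure(list(mu = as.numeric(mu0),
                 Sigma = diag(params$sigma0^2, 2),
                 n = 0L, polarity = as.integer(polarity)),
            class = "gaussian_tracker")
}

#' Update a tracker with one event
#'
#' Evaluates the bivariate normal density
#' p(u) = (2 pi)^-1 |Sigma|^-1/2 exp(-(u - mu)' Sigma^-1 (u - mu) / 2) at
#' the event address and, if it exceeds the adaptive threshold delta
#' (density at Mahalanobis distance \code{mahal_accept}), applies the convex
#' center and covariance updates followed by the SPD floor. Rejected events
#' leave the tracker untouched.
#'
#' @param tracker a [gaussian_tracker()].
#' @param u event address c(x, y).
#' @param params a [tracker_params()].
#' @return A list \code{list(tracker, accepted)}.
#' @export
tracker_update <- function(tracker, u, params = tracker_params()) {
  mu <- tracker$mu
  S <- tracker$Sigma
  det_s <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (!is.finite(det_s) || det_s <= 0) stop("tracker covariance is singular")
  d <- c(u[1] - mu[1], u[2] - mu[2])
  # closed-form 2x2 Mahalanobis distance
  m2 <- (d[1] * (S[2, 2] * d[1] - S[1, 2] * d[2]) +
         d[2] * (S[1, 1] * d[2] - S[2, 1] * d[1])) / det_s
  if (m2 >= params$mahal_accept^2)
    return(list(tracker = tracker, accepted = FALSE))
  a1 <- params$alpha1; a2 <- params$alpha2
  tracker$mu <- a1 * mu + (1 - a1) * u
  S_new <- a2 * S + (1 - a2) * (d %o% d)   # outer product on u - mu_old
  # SPD floor: clamp eigenvalues of the symmetric 2x2 at sigma_min^2
  eg <- eigen(S_new, symmetric = TRUE)
  vals <- pmax(eg$values, params$sigma_min^2)
  tracker$Sigma <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  tracker$n <- tracker$n + 1L
  list(tracker = tracker, accepted = TRUE)
}

#' Deviation angle of motion from the ON/OFF center pair
#'
#' The motion direction is the vector between the OFF and ON event-cloud
#' centers; which center leads depends on the contrast: a dark object on a
#' light background darkens pixels at its leading edge (OFF leads), a light
#' object brightens them (ON leads). With (dx, dy) = lead - trail, the
#' deviation angle off the reference orientation (motion toward -x),
#' measured clockwise with y pointing down, is
#' \deqn{An = (180/\pi)\,\arccos(-dx/\sqrt{dx^2+dy^2})}{An = (180/pi) acos(-dx / sqrt(dx^2 + dy^2))}
#' when dy >= 0 and 360 minus that when dy < 0, giving An in [0, 360).
#'
#' @param mu_on,mu_off ON and OFF centers, c(x, y).
#' @param contrast_mode \code{"dark_object"} or \code{"light_object"}.
#' @return A list with \code{dx}, \code{dy} and \code{angle} (degrees).
#' @export
compute_angle <- function(mu_on, mu_off,
                          contrast_mode = c("dark_object", "light_object")) {
  contrast_mode <- match.arg(contrast_mode)
  d <- if (contrast_mode == "dark_object") mu_off - mu_on else mu_on - mu_off
  r <- sqrt(sum(d^2))
  if (!is.finite(r) || r == 0)
    stop("zero deviation between ON and OFF centers: orientation undefined")
  an <- 180 / pi * acos(-d[1] / r)
  if (d[2] < 0) an <- 360 - an
  if (an >= 360) an <- an - 360
  list(dx = d[1], dy = d[2], angle = an)
}

#' Classify a deviation angle into one of 8 orientation classes
#'
#' Class m covers angles within +-22.5 degrees of 45 (m - 1) degrees, with
#' the range [337.5, 360) wrapping into class 1: m = 1 + (round(An / 45)
#' mod 8). Boundary angles (e.g. exactly 22.5) round half-up into the higher
#' class.
#'
#' @param angle deviation angle in degrees, in [0, 360).
#' @return Integer class in 1..8.
#' @export
classify_orientation <- function(angle) {
  stopifnot(all(angle >= 0), all(angle < 360))
  1L + as.integer(floor(angle / 45 + 0.5)) %% 8L
}

#' Detect motion orientation from an event stream
#'
#' Routes every event, in time order, to the tracker of its polarity; the
#' final centers give the deviation angle ([compute_angle()]) and its
#' orientation class ([classify_orientation()]).
#'
#' @param stream an [event_stream()] containing both polarities.
#' @param params a [tracker_params()].
#' @param contrast_mode \code{"dark_object"} (OFF edge leads) or
#'   \code{"light_object"} (ON edge leads).
#' @return A list of class \code{"orientation_estimate"}: \code{class},
#'   \code{angle}, \code{dx}, \code{dy}, \code{mu_on}, \code{mu_off},
#'   \code{n_on}, \code{n_off}, \code{trackers}.
#' @export
detect_orientation <- function(stream, params = tracker_params(),
                               contrast_mode = c("dark_object",
                                                 "light_object")) {
  contrast_mode <- match.arg(contrast_mode)
  ev <- stream$events
  center <- c((stream$width - 1) / 2, (stream$height - 1) / 2)
  trk <- list(`1` = gaussian_tracker(center, params, 1L),
              `-1` = gaussian_tracker(center, params, -1L))
  for (i in seq_len(nrow(ev))) {
    key <- if (ev$p[i] == 1L) "1" else "-1"
    trk[[key]] <- tracker_update(trk[[key]], c(ev$x[i], ev$y[i]),
                                 params)$tracker
  }
  if (trk$`1`$n == 0L || trk$`-1`$n == 0L)
    stop("a polarity produced no accepted events; no center available")
  ang <- compute_angle(trk$`1`$mu, trk$`-1`$mu, contrast_mode)
  structure(list(class = classify_orientation(ang$angle),
                 angle = ang$angle, dx = ang$dx, dy = ang$dy,
                 mu_on = trk$`1`$mu, mu_off = trk$`-1`$mu,
                 n_on = trk$`1`$n, n_off = trk$`-1`$n,
                 trackers = trk),
            class = "orientation_estimate")
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("orientation class %d (angle %.1f deg)\n", x$class, x$angle))
  cat(sprintf("  ON center (%.2f, %.2f), n = %d; OFF center (%.2f, %.2f), n = %d\n",
              x$mu_on[1], x$mu_on[2], x$n_on,
              x$mu_off[1], x$mu_off[2], x$n_off))
  invisible(x)
}

#' One-line JSON record of an orientation estimate
#'
#' @param est an \code{orientation_estimate}.
#' @return A single JSON string (requires the jsonlite package).
#' @export
orientation_json <- function(est) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("orientation_json requires the jsonlite package")
  jsonlite::toJSON(list(class = est$class, An = est$angle,
                        mu_on = est$mu_on, mu_off = est$mu_off,
                        n_on = est$n_on, n_off = est$n_off),
                   auto_unbox = TRUE, digits = NA)
}
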