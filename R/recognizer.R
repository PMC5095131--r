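#' Configuration for the multi-orientation recognizer
#'
#' Bundles the parameters of every stage: canvas geometry, S1 forgetting,
#' C1 selection, tracker behavior, tempotron training, and the contrast
#' convention used by the orientation detector.
#'
#' @param canvas square canvas side in pixels (40 fits a 28 x 28 sample
#'   rotated by 45 degrees).
#' @param leak S1 decay rate, response-units per second (paper value 5e4).
#' @param c1_threshold C1 threshold (paper value 0.1).
#' @param top_k maximum C1 peaks fed to the classifier (paper ceiling 100).
#' @param tracker a [tracker_params()].
#' @param train a [tempotron_config()].
#' @param contrast \code{"dark_object"} or \code{"light_object"}; decides
#'   whether the OFF or the ON center leads the motion.
#' @return A list of class \code{"aer_config"}.
#' @export
aer_config <- function(canvas = 40L, leak = 5e4, c1_threshold = 0.1,
                       top_k = 100L, tracker = tracker_params(),
                       train = tempotron_config(),
                       contrast = c("dark_object", "light_object")) {
  contrast <- match.arg(contrast)
  structure(list(canvas = as.integer(canvas), leak = leak,
                 c1_threshold = c1_threshold, top_k = as.integer(top_k),
                 tracker = tracker, train = train, contrast = contrast),
            class = "aer_config")
}

#' Fit a multi-orientation AER object recognizer
#'
#' Trains the full recognition system on event streams of objects moving in
#' the single reference orientation (toward -x): each stream is run through
#' event-driven S1 Gabor convolution with forgetting and C1 MAX pooling,
#' the surviving peaks are converted to time-to-first-spike patterns, and a
#' bank of tempotron neurons (10 per category) is trained with the
#' error-driven tempotron rule under one-hot targets. The fitted object
#' also carries the 8-class address LUT used at prediction time to rotate
#' the features of test samples moving in other orientations back to the
#' reference frame.
#'
#' @param x an \code{aer_dataset} (see [make_dataset()]) or a list of
#'   [event_stream()]s.
#' @param labels category labels, one per stream (taken from \code{x} when
#'   it is an \code{aer_dataset}).
#' @param config an [aer_config()].
#' @return An object of class \code{"aer_recognizer"} with components
#'   \code{weights} (trained \code{weights_lut}), \code{address_lut},
#'   \code{bank}, \code{config}, \code{categories}, \code{n_train},
#'   \code{train_accuracy} (final training epoch), \code{epochs_run}.
#' @seealso [predict.aer_recognizer()], [aer_evaluate()]
#' @examples
#' \donttest{
#' ds <- make_dataset(c("cross", "ring"), n_per_class = 2, seed = 7)
#' fit <- aer_recognizer(ds)
#' print(fit)
#' }
#' @export
aer_recognizer <- function(x, labels = NULL, config = aer_config()) {
  if (inherits(x, "aer_dataset")) {
    streams <- x$streams
    if (is.null(labels)) labels <- x$labels
    gt_angles <- x$angles
  } else {
    streams <- x
    gt_angles <- vapply(streams, function(s) {
      gt <- attr(s, "ground_truth")
      if (is.null(gt)) 0 else gt$angle
    }, numeric(1))
  }
  if (length(streams) == 0L) stop("empty training set")
  if (is.null(labels) || length(labels) != length(streams))
    stop("one label per training stream required")
  if (any(gt_angles %% 360 != 0))
    warning("training samples should move in the reference orientation ",
            "(angle 0); found other angles in the ground truth")
  bank <- gabor_bank()
  peaks <- lapply(streams, extract_peaks, bank = bank, leak = config$leak,
                  c1_threshold = config$c1_threshold, top_k = config$top_k)
  patterns <- lapply(peaks, peaks_to_spikes, t_win = config$train$t_win)
  wl <- tempotron_train(patterns, labels, config$train)
  structure(list(weights = wl,
                 address_lut = build_address_lut(config$canvas,
                                                 config$canvas),
                 bank = bank, config = config, categories = wl$categories,
                 n_train = length(streams),
                 train_accuracy = wl$train_accuracy[wl$epochs_run],
                 epochs_run = wl$epochs_run,
                 call = match.call()),
            class = "aer_recognizer")
}

#' Predict categories and orientations for event streams
#'
#' For each stream the orientation detector (dual Gaussian-blob tracker)
#' estimates the deviation angle and its 8-way class m; feature extraction
#' runs independently on the same events; the C1 peaks are then remapped
#' through the class-m address LUT and orientation-map reordering (unless
#' \code{remap = FALSE}, the ablation mode) and classified by the tempotron
#' bank with majority voting.
#'
#' @param object an [aer_recognizer()] fit.
#' @param newdata an [event_stream()], a list of streams, or an
#'   \code{aer_dataset}.
#' @param remap apply the orientation-dependent address remapping.
#' @param ... unused.
#' @return A data.frame with one row per stream: \code{category} (factor),
#'   \code{orientation_class}, \code{angle} (degrees), \code{votes} (fires
#'   for the winning category), \code{n_peaks}.
#' @export
predict.aer_recognizer <- function(object, newdata, remap = TRUE, ...) {
  streams <- if (inherits(newdata, "aer_dataset")) newdata$streams
             else if (inherits(newdata, "event_stream")) list(newdata)
             else newdata
  cfg <- object$config
  rows <- lapply(streams, function(s) {
    est <- tryCatch(
      detect_orientation(s, cfg$tracker, cfg$contrast),
      error = function(e) NULL)
    m <- if (is.null(est)) 1L else est$class
    an <- if (is.null(est)) NA_real_ else est$angle
    pk <- extract_peaks(s, object$bank, cfg$leak, cfg$c1_threshold,
                        cfg$top_k)
    if (remap) pk <- remap_peaks(pk, m, object$address_lut)
    dec <- tempotron_classify(pk, object$weights)
    data.frame(category = dec$category, orientation_class = m, angle = an,
               votes = as.integer(dec$votes[dec$category]),
               n_peaks = nrow(pk))
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = object$categories)
  out
}

#' Evaluate a recognizer on a labeled dataset
#'
#' @param object an [aer_recognizer()] fit.
#' @param dataset an \code{aer_dataset} (streams + labels + angles).
#' @param remap apply orientation remapping (see
#'   [predict.aer_recognizer()]).
#' @return A list of class \code{"aer_metrics"}: \code{accuracy},
#'   \code{orientation_accuracy} (against the ground-truth angle classes),
#'   \code{confusion} (row-normalized, rows = true class), \code{predictions}.
#' @export
aer_evaluate <- function(object, dataset, remap = TRUE) {
  stopifnot(inherits(dataset, "aer_dataset"))
  pred <- predict(object, dataset, remap = remap)
  truth <- factor(dataset$labels, levels = object$categories)
  acc <- mean(as.character(pred$category) == as.character(truth))
  true_m <- classify_orientation(dataset$angles %% 360)
  ori_acc <- mean(pred$orientation_class == true_m)
  tab <- table(true = truth, predicted = pred$category)
  conf <- prop.table(tab, 1)
  conf[is.nan(conf)] <- 0
  structure(list(accuracy = acc, orientation_accuracy = ori_acc,
                 confusion = conf,
                 predictions = cbind(pred, true = truth,
                                     true_angle = dataset$angles)),
            class = "aer_metrics")
}

#' @export
print.aer_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("classification accuracy: %.*f\n", digits, x$accuracy))
  cat(sprintf("orientation accuracy:    %.*f\n", digits,
              x$orientation_accuracy))
  cat("confusion matrix (rows = true, row-normalized):\n")
  print(round(x$confusion, digits))
  invisible(x)
}

#' @export
print.aer_recognizer <- function(x, ...) {
  cat("Multi-orientation AER recognizer\n")
  cat(sprintf("  categories: %s\n", paste(x$categories, collapse = ", ")))
  cat(sprintf("  %d training streams; %d epochs; final training accuracy %.3f\n",
              x$n_train, x$epochs_run, x$train_accuracy))
  cat(sprintf("  canvas %dx%d, %d tempotron neurons (%d per category)\n",
              x$config$canvas, x$config$canvas, length(x$weights$weights),
              x$config$train$n_neurons))
  invisible(x)
}

#' @export
summary.aer_recognizer <- function(object, ...) {
  print(object)
  cat("\ntraining accuracy by epoch:\n")
  print(round(object$weights$train_accuracy, 3))
  w <- coef(object)
  norms <- tapply(sqrt(colSums(w^2)), object$weights$neuron_category, mean)
  cat("\nmean weight-vector L2 norm per category:\n")
  print(round(norms, 3))
  invisible(object)
}

#' Extract the trained tempotron weights
#'
#' @param object an [aer_recognizer()] fit.
#' @param ... unused.
#' @return A numeric matrix, afferents x neurons; column names are
#'   \code{<category>.<neuron>}.
#' @export
coef.aer_recognizer <- function(object, ...) {
  w <- do.call(cbind, object$weights$weights)
  colnames(w) <- paste(object$weights$neuron_category,
                       seq_len(ncol(w)) %% object$config$train$n_neurons,
                       sep = ".")
  w
}

#' Plot a fitted recognizer
#'
#' \code{type = "weights"} shows, per category, the spatial footprint of
#' the learned weights (sum of |w| over maps and the category's neurons on
#' the canvas grid); \code{type = "kernels"} shows the 16 Gabor kernels.
#'
#' @param x an [aer_recognizer()] fit.
#' @param type \code{"weights"} or \code{"kernels"}.
#' @param ... unused.
#' @export
plot.aer_recognizer <- function(x, type = c("weights", "kernels"), ...) {
  type <- match.arg(type)
  W <- x$config$canvas
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (type == "weights") {
    cats <- x$categories
    graphics::par(mfrow = c(1, length(cats)), mar = c(1, 1, 2, 1))
    for (cat_i in cats) {
      idx <- which(x$weights$neuron_category == cat_i)
      tot <- Reduce(`+`, lapply(x$weights$weights[idx], abs))
      sp <- rowSums(matrix(tot, W * W, 16L))   # collapse the 16 maps
      img <- matrix(sp, W, W)                  # [x + 1, y + 1]
      graphics::image(img[, W:1], axes = FALSE, xlab = "", ylab = "",
                      main = cat_i)
    }
  } else {
    graphics::par(mfrow = c(4, 4), mar = c(1, 1, 2, 1))
    for (k in x$bank) {
      graphics::image(t(k)[, nrow(k):1], axes = FALSE,
                      main = sprintf("s=%d %ddeg", attr(k, "s"),
                                     attr(k, "theta")))
    }
  }
  invisible(x)
}
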