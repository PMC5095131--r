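#' PSP kernel parameters
#'
#' The postsynaptic potential contributed by one input spike is the
#' double-exponential kernel
#' K(t) = V0 (exp(-t / tau_m) - exp(-t / tau_s)) for t >= 0 (0 before the
#' spike), with membrane time constant tau_m = 0.1 (in units of the pattern
#' window, which has length 1) and synaptic time constant tau_s = tau_m / 4.
#' V0 is the analytic normalizer making the kernel peak equal 1: the peak
#' sits at t* = tau_m tau_s / (tau_m - tau_s) * log(tau_m / tau_s).
#'
#' @param tau_m membrane time constant (pattern-window units).
#' @param tau_s synaptic time constant.
#' @return A list of class \code{"psp_params"} with \code{tau_m},
#'   \code{tau_s}, \code{v0}, \code{t_peak}.
#' @export
psp_params <- function(tau_m = 0.1, tau_s = tau_m / 4) {
  stopifnot(tau_m > tau_s, tau_s > 0)
  t_peak <- tau_m * tau_s / (tau_m - tau_s) * log(tau_m / tau_s)
  v0 <- 1 / (exp(-t_peak / tau_m) - exp(-t_peak / tau_s))
  structure(list(tau_m = tau_m, tau_s = tau_s, v0 = v0, t_peak = t_peak),
            class = "psp_params")
}

#' Evaluate the normalized PSP kernel
#'
#' @param dt time since the presynaptic spike (vectorized); the kernel is
#'   causal, 0 for dt < 0.
#' @param params a [psp_params()].
#' @return Kernel values in 0..1.
#' @export
psp_kernel <- function(dt, params = psp_params()) {
  out <- params$v0 * (exp(-dt / params$tau_m) - exp(-dt / params$tau_s))
  out[dt < 0] <- 0
  out
}

#' Convert C1 peaks to a time-to-first-spike pattern
#'
#' Each surviving peak becomes one spike on the afferent addressed by its
#' (orientation map, x, y) triple; stronger responses fire earlier:
#' t_i = T_win (1 - v_i / v_max), so the strongest peak fires at t = 0 and
#' equal values fire simultaneously. The afferent address space has
#' 16 * W * H entries (16 superposed C1 maps); the flat index is
#' 1 + x + W * (y + H * map_index) with map_index = scale_rank + 4 *
#' orientation_rank over scales (3,5,7,9) and orientations (0,45,90,135).
#'
#' @param peaks a [peak_set()] with positive values.
#' @param t_win pattern window length (default 1).
#' @return A list of class \code{"spike_pattern"}: \code{afferent} (integer
#'   ids), \code{time}, \code{n_afferents}, \code{t_win}. Empty peak sets
#'   give an empty pattern.
#' @export
peaks_to_spikes <- function(peaks, t_win = 1) {
  w <- attr(peaks, "width"); h <- attr(peaks, "height")
  n_aff <- 16L * w * h
  if (nrow(peaks) == 0L)
    return(structure(list(afferent = integer(0), time = numeric(0),
                          n_afferents = n_aff, t_win = t_win),
                     class = "spike_pattern"))
  stopifnot(all(peaks$value > 0))
  s_rank <- match(peaks$s, c(3L, 5L, 7L, 9L)) - 1L
  o_rank <- match(peaks$theta, c(0, 45, 90, 135)) - 1L
  map_i <- s_rank + 4L * o_rank
  aff <- 1L + peaks$x + w * (peaks$y + h * map_i)
  tt <- t_win * (1 - peaks$value / max(peaks$value))
  structure(list(afferent = aff, time = tt, n_afferents = n_aff,
                 t_win = t_win),
            class = "spike_pattern")
}

#' Tempotron configuration
#'
#' @param lambda learning rate of the tempotron rule.
#' @param max_epochs maximum training epochs (paper value 10).
#' @param seed integer seed for weight initialization and presentation
#'   order.
#' @param t_win pattern window length; the PSP time constants are expressed
#'   in these units (tau_m = 0.1 is a tenth of the window).
#' @param n_steps number of time steps the membrane potential is evaluated
#'   on (grid spacing dt = t_win / n_steps).
#' @param v_thr firing threshold.
#' @param v_rest resting potential.
#' @param n_neurons tempotron neurons per category (paper value 10).
#' @param w_init weights initialized uniformly in 0..w_init.
#' @param psp a [psp_params()].
#' @return A list of class \code{"tempotron_config"}.
#' @export
tempotron_config <- function(lambda = 3e-3, max_epochs = 10L, seed = 1L,
                             t_win = 1, n_steps = 256L, v_thr = 1,
                             v_rest = 0, n_neurons = 10L, w_init = 0.01,
                             psp = psp_params()) {
  stopifnot(lambda >= 0, max_epochs >= 1, n_steps >= 2, n_neurons >= 1)
  structure(list(lambda = lambda, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), t_win = t_win,
                 n_steps = as.integer(n_steps), v_thr = v_thr,
                 v_rest = v_rest, n_neurons = as.integer(n_neurons),
                 w_init = w_init, psp = psp),
            class = "tempotron_config")
}

#' Membrane potential of a tempotron neuron
#'
#' V(t) = sum_i w_i K(t - t_i) + V_rest over the spikes of the pattern.
#'
#' @param weights numeric weight vector over the afferent space.
#' @param pattern a [peaks_to_spikes()] pattern.
#' @param t evaluation times (vectorized).
#' @param config a [tempotron_config()].
#' @return Potential values at \code{t}.
#' @export
membrane_potential <- function(weights, pattern, t,
                               config = tempotron_config()) {
  if (length(pattern$afferent) == 0L)
    return(rep(config$v_rest, length(t)))
  K <- psp_kernel(outer(t, pattern$time, `-`), config$psp)
  as.numeric(K %*% weights[pattern$afferent]) + config$v_rest
}

# Potential on the standard evaluation grid for a matrix of weight columns.
# Returns list(grid, V) with V of dim (n_steps + 1) x n_neurons.
potential_grid <- function(wmat, pattern, config) {
  grid <- seq(0, config$t_win, length.out = config$n_steps + 1L)
  if (length(pattern$afferent) == 0L) {
    V <- matrix(config$v_rest, length(grid), ncol(wmat))
  } else {
    K <- psp_kernel(outer(grid, pattern$time, `-`), config$psp)
    V <- K %*% wmat[pattern$afferent, , drop = FALSE] + config$v_rest
  }
  list(grid = grid, V = V, K = if (length(pattern$afferent)) K else NULL)
}

#' Simulate a tempotron neuron on a spike pattern
#'
#' Scans the membrane potential on the evaluation grid. At the first time
#' the potential strictly exceeds the threshold the neuron fires and all
#' later input spikes are shunted (post-fire dynamics are not evaluated).
#' If it never fires, \code{t_event} is the time of the maximum potential
#' (first grid point on ties).
#'
#' @param weights numeric weight vector.
#' @param pattern a [peaks_to_spikes()] pattern.
#' @param config a [tempotron_config()].
#' @return A list \code{fired} (logical), \code{t_event}, \code{v_peak}.
#' @export
tempotron_simulate <- function(weights, pattern,
                               config = tempotron_config()) {
  pg <- potential_grid(matrix(weights, ncol = 1), pattern, config)
  v <- pg$V[, 1]
  cross <- which(v > config$v_thr)
  if (length(cross) > 0)
    list(fired = TRUE, t_event = pg$grid[cross[1]], v_peak = max(v))
  else
    list(fired = FALSE, t_event = pg$grid[which.max(v)], v_peak = max(v))
}

#' Train a bank of tempotron neurons
#'
#' One-hot supervision with \code{n_neurons} tempotron neurons per
#' category: all neurons of the pattern's own category should fire, all
#' others should stay silent. After each presentation every mismatched
#' neuron is corrected at its decision time t* (the time of the maximum
#' potential for a miss, the threshold-crossing time for a false alarm):
#' w_a <- w_a +/- lambda K(t* - t_a) for every pattern spike, which by
#' causality only touches spikes earlier than t*. Presentations are
#' shuffled each epoch with the config seed; training stops early once an
#' epoch is error-free.
#'
#' @param patterns list of [peaks_to_spikes()] patterns.
#' @param labels factor (or coercible) of category labels, one per pattern.
#' @param config a [tempotron_config()].
#' @return A list of class \code{"weights_lut"}: \code{weights} (list of
#'   numeric vectors, one per neuron), \code{neuron_category} (factor),
#'   \code{categories}, \code{config}, \code{epochs_run},
#'   \code{train_accuracy} (per-epoch fraction of patterns classified
#'   correctly by [tempotron_classify()]'s voting rule during training).
#' @export
tempotron_train <- function(patterns, labels, config = tempotron_config()) {
  if (length(patterns) == 0L) stop("empty training set")
  labels <- factor(labels)
  if (length(labels) != length(patterns))
    stop("one label per pattern required")
  cats <- levels(labels)
  n_aff <- patterns[[1]]$n_afferents
  n_neu <- config$n_neurons * length(cats)
  neuron_cat <- factor(rep(cats, each = config$n_neurons), levels = cats)
  weights <- with_seed(config$seed, lapply(seq_len(n_neu), function(i)
    runif(n_aff, 0, config$w_init)))
  acc_hist <- numeric(0)
  epoch_seeds <- with_seed(config$seed + 1L,
                           sample.int(.Machine$integer.max, config$max_epochs))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(epoch_seeds[epoch], sample.int(length(patterns)))
    n_correct <- 0L
    any_error <- FALSE
    for (pi in ord) {
      pat <- patterns[[pi]]
      wmat <- do.call(cbind, lapply(weights, function(w) w[pat$afferent]))
      pg <- potential_grid_aff(wmat, pat, config)
      should <- neuron_cat == labels[pi]
      fired <- apply(pg$V > config$v_thr, 2, any)
      votes <- tapply(fired, neuron_cat, sum)
      pred <- vote_winner(votes, pg$V, neuron_cat)
      if (pred == as.character(labels[pi])) n_correct <- n_correct + 1L
      wrong <- which(fired != should)
      if (length(wrong) > 0) any_error <- TRUE
      for (n_i in wrong) {
        v <- pg$V[, n_i]
        if (should[n_i]) {            # miss: push up at the potential peak
          i_star <- which.max(v)
          dw <- config$lambda * pg$K[i_star, ]
        } else {                      # false alarm: push down at the crossing
          i_star <- which(v > config$v_thr)[1]
          dw <- -config$lambda * pg$K[i_star, ]
        }
        w <- weights[[n_i]]
        w[pat$afferent] <- w[pat$afferent] + dw
        weights[[n_i]] <- w
      }
    }
    acc_hist <- c(acc_hist, n_correct / length(patterns))
    if (!any_error) break
  }
  structure(list(weights = weights, neuron_category = neuron_cat,
                 categories = cats, config = config,
                 epochs_run = length(acc_hist), train_accuracy = acc_hist),
            class = "weights_lut")
}

# potential_grid for a weight matrix already subset to the pattern's
# afferents (rows = spikes, cols = neurons).
potential_grid_aff <- function(wmat_aff, pattern, config) {
  grid <- seq(0, config$t_win, length.out = config$n_steps + 1L)
  if (length(pattern$afferent) == 0L)
    return(list(grid = grid,
                V = matrix(config$v_rest, length(grid), ncol(wmat_aff)),
                K = matrix(0, length(grid), 0)))
  K <- psp_kernel(outer(grid, pattern$time, `-`), config$psp)
  list(grid = grid, V = K %*% wmat_aff + config$v_rest, K = K)
}

# Majority vote with deterministic fallback: the category with the most
# firing neurons wins; ties (including zero fires everywhere) go to the
# category with the largest summed peak potential.
vote_winner <- function(votes, V, neuron_cat) {
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) return(top)
  peak_sum <- tapply(apply(V, 2, max), neuron_cat, sum)
  top[which.max(peak_sum[top])]
}

#' Classify a peak set with a trained tempotron bank
#'
#' Converts the peaks to a TFS spike pattern, simulates every neuron, and
#' applies majority voting: the category with the most firing neurons wins;
#' a tie (or no neuron firing at all) is broken by the largest summed peak
#' membrane potential across each category's neurons.
#'
#' @param peaks a [peak_set()] (or an existing \code{spike_pattern}).
#' @param lut a [tempotron_train()] result.
#' @return A list of class \code{"tempotron_decision"}: \code{category},
#'   \code{votes} (named integer vector), \code{fired} (per neuron),
#'   \code{peak_potential} (per neuron).
#' @export
tempotron_classify <- function(peaks, lut) {
  config <- lut$config
  pat <- if (inherits(peaks, "spike_pattern")) peaks
         else peaks_to_spikes(peaks, config$t_win)
  wmat <- do.call(cbind, lapply(lut$weights, function(w) w[pat$afferent]))
  if (length(pat$afferent) == 0L)
    wmat <- matrix(0, 0, length(lut$weights))
  pg <- potential_grid_aff(wmat, pat, config)
  fired <- apply(pg$V > config$v_thr, 2, any)
  votes <- tapply(fired, lut$neuron_category, sum)
  structure(list(category = vote_winner(votes, pg$V, lut$neuron_category),
                 votes = votes, fired = fired,
                 peak_potential = apply(pg$V, 2, max)),
            class = "tempotron_decision")
}
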