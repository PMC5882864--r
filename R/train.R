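#' Train one network on the gamble task
#'
#' Runs the full trial-by-trial protocol: sample a trial, forward pass, read
#' the choice, draw the Bernoulli outcome of the chosen gamble, backpropagate
#' the prediction error through the chosen output unit only (the unchosen
#' unit's incoming weights are left untouched that trial), update all weights
#' with learning rate `eta`, then renormalise each layer.
#'
#' The default normalisation, `"max_bound"`, divides a layer by its maximum
#' absolute weight only when that maximum exceeds 1, so weights stay in
#' \[-1, 1\] without inflating the small initial weights.  `"absmax"`
#' renormalises every layer to maximum absolute weight 1 on every trial,
#' `"signed_max"` divides by the (signed) largest weight, and `"none"`
#' disables normalisation.
#'
#' All randomness (weights, trials, tie-breaks, outcomes) is drawn from R's
#' stream in a fixed order, so `seed` makes runs bit-reproducible.
#'
#' @param n_trials Number of training trials (default 3000).
#' @param eta Learning rate (default 0.01).
#' @param layer_sizes Unit counts per layer (default `c(4, 20, 20, 20, 2)`).
#' @param slope Activation slope (default 3).
#' @param init_range Half-width of the uniform weight initialisation.
#' @param derivative `"analytic"` (default) or `"printed"`; see
#'   [activation_deriv()].
#' @param normalization One of `"max_bound"` (default), `"absmax"`,
#'   `"signed_max"`, `"none"`.
#' @param analysis_window Number of final trials whose activities are kept
#'   for analysis (default 1000).
#' @param seed Optional integer seed; when `NULL` the current stream is used.
#' @return A `choicenet_fit` object: trained `weights`, the per-trial log
#'   `trials` (inputs, expected values, choice, outcome, prediction error,
#'   `correct` flag with `NA` on expected-value ties), the `activities`
#'   matrix (analysis-window trials x all hidden + output units), the
#'   final-window accuracy, and the configuration.
#' @export
#' @examples
#' fit <- train_network(n_trials = 200, seed = 1)
#' glance(fit)
train_network <- function(n_trials = 3000, eta = 0.01,
                          layer_sizes = c(4, 20, 20, 20, 2),
                          slope = 3, init_range = 0.01,
                          derivative = c("analytic", "printed"),
                          normalization = c("max_bound", "absmax", "signed_max", "none"),
                          analysis_window = 1000, seed = NULL) {
  derivative <- match.arg(derivative)
  normalization <- match.arg(normalization)
  stopifnot(eta >= 0, n_trials >= 1, analysis_window <= n_trials,
            layer_sizes[1] == 4, layer_sizes[length(layer_sizes)] == 2)
  if (!is.null(seed)) set.seed(seed)

  w0     <- init_weights(layer_sizes, init_range)
  trials <- make_trials(n_trials)
  tie_u  <- stats::runif(n_trials)
  out_u  <- stats::runif(n_trials)

  res <- cpp_train_loop(w0, trial_inputs(trials), tie_u, out_u,
                        eta = eta, slope = slope,
                        derivative = match(derivative, c("analytic", "printed")) - 1L,
                        normalization = match(normalization,
                          c("max_bound", "absmax", "signed_max", "none")) - 1L,
                        record_from = n_trials - analysis_window + 1L,
                        learn = TRUE)

  trials$choose_left <- res$choose_left
  trials$choice      <- ifelse(res$choose_left == 1L, "left", "right")
  trials$outcome     <- res$outcome
  trials$y_chosen    <- res$y_chosen
  trials$error       <- res$error
  trials$ev_chosen   <- ifelse(res$choose_left == 1L, trials$ev_left, trials$ev_right)
  trials$correct     <- ifelse(trials$ev_tie, NA,
                               trials$ev_chosen >= pmax(trials$ev_left, trials$ev_right))

  acts <- res$activities
  colnames(acts) <- unit_names(layer_sizes)

  window <- trials[trials$trial > n_trials - analysis_window, ]
  acc <- mean(window$correct, na.rm = TRUE)

  structure(list(
    weights    = res$weights,
    trials     = trials,
    activities = acts,
    accuracy   = acc,
    config     = list(n_trials = n_trials, eta = eta, layer_sizes = layer_sizes,
                      slope = slope, init_range = init_range,
                      derivative = derivative, normalization = normalization,
                      analysis_window = analysis_window, seed = seed)
  ), class = "choicenet_fit")
}

unit_names <- function(layer_sizes) {
  n_hidden <- length(layer_sizes) - 2
  c(unlist(lapply(seq_len(n_hidden), function(l)
      sprintf("h%d_%02d", l, seq_len(layer_sizes[l + 1])))),
    "out_right", "out_left")
}

# tibble describing the analysis-window activity columns
unit_table <- function(layer_sizes) {
  n_hidden <- length(layer_sizes) - 2
  tibble::tibble(
    layer = c(rep(seq_len(n_hidden), layer_sizes[2:(n_hidden + 1)]), 0L, 0L),
    unit  = c(unlist(lapply(layer_sizes[2:(n_hidden + 1)], seq_len)), 1L, 2L),
    name  = unit_names(layer_sizes)
  )
}

#' @export
print.choicenet_fit <- function(x, ...) {
  cfg <- x$config
  cat("<choicenet_fit> ", paste(cfg$layer_sizes, collapse = "-"),
      " network, ", cfg$n_trials, " trials (eta = ", cfg$eta, ")\n", sep = "")
  cat("  final-window accuracy (ties excluded): ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Per-trial tidy log of a fitted network
#'
#' @param x A `choicenet_fit`.
#' @param ... Unused.
#' @return The per-trial tibble (inputs, expected values, choice, outcome,
#'   prediction error, correctness).
#' @method tidy choicenet_fit
#' @export
tidy.choicenet_fit <- function(x, ...) x$trials

#' One-row summary of a fitted network
#'
#' @param x A `choicenet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: accuracy over the analysis window (expected-value
#'   ties excluded), mean squared prediction error over the window, trial and
#'   window counts, and whether the 80% performance criterion was met.
#' @method glance choicenet_fit
#' @export
glance.choicenet_fit <- function(x, ...) {
  w <- analysis_trials(x)
  tibble::tibble(
    accuracy = x$accuracy,
    mse      = mean(w$error^2),
    n_trials = x$config$n_trials,
    analysis_window = x$config$analysis_window,
    met_criterion   = x$accuracy > 0.8
  )
}

# trials of the analysis window
analysis_trials <- function(fit) {
  n <- fit$config$n_trials
  fit$trials[fit$trials$trial > n - fit$config$analysis_window, ]
}

#' Train an ensemble of networks
#'
#' Trains `n_networks` independent networks that differ only in their seed
#' (network `k` uses `base_seed + k`), mirroring the study protocol of
#' averaging statistics over many random initialisations.
#'
#' @param n_networks Number of networks (study default 300).
#' @param base_seed Base seed; network `k` uses `base_seed + k`.
#' @param ... Passed to [train_network()].
#' @return A `choicenet_ensemble`: list of fits with the shared configuration.
#' @export
#' @examples
#' ens <- run_ensemble(n_networks = 2, base_seed = 1, n_trials = 200)
#' glance(ens)
run_ensemble <- function(n_networks = 300, base_seed = 1, ...) {
  stopifnot(n_networks >= 1)
  fits <- lapply(seq_len(n_networks), function(k)
    train_network(..., seed = base_seed + k))
  structure(list(fits = fits, base_seed = base_seed,
                 config = fits[[1]]$config),
            class = "choicenet_ensemble")
}

#' @export
print.choicenet_ensemble <- function(x, ...) {
  cat("<choicenet_ensemble> ", length(x$fits), " networks, ",
      "mean final-window accuracy ",
      sprintf("%.3f", mean(vapply(x$fits, function(f) f$accuracy, 0))),
      "\n", sep = "")
  invisible(x)
}

#' Per-network summaries of an ensemble
#'
#' @param x A `choicenet_ensemble`.
#' @param ... Unused.
#' @return A tibble with one row per network ([glance.choicenet_fit()]
#'   columns plus `network` and `seed`).
#' @method tidy choicenet_ensemble
#' @export
tidy.choicenet_ensemble <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$fits), function(k)
    dplyr::mutate(glance(x$fits[[k]]), network = k,
                  seed = x$base_seed + k, .before = 1)))
}

#' One-row summary of an ensemble
#'
#' @param x A `choicenet_ensemble`.
#' @param ... Unused.
#' @return A one-row tibble with the ensemble-mean accuracy, its standard
#'   deviation across networks, the pooled per-trial (Bernoulli-like)
#'   variance of correctness, and counts.
#' @method glance choicenet_ensemble
#' @export
glance.choicenet_ensemble <- function(x, ...) {
  accs <- vapply(x$fits, function(f) f$accuracy, 0)
  correct <- unlist(lapply(x$fits, function(f) {
    w <- analysis_trials(f); w$correct[!is.na(w$correct)]
  }))
  tibble::tibble(
    mean_accuracy     = mean(accs),
    sd_accuracy       = stats::sd(accs),
    trial_variance    = mean(correct) * (1 - mean(correct)),
    n_networks        = length(accs),
    frac_met_criterion = mean(accs > 0.8)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
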