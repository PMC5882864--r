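#' Specify a lesion
#'
#' A lesion silences a randomly selected fraction of units in one hidden
#' layer (or in all three): their post-activation activity is forced to zero
#' on every forward pass, so they also stop contributing downstream.  Weights
#' are untouched.  The number of silenced units per targeted layer is
#' `round(fraction * layer size)`.
#'
#' @param target `1`, `2`, `3` (a hidden layer) or `"all"`.
#' @param fraction Fraction of units to silence, in (0, 1].
#' @param mask_seed Seed for the random unit selection.
#' @return A `lesion_spec` object.
#' @export
#' @examples
#' lesion_spec(3, 0.25, mask_seed = 7)
lesion_spec <- function(target, fraction, mask_seed = 1) {
  target <- as.character(target)
  stopifnot(target %in% c("1", "2", "3", "all"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("lesion fraction must be in (0, 1]")
  structure(list(target = target, fraction = fraction, mask_seed = mask_seed),
            class = "lesion_spec")
}

#' Draw the unit mask of a lesion
#'
#' @param spec A [lesion_spec()].
#' @param layer_sizes Layer sizes of the network.
#' @return A list of logical vectors, one per hidden layer; `TRUE` marks
#'   silenced units.  The same `mask_seed` always yields the same mask.
#' @export
draw_lesion_mask <- function(spec, layer_sizes = c(4, 20, 20, 20, 2)) {
  n_hidden <- length(layer_sizes) - 2
  targets <- if (spec$target == "all") seq_len(n_hidden)
             else as.integer(spec$target)
  local_seed(spec$mask_seed, {
    lapply(seq_len(n_hidden), function(l) {
      size <- layer_sizes[l + 1]
      mask <- rep(FALSE, size)
      if (l %in% targets) {
        k <- round(spec$fraction * size)
        if (k > 0) mask[sample.int(size, k)] <- TRUE
      }
      mask
    })
  })
}

#' Apply a lesion to a trained network
#'
#' @param object A `choicenet_fit` (or a bare weight list, with `slope`
#'   given).
#' @param spec A [lesion_spec()], or `NULL` for an intact handle.
#' @param slope Activation slope when `object` is a weight list.
#' @return A `choicenet_handle`: frozen weights plus the lesion mask, ready
#'   for [evaluate_network()].
#' @export
apply_lesion <- function(object, spec = NULL, slope = 3) {
  if (inherits(object, "choicenet_fit")) {
    weights <- object$weights
    slope <- object$config$slope
    layer_sizes <- object$config$layer_sizes
  } else {
    weights <- object
    layer_sizes <- c(ncol(weights[[1]]), vapply(weights, nrow, 0L))
  }
  mask <- if (is.null(spec)) NULL else draw_lesion_mask(spec, layer_sizes)
  structure(list(weights = weights, slope = slope, mask = mask, spec = spec,
                 layer_sizes = layer_sizes),
            class = "choicenet_handle")
}

#' Evaluate a frozen (optionally lesioned) network
#'
#' Runs fresh trials through the network with learning disabled (no weight
#' updates, no normalisation) and reports the expected-value accuracy
#' (tie trials excluded) together with the trial log.
#'
#' @param object A `choicenet_handle` (from [apply_lesion()]) or a
#'   `choicenet_fit` (evaluated intact).
#' @param n_trials Number of evaluation trials (default 1000).
#' @param seed Optional seed for the evaluation trials and tie-breaks.
#' @return A list (class `choicenet_eval`) with `trials`, `accuracy`, and
#'   the handle's lesion `spec`.
#' @export
#' @examples
#' fit <- train_network(n_trials = 300, seed = 1)
#' evaluate_network(fit, n_trials = 200, seed = 2)$accuracy
evaluate_network <- function(object, n_trials = 1000, seed = NULL) {
  handle <- if (inherits(object, "choicenet_handle")) object
            else apply_lesion(object, NULL)
  if (!is.null(seed)) set.seed(seed)
  trials <- make_trials(n_trials)
  tie_u <- stats::runif(n_trials)
  acts <- forward(handle$weights, trial_inputs(trials),
                  slope = handle$slope, lesion = handle$mask)
  out <- acts[[length(acts)]]
  trials$choose_left <- read_choice(out, tie_u)
  trials$choice <- ifelse(trials$choose_left == 1L, "left", "right")
  trials$ev_chosen <- ifelse(trials$choose_left == 1L,
                             trials$ev_left, trials$ev_right)
  trials$correct <- ifelse(trials$ev_tie, NA,
                           trials$ev_chosen >= pmax(trials$ev_left, trials$ev_right))
  structure(list(trials = trials,
                 accuracy = mean(trials$correct, na.rm = TRUE),
                 spec = handle$spec),
            class = "choicenet_eval")
}

#' @export
print.choicenet_eval <- function(x, ...) {
  cat("<choicenet_eval> ", nrow(x$trials), " frozen trials, accuracy ",
      sprintf("%.3f", x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Psychometric curve and tanh fit
#'
#' Bins trials by the expected-value difference between the offers
#' (`ev_diff = EV_left - EV_right`), computes the fraction of left choices
#' per bin, and fits the sigmoid `P = 0.5 * (1 + tanh(k * (x - b)))` by least
#' squares.  The crossing slope (derivative at the 50% point) is `k / 2`.
#'
#' @param trials A trial tibble with `ev_diff` and `choose_left` columns
#'   (from a fit's log or [evaluate_network()]), or a `choicenet_fit` /
#'   `choicenet_eval` (a fit contributes its analysis window).
#' @param bin_width Width of the `ev_diff` bins (default 0.25 over
#'   \[-2, 2\]).
#' @param min_per_bin Bins with fewer trials are dropped from fitting
#'   (default 5).
#' @return A `choicenet_psychfit`: the per-bin curve, the fitted gain `k`,
#'   bias `b`, and `crossing_slope = k / 2`.
#' @export
#' @examples
#' fit <- train_network(n_trials = 500, seed = 1)
#' glance(psychometric_curve(fit))
psychometric_curve <- function(trials, bin_width = 0.25, min_per_bin = 5) {
  if (inherits(trials, "choicenet_fit")) trials <- analysis_trials(trials)
  if (inherits(trials, "choicenet_eval")) trials <- trials$trials
  stopifnot(all(c("ev_diff", "choose_left") %in% names(trials)),
            nrow(trials) >= 100)
  breaks <- seq(-2, 2 + 1e-9, by = bin_width)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- cut(trials$ev_diff, breaks, include.lowest = TRUE, labels = FALSE)
  curve <- tibble::tibble(
    ev_diff = mid[sort(unique(bin))],
    n = as.vector(table(bin)),
    p_left = as.vector(tapply(trials$choose_left, bin, mean))
  )
  usable <- curve[curve$n >= min_per_bin, ]
  if (nrow(usable) < 3) stop("fewer than 3 usable ev_diff bins")
  fit <- fit_tanh_curve(usable$ev_diff, usable$p_left)
  structure(list(curve = curve, k = fit$k, b = fit$b,
                 crossing_slope = fit$k / 2, converged = fit$converged),
            class = "choicenet_psychfit")
}

# least-squares fit of P = 0.5 (1 + tanh(k (x - b))), started from the
# linearised (atanh) regression; falls back to the linearised estimate when
# nls cannot improve (e.g. a step-like curve)
fit_tanh_curve <- function(x, p) {
  z <- atanh(pmin(pmax(2 * p - 1, -0.999), 0.999))
  lin <- stats::lm(z ~ x)
  k0 <- max(unname(stats::coef(lin)[2]), 1e-3)
  b0 <- -unname(stats::coef(lin)[1]) / k0
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(p ~ 0.5 * (1 + tanh(k * (ev - b))),
                 data = data.frame(ev = x, p = p),
                 start = list(k = k0, b = b0),
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(k = k0, b = b0, converged = FALSE))
  cf <- stats::coef(fit)
  list(k = unname(cf["k"]), b = unname(cf["b"]), converged = TRUE)
}

#' @export
print.choicenet_psychfit <- function(x, ...) {
  cat("<choicenet_psychfit> k = ", sprintf("%.3f", x$k),
      ", b = ", sprintf("%.3f", x$b),
      ", crossing slope = ", sprintf("%.3f", x$crossing_slope), "\n", sep = "")
  invisible(x)
}

#' @rdname psychometric_curve
#' @param x A `choicenet_psychfit`.
#' @param ... Unused.
#' @method tidy choicenet_psychfit
#' @export
tidy.choicenet_psychfit <- function(x, ...) x$curve

#' @rdname psychometric_curve
#' @method glance choicenet_psychfit
#' @export
glance.choicenet_psychfit <- function(x, ...) {
  tibble::tibble(k = x$k, b = x$b, crossing_slope = x$crossing_slope,
                 converged = x$converged)
}

#' Factorial lesion sweep over an ensemble
#'
#' Evaluates every (lesion fraction x target) condition on every network of a
#' trained ensemble with frozen weights: accuracy and the psychometric
#' crossing slope per condition.  Masks are drawn per network (seed
#' `base_seed + 10000 + k`, so masks are nested across fractions within a
#' network), and the same evaluation trials (seed `base_seed + 20000 + k`)
#' are reused across conditions of a network for paired comparisons.
#'
#' @param ensemble A `choicenet_ensemble`.
#' @param fractions Lesion fractions (default `c(0.05, 0.1, 0.25, 0.5, 0.75)`).
#' @param targets Targets (default layer 1, 2, 3 and `"all"`).
#' @param n_trials Evaluation trials per condition (default 1000).
#' @param base_seed Base seed for masks and evaluation trials; defaults to
#'   the ensemble's.
#' @param include_intact Also evaluate the intact network per network
#'   (rows with `fraction = 0`, `target = "none"`).
#' @return A tibble `network`, `target`, `fraction`, `mask_seed`,
#'   `accuracy`, `k`, `b`, `crossing_slope`.
#' @export
lesion_sweep <- function(ensemble, fractions = c(0.05, 0.1, 0.25, 0.5, 0.75),
                         targets = c("1", "2", "3", "all"), n_trials = 1000,
                         base_seed = NULL, include_intact = FALSE) {
  stopifnot(inherits(ensemble, "choicenet_ensemble"))
  if (is.null(base_seed)) base_seed <- ensemble$base_seed
  purrr::map_dfr(seq_along(ensemble$fits), function(k) {
    fit <- ensemble$fits[[k]]
    mask_seed <- base_seed + 10000 + k
    eval_seed <- base_seed + 20000 + k
    conds <- expand.grid(fraction = fractions, target = targets,
                         stringsAsFactors = FALSE)
    rows <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
      spec <- lesion_spec(conds$target[i], conds$fraction[i], mask_seed)
      ev <- evaluate_network(apply_lesion(fit, spec), n_trials, seed = eval_seed)
      ps <- psychometric_curve(ev$trials)
      tibble::tibble(network = k, target = conds$target[i],
                     fraction = conds$fraction[i], mask_seed = mask_seed,
                     accuracy = ev$accuracy, k = ps$k, b = ps$b,
                     crossing_slope = ps$crossing_slope)
    })
    if (include_intact) {
      ev <- evaluate_network(fit, n_trials, seed = eval_seed)
      ps <- psychometric_curve(ev$trials)
      rows <- dplyr::bind_rows(
        tibble::tibble(network = k, target = "none", fraction = 0,
                       mask_seed = NA_integer_, accuracy = ev$accuracy,
                       k = ps$k, b = ps$b, crossing_slope = ps$crossing_slope),
        rows)
    }
    rows
  })
}
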