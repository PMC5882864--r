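# Independent pure-R reference implementation of the training rule, used as
# an oracle for the compiled loop, plus small fixture builders.  Kept free of
# the package's own C++ path on purpose.

ref_forward <- function(weights, x, slope = 3) {
  ys <- list(as.numeric(x))
  nets <- list()
  for (l in seq_along(weights)) {
    nets[[l]] <- as.numeric(weights[[l]] %*% ys[[l]])
    ys[[l + 1]] <- tanh(slope * nets[[l]])
  }
  list(ys = ys, nets = nets)
}

ref_deriv <- function(x, slope = 3, derivative = "analytic") {
  d <- 1 - tanh(slope * x)^2
  if (derivative == "analytic") slope * d else d
}

# one full training trial: forward, choice, outcome, gated deltas, update,
# normalization; all randomness passed in
ref_train_step <- function(weights, x, tie_u, out_u, eta = 0.01, slope = 3,
                           derivative = "analytic",
                           normalization = "max_bound") {
  L <- length(weights)
  fw <- ref_forward(weights, x, slope)
  out <- fw$ys[[L + 1]]
  chosen <- if (out[1] > out[2]) 1L else if (out[2] > out[1]) 2L
            else if (tie_u < 0.5) 1L else 2L
  r_ch <- if (chosen == 1L) x[1] else x[3]
  p_ch <- if (chosen == 1L) x[2] else x[4]
  R <- if (out_u < p_ch) r_ch else 0
  e <- R - out[chosen]

  deltas <- vector("list", L)
  dN <- c(0, 0)
  dN[chosen] <- e * ref_deriv(fw$nets[[L]][chosen], slope, derivative)
  deltas[[L]] <- dN
  for (l in (L - 1):1)
    deltas[[l]] <- as.numeric(crossprod(weights[[l + 1]], deltas[[l + 1]])) *
      ref_deriv(fw$nets[[l]], slope, derivative)

  for (l in seq_len(L)) {
    weights[[l]] <- weights[[l]] + eta * outer(deltas[[l]], fw$ys[[l]])
    m <- max(abs(weights[[l]]))
    ms <- max(weights[[l]])
    if (normalization == "max_bound" && m > 1) weights[[l]] <- weights[[l]] / m
    if (normalization == "absmax" && m > 0)   weights[[l]] <- weights[[l]] / m
    if (normalization == "signed_max" && ms != 0) weights[[l]] <- weights[[l]] / ms
  }
  list(weights = weights, chosen = chosen, outcome = R, error = e,
       deltas = deltas, ys = fw$ys)
}

# numeric gradient of the gated per-trial loss 0.5 * (R - y_chosen)^2 with
# the choice held fixed, by central finite differences
ref_numeric_gradient <- function(weights, x, chosen, R, slope = 3, eps = 1e-6) {
  loss <- function(w) {
    y <- ref_forward(w, x, slope)$ys[[length(w) + 1]]
    0.5 * (R - y[chosen])^2
  }
  lapply(seq_along(weights), function(l) {
    g <- weights[[l]]
    for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
      wp <- weights; wm <- weights
      wp[[l]][i, j] <- wp[[l]][i, j] + eps
      wm[[l]][i, j] <- wm[[l]][i, j] - eps
      g[i, j] <- (loss(wp) - loss(wm)) / (2 * eps)
    }
    g
  })
}

# a fit-shaped object with hand-made activities, for analysis-level tests
fake_fit <- function(activities, trials, layer_sizes) {
  n <- nrow(trials)
  structure(list(
    weights = NULL, trials = trials, activities = activities,
    accuracy = NA_real_,
    config = list(n_trials = n, eta = 0, layer_sizes = layer_sizes, slope = 3,
                  init_range = 0.01, derivative = "analytic",
                  normalization = "max_bound", analysis_window = n,
                  seed = NULL)),
    class = "choicenet_fit")
}

# shared trained ensemble for the acceptance checks (built once per run)
.test_cache <- new.env(parent = emptyenv())

test_ensemble <- function(n_networks = 50, base_seed = 20) {
  key <- paste0("ens_", n_networks, "_", base_seed)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- run_ensemble(n_networks, base_seed = base_seed)
  .test_cache[[key]]
}

test_tuning <- function(ens) {
  key <- paste0("tun_", length(ens$fits), "_", ens$base_seed)
  if (is.null(.test_cache[[key]]))
    .test_cache[[key]] <- compute_tuning(ens)
  .test_cache[[key]]
}
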