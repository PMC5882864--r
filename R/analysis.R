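#' Single-regressor tuning of one unit
#'
#' A unit is "tuned" to a task variable when the ordinary least-squares slope
#' of its activity on that variable (single predictor plus intercept) is
#' significant by the two-sided t-test.  Degenerate inputs (constant
#' predictor or constant activity) yield `beta = 0`, `p = 1` and are flagged.
#'
#' @param activity Numeric vector of per-trial activity of one unit.
#' @param predictor Numeric vector of per-trial task-variable values.
#' @return A one-row tibble: `beta`, `p`, `degenerate`.
#' @export
#' @examples
#' unit_tuning(2 * (1:20), 1:20)
unit_tuning <- function(activity, predictor) {
  stopifnot(length(activity) == length(predictor), length(activity) >= 10)
  r <- ols_betas(matrix(activity, ncol = 1), predictor)
  tibble::tibble(beta = r$beta, p = r$p, degenerate = r$degenerate)
}

# vectorised single-regressor OLS: one predictor, every column of `acts` a
# response; returns slope, two-sided p and a degeneracy flag per column
ols_betas <- function(acts, x) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    k <- ncol(acts)
    return(list(beta = rep(0, k), p = rep(1, k), degenerate = rep(TRUE, k)))
  }
  ac <- sweep(acts, 2, colMeans(acts))
  beta <- as.vector(crossprod(xc, ac)) / sxx
  rss <- colSums(ac^2) - beta^2 * sxx
  rss[rss < 0] <- 0
  s2 <- rss / (n - 2)
  se <- sqrt(s2 / sxx)
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  degen <- colSums(ac^2) == 0
  p[degen] <- 1
  beta[degen] <- 0
  p[se == 0 & !degen] <- 0          # exact linear relation
  list(beta = beta, p = p, degenerate = degen)
}

tuning_variables <- c("rew_L", "prob_L", "rew_R", "prob_R",
                      "EV_L", "EV_R", "chosen_value", "choice", "pos")

#' Per-unit tuning records for all task variables
#'
#' For every hidden unit and every task variable, fits the single-regressor
#' model of final-window activity on the variable and records the slope
#' (beta) and p-value.  Variables are the attributes of the two offers
#' (`rew_L`, `prob_L`, `rew_R`, `prob_R`), their expected values (`EV_L`,
#' `EV_R`), the expected value of the chosen gamble (`chosen_value`), the
#' binary choice (`choice`, left = 1), and the spatial position of a matched
#' offer (`pos`, see [spatial_coding()]).
#'
#' @param object A `choicenet_fit` or `choicenet_ensemble`.
#' @param variables Subset of variables to fit (default all).
#' @return A tibble with columns `network`, `layer`, `unit`, `variable`,
#'   `beta`, `p`, `degenerate`.
#' @export
#' @examples
#' fit <- train_network(n_trials = 300, analysis_window = 200, seed = 1)
#' dplyr::count(compute_tuning(fit), variable)
compute_tuning <- function(object, variables = tuning_variables) {
  stopifnot(all(variables %in% tuning_variables))
  purrr::map_dfr(seq_along(fits_of(object)), function(k) {
    fit <- fits_of(object)[[k]]
    ut <- unit_table(fit$config$layer_sizes)
    hid <- ut$layer > 0
    acts <- fit$activities[, hid, drop = FALSE]
    w <- analysis_trials(fit)
    preds <- list(
      rew_L = w$r_left, prob_L = w$p_left,
      rew_R = w$r_right, prob_R = w$p_right,
      EV_L = w$ev_left, EV_R = w$ev_right,
      chosen_value = w$ev_chosen, choice = as.numeric(w$choose_left)
    )
    out <- purrr::map_dfr(intersect(variables, names(preds)), function(v) {
      r <- ols_betas(acts, preds[[v]])
      tibble::tibble(layer = ut$layer[hid], unit = ut$unit[hid], variable = v,
                     beta = r$beta, p = r$p, degenerate = r$degenerate)
    })
    if ("pos" %in% variables)
      out <- dplyr::bind_rows(out, spatial_coding(fit))
    dplyr::mutate(out, network = k, .before = 1)
  })
}

fits_of <- function(object) {
  if (inherits(object, "choicenet_ensemble")) object$fits
  else if (inherits(object, "choicenet_fit")) list(object)
  else stop("expected a choicenet_fit or choicenet_ensemble")
}

#' Spatial-position coding of matched offers
#'
#' Offer-side coding compares the responses to the *same* offer (a fixed
#' reward/probability cell) when it appears on the left (position 1) versus
#' the right (position 2), irrespective of the opposing offer: per cell the
#' mean activity on each side is computed, and the cell means are regressed
#' on the position code \{1, 2\}.  Cells not observed on both sides are
#' skipped; units with fewer than 3 usable cells are flagged.
#'
#' @param fit A `choicenet_fit`.
#' @return Tuning-record tibble rows (`variable = "pos"`).
#' @export
spatial_coding <- function(fit) {
  ut <- unit_table(fit$config$layer_sizes)
  hid <- ut$layer > 0
  acts <- fit$activities[, hid, drop = FALSE]
  w <- analysis_trials(fit)
  key_l <- w$ridx_left * 11L + w$pidx_left + 1L
  key_r <- w$ridx_right * 11L + w$pidx_right + 1L
  ml <- rowsum(acts, key_l) / as.vector(table(key_l))
  mr <- rowsum(acts, key_r) / as.vector(table(key_r))
  common <- intersect(rownames(ml), rownames(mr))
  if (length(common) < 3) {
    return(tibble::tibble(layer = ut$layer[hid], unit = ut$unit[hid],
                          variable = "pos", beta = 0, p = 1, degenerate = TRUE))
  }
  y <- rbind(ml[common, , drop = FALSE], mr[common, , drop = FALSE])
  x <- rep(c(1, 2), each = length(common))
  r <- ols_betas(y, x)
  tibble::tibble(layer = ut$layer[hid], unit = ut$unit[hid], variable = "pos",
                 beta = r$beta, p = r$p, degenerate = r$degenerate)
}

#' Fraction of tuned units per layer and variable
#'
#' @param tuning Tuning records from [compute_tuning()].
#' @param alpha Significance level (default 0.05, uncorrected as in the
#'   study; apply [stats::p.adjust()] upstream if correction is wanted).
#' @param average `"networks"` (default): fraction per network, then averaged
#'   over networks; `"pooled"`: one fraction over all pooled units.
#' @return A tibble `layer`, `variable`, `fraction`.
#' @export
tuning_fractions <- function(tuning, alpha = 0.05,
                             average = c("networks", "pooled")) {
  average <- match.arg(average)
  if (average == "networks") {
    tuning |>
      dplyr::group_by(.data$network, .data$layer, .data$variable) |>
      dplyr::summarise(fraction = mean(.data$p < alpha), .groups = "drop") |>
      dplyr::group_by(.data$layer, .data$variable) |>
      dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  } else {
    tuning |>
      dplyr::group_by(.data$layer, .data$variable) |>
      dplyr::summarise(fraction = mean(.data$p < alpha), .groups = "drop")
  }
}

#' Correlation of tuning coefficients across the population
#'
#' Pearson correlation, across hidden units pooled over ensemble networks
#' within a layer, between the regression coefficients for two task
#' variables.  `mode = "signed"` correlates the raw betas; `"unsigned"`
#' correlates their absolute values (coding strength irrespective of sign).
#'
#' @param tuning Tuning records from [compute_tuning()].
#' @param var_x,var_y Variable names (see [compute_tuning()]).
#' @param mode `"signed"` (default) or `"unsigned"`.
#' @param pool_layers If `TRUE`, one correlation over units of all hidden
#'   layers; otherwise one row per layer.
#' @return A tibble `layer` (`NA` when pooled), `var_x`, `var_y`, `mode`,
#'   `rho`, `p`, `n_units`.
#' @export
#' @examples
#' ens <- run_ensemble(2, n_trials = 300, analysis_window = 200)
#' beta_correlation(compute_tuning(ens), "EV_L", "EV_R")
beta_correlation <- function(tuning, var_x, var_y,
                             mode = c("signed", "unsigned"),
                             pool_layers = FALSE) {
  mode <- match.arg(mode)
  wide <- tuning |>
    dplyr::filter(.data$variable %in% c(var_x, var_y)) |>
    dplyr::select("network", "layer", "unit", "variable", "beta") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "beta")
  if (mode == "unsigned") {
    wide[[var_x]] <- abs(wide[[var_x]])
    wide[[var_y]] <- abs(wide[[var_y]])
  }
  one <- function(d, layer) {
    x <- d[[var_x]]; y <- d[[var_y]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(tibble::tibble(layer = layer, var_x = var_x, var_y = var_y,
                            mode = mode, rho = NA_real_, p = NA_real_,
                            n_units = length(x)))
    ct <- stats::cor.test(x, y)
    tibble::tibble(layer = layer, var_x = var_x, var_y = var_y, mode = mode,
                   rho = unname(ct$estimate), p = ct$p.value,
                   n_units = length(x))
  }
  if (pool_layers) return(one(wide, NA_integer_))
  purrr::map_dfr(sort(unique(wide$layer)), function(l)
    one(wide[wide$layer == l, ], l))
}

#' Choice probability correlations
#'
#' For each hidden unit, the activity over the analysis window is
#' residualised by a multiple linear regression on the four task inputs
#' (right reward/probability, left reward/probability); the Pearson
#' correlation of the residuals with the binary choice (left = 1) is the
#' unit's choice probability correlation (CPC).
#'
#' @param object A `choicenet_fit` or `choicenet_ensemble`.
#' @return A tibble `network`, `layer`, `unit`, `cpc`, `degenerate`.
#' @export
choice_probability <- function(object) {
  purrr::map_dfr(seq_along(fits_of(object)), function(k) {
    fit <- fits_of(object)[[k]]
    ut <- unit_table(fit$config$layer_sizes)
    hid <- ut$layer > 0
    acts <- fit$activities[, hid, drop = FALSE]
    w <- analysis_trials(fit)
    X <- cbind(1, w$r_right, w$p_right, w$r_left, w$p_left)
    res <- stats::lm.fit(X, acts)$residuals
    ch <- w$choose_left - mean(w$choose_left)
    rv <- colSums(res^2)
    cv <- sum(ch^2)
    tv <- colSums(sweep(acts, 2, colMeans(acts))^2)
    # residual variance at rounding-noise level counts as fully explained
    degen <- rv <= 1e-16 * pmax(tv, 1) | cv == 0
    num <- as.vector(crossprod(ch, res))
    den <- sqrt(rv * cv)
    cpc <- ifelse(!degen & den > 0, num / den, NA_real_)
    tibble::tibble(network = k, layer = ut$layer[hid], unit = ut$unit[hid],
                   cpc = cpc, degenerate = degen)
  })
}

#' Fixed-expected-value ("common currency") probe
#'
#' Enumerates every grid combination of reward and probability whose product
#' equals `ev_level` exactly (on the integer-scaled grid), presents each
#' combination as the probe-side offer against a fixed seeded sample of
#' opposing offers (the same opposing set for every combination), and records
#' each unit's response.  A unit using a common currency code would respond
#' identically across combinations of equal expected value; this is tested
#' per unit with a one-way ANOVA across combinations.
#'
#' @param object A `choicenet_fit` or `choicenet_ensemble` (trained weights
#'   are probed; no learning).
#' @param ev_level Expected value to probe (default 0.16, giving the four
#'   combinations (0.2, 0.8), (0.4, 0.4), (0.8, 0.2), (1.6, 0.1)).
#' @param layer Hidden layer to read out (default 3).
#' @param n_opposing Number of opposing offers marginalised over (default 50).
#' @param probe_side Side on which the probe offer is shown (default "left").
#' @param seed Seed for the opposing-offer sample (default 1).
#' @return A tibble with one row per network x unit x combination:
#'   `reward`, `probability`, `mean_response`, and the per-unit equality test
#'   (`f_stat`, `p_value`, `degenerate`).
#' @export
#' @examples
#' fit <- train_network(n_trials = 300, seed = 1)
#' probe <- common_currency_probe(fit)
#' unique(probe[, c("reward", "probability")])
common_currency_probe <- function(object, ev_level = 0.16, layer = 3,
                                  n_opposing = 50,
                                  probe_side = c("left", "right"), seed = 1) {
  probe_side <- match.arg(probe_side)
  target <- round(ev_level * 50)
  if (abs(ev_level * 50 - target) > 1e-9)
    stop("ev_level is not attainable on the reward x probability grid")
  grid <- expand.grid(ridx = 0:10, pidx = 0:10)
  combos <- grid[grid$ridx * grid$pidx == target & grid$ridx > 0, , drop = FALSE]
  if (target == 0) combos <- grid[grid$ridx * grid$pidx == 0, , drop = FALSE]
  if (nrow(combos) == 0) stop("no grid combination matches ev_level")

  opposing <- local_seed(seed, sample_gambles(n_opposing))

  purrr::map_dfr(seq_along(fits_of(object)), function(k) {
    fit <- fits_of(object)[[k]]
    ut <- unit_table(fit$config$layer_sizes)
    sel <- ut$layer == layer
    resp <- purrr::map(seq_len(nrow(combos)), function(ci) {
      r <- combos$ridx[ci] / 5; p <- combos$pidx[ci] / 10
      inp <- if (probe_side == "left")
        cbind(opposing$reward, opposing$probability, r, p)
      else cbind(r, p, opposing$reward, opposing$probability)
      a <- forward(fit$weights, inp, slope = fit$config$slope)
      a[[layer + 1]]
    })
    purrr::map_dfr(which(sel), function(col) {
      groups <- lapply(resp, function(m) m[, ut$unit[col]])
      test <- oneway_equal(groups)
      tibble::tibble(network = k, layer = layer, unit = ut$unit[col],
                     reward = combos$ridx / 5, probability = combos$pidx / 10,
                     mean_response = vapply(groups, mean, 0),
                     f_stat = test$f, p_value = test$p,
                     degenerate = test$degenerate)
    })
  })
}

# one-way equal-variance ANOVA across groups, with explicit handling of
# degenerate (zero-variance) responses
oneway_equal <- function(groups) {
  y <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(y); kg <- length(groups)
  gm <- tapply(y, g, mean)
  ssb <- sum(lengths(groups) * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  tot <- ssb + ssw
  if (tot < 1e-24 * max(1, mean(y)^2))
    return(list(f = 0, p = 1, degenerate = TRUE))
  if (ssw == 0) return(list(f = Inf, p = 0, degenerate = FALSE))
  f <- (ssb / (kg - 1)) / (ssw / (n - kg))
  list(f = f, p = stats::pf(f, kg - 1, n - kg, lower.tail = FALSE),
       degenerate = FALSE)
}

# evaluate expr under a temporary seed, restoring the caller's stream
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Kruskal-Wallis trend test across layers
#'
#' Tests whether a per-unit statistic differs across layer groups.  The H
#' statistic is chi-squared distributed under the null and is reported as
#' such.
#'
#' @param values Numeric vector of per-unit values.
#' @param layer Grouping vector (layer of each value).
#' @return A tibble `statistic` (chi-squared), `df`, `p_value`, `degenerate`.
#' @export
layer_trend_test <- function(values, layer) {
  stopifnot(length(values) == length(layer))
  if (length(unique(values)) == 1)
    return(tibble::tibble(statistic = 0, df = length(unique(layer)) - 1,
                          p_value = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(values, factor(layer))
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, degenerate = FALSE)
}

#' Linear decodability of offer attributes from one layer
#'
#' Fits a linear readout of one attribute (e.g. left-offer reward) from the
#' activities of a hidden layer on half of the analysis window and reports
#' out-of-sample R-squared on the other half, per network.  Positive
#' out-of-sample R-squared for both reward and probability demonstrates that
#' the attributes remain independently decodable.
#'
#' @param object A `choicenet_fit` or `choicenet_ensemble`.
#' @param layer Hidden layer (default 3).
#' @param variables Which attributes to decode (default left reward and
#'   probability).
#' @return A tibble `network`, `variable`, `r_squared`.
#' @export
decode_attributes <- function(object, layer = 3,
                              variables = c("rew_L", "prob_L")) {
  purrr::map_dfr(seq_along(fits_of(object)), function(k) {
    fit <- fits_of(object)[[k]]
    ut <- unit_table(fit$config$layer_sizes)
    acts <- fit$activities[, ut$layer == layer, drop = FALSE]
    w <- analysis_trials(fit)
    preds <- list(rew_L = w$r_left, prob_L = w$p_left,
                  rew_R = w$r_right, prob_R = w$p_right)
    n <- nrow(acts)
    train <- seq_len(floor(n / 2)); test <- setdiff(seq_len(n), train)
    X <- cbind(1, acts)
    purrr::map_dfr(variables, function(v) {
      y <- preds[[v]]
      coefs <- stats::lm.fit(X[train, ], y[train])$coefficients
      coefs[is.na(coefs)] <- 0
      pred <- drop(X[test, ] %*% coefs)
      r2 <- 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[train]))^2)
      tibble::tibble(network = k, variable = v, r_squared = r2)
    })
  })
}
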