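test_that("single-regressor tuning recovers exact and degenerate cases", {
  x <- seq(0, 2, length.out = 50)
  exact <- unit_tuning(2 * x, x)
  expect_equal(exact$beta, 2)
  expect_lt(exact$p, 1e-12)
  neg <- unit_tuning(-x, x)
  expect_equal(neg$beta, -1)
  flat <- unit_tuning(rep(0.3, 50), x)
  expect_equal(flat$beta, 0)
  expect_equal(flat$p, 1)
  expect_true(flat$degenerate)
  const_pred <- unit_tuning(rnorm(50), rep(1, 50))
  expect_true(const_pred$degenerate)
})

test_that("vectorised OLS agrees with lm() on noisy data", {
  set.seed(8)
  x <- runif(120)
  acts <- cbind(1.5 * x + rnorm(120, sd = 0.3),
                rnorm(120),
                -0.4 * x + rnorm(120, sd = 1))
  r <- choicenet:::ols_betas(acts, x)
  for (j in 1:3) {
    m <- summary(lm(acts[, j] ~ x))
    expect_equal(r$beta[j], unname(m$coefficients["x", "Estimate"]))
    expect_equal(r$p[j], unname(m$coefficients["x", "Pr(>|t|)"]))
  }
})

test_that("tuning p-values are calibrated on null data", {
  set.seed(123)
  x <- runif(200, 0, 2)
  noise <- matrix(rnorm(200 * 1000), 200, 1000)
  r <- choicenet:::ols_betas(noise, x)
  rej <- mean(r$p < 0.05)
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("tuning fractions are ~alpha on noise and scale-invariant", {
  set.seed(31)
  n <- 400
  trials <- make_trials(n)
  trials$choose_left <- rbinom(n, 1, 0.5)
  trials$ev_chosen <- ifelse(trials$choose_left == 1, trials$ev_left,
                             trials$ev_right)
  acts <- matrix(rnorm(n * 26), n,
                 dimnames = list(NULL, choicenet:::unit_names(c(4, 8, 8, 8, 2))))
  fit <- fake_fit(acts, trials, c(4, 8, 8, 8, 2))
  tun <- compute_tuning(fit, variables = c("rew_L", "prob_R", "EV_L", "choice"))
  fr <- tuning_fractions(tun)
  expect_true(all(fr$fraction < 0.40))
  expect_lt(abs(mean(tun$p < 0.05) - 0.05), 0.03)
  # positive rescaling of a unit's activity changes no tuning decision
  fit2 <- fit
  fit2$activities <- acts * 7.3
  tun2 <- compute_tuning(fit2, variables = c("rew_L", "prob_R", "EV_L", "choice"))
  expect_equal(tun$p, tun2$p)
})

test_that("beta correlations behave on constructed records", {
  b <- rnorm(30)
  tun <- tibble::tibble(network = 1, layer = rep(1L, 60),
                        unit = rep(1:30, 2),
                        variable = rep(c("EV_L", "EV_R"), each = 30),
                        beta = c(b, b), p = 0.01, degenerate = FALSE)
  r <- beta_correlation(tun, "EV_L", "EV_R")
  expect_equal(r$rho, 1)
  tun$beta[31:60] <- -2 * b
  r <- beta_correlation(tun, "EV_L", "EV_R")
  expect_equal(r$rho, -1)
  r_uns <- beta_correlation(tun, "EV_L", "EV_R", mode = "unsigned")
  expect_equal(r_uns$rho, 1)
  tun$beta[31:60] <- 0
  r0 <- beta_correlation(tun, "EV_L", "EV_R")
  expect_true(is.na(r0$rho))          # zero-variance vector flagged
})

test_that("side coding matches the matched-cell arithmetic and vanishes for
           slot-symmetric units", {
  set.seed(61)
  n <- 600
  trials <- make_trials(n)
  acts <- matrix(rnorm(n * 8), n,
                 dimnames = list(NULL, choicenet:::unit_names(c(4, 2, 2, 2, 2))))
  fit <- fake_fit(acts, trials, c(4, 2, 2, 2, 2))
  pos <- spatial_coding(fit)
  # oracle: the slope on the side code {1, 2} is the difference of the grand
  # means of the per-cell means, over cells seen on both sides
  key_l <- trials$ridx_left * 11 + trials$pidx_left
  key_r <- trials$ridx_right * 11 + trials$pidx_right
  common <- intersect(unique(key_l), unique(key_r))
  for (col in c(1, 4)) {
    ml <- tapply(acts[, col], key_l, mean)[as.character(common)]
    mr <- tapply(acts[, col], key_r, mean)[as.character(common)]
    expect_equal(pos$beta[col], unname(mean(mr) - mean(ml)))
  }
  # a unit exactly symmetric in the two offer slots has no side coding in
  # expectation: with many trials the slope shrinks toward 0
  set.seed(62)
  big <- make_trials(20000)
  sym <- with(big, tanh(0.4 * r_right - 0.3 * p_right) +
                   tanh(0.4 * r_left - 0.3 * p_left)) # f(A,B) = f(B,A)
  acts2 <- matrix(rep(sym, 8), ncol = 8,
                  dimnames = list(NULL, choicenet:::unit_names(c(4, 2, 2, 2, 2))))
  fit2 <- fake_fit(acts2, big, c(4, 2, 2, 2, 2))
  pos2 <- spatial_coding(fit2)
  expect_true(all(abs(pos2$beta) < 0.02))
})

test_that("choice probability correlations separate signal from residuals", {
  set.seed(17)
  n <- 500
  trials <- make_trials(n)
  trials$choose_left <- rbinom(n, 1, 0.5)
  trials$ev_chosen <- ifelse(trials$choose_left == 1, trials$ev_left,
                             trials$ev_right)
  task_only <- with(trials, 0.5 * r_right - 0.2 * p_left + 0.1 * r_left)
  choice_unit <- trials$choose_left + rnorm(n, sd = 0.05)
  acts <- cbind(task_only, choice_unit,
                matrix(rnorm(n * 6), n, 6))
  colnames(acts) <- choicenet:::unit_names(c(4, 2, 2, 2, 2))
  fit <- fake_fit(acts, trials, c(4, 2, 2, 2, 2))
  cpc <- choice_probability(fit)
  expect_true(cpc$degenerate[1])            # perfectly residualised away
  expect_gt(cpc$cpc[2], 0.9)                # choice-driven unit
  expect_true(all(abs(cpc$cpc[3:6]) < 0.2, na.rm = TRUE))
})

test_that("the fixed-EV probe enumerates the grid and tests equality", {
  fit <- train_network(n_trials = 300, analysis_window = 200, seed = 5)
  probe <- common_currency_probe(fit, ev_level = 0.16, n_opposing = 10)
  combos <- unique(probe[, c("reward", "probability")])
  expect_equal(nrow(combos), 4)
  expect_setequal(paste(combos$reward, combos$probability),
                  c("0.2 0.8", "0.4 0.4", "0.8 0.2", "1.6 0.1"))
  expect_equal(unique(combos$reward * combos$probability), 0.16)
  expect_error(common_currency_probe(fit, ev_level = 0.17), "grid")
  # a pure-EV response (identical across equal-EV combinations) is never
  # rejected; an attribute-coded response is
  pure <- lapply(1:4, function(i) rep(0.16, 50))
  expect_equal(choicenet:::oneway_equal(pure)$p, 1)
  coded <- lapply(c(0.2, 0.4, 0.8, 1.6), function(r) r + rnorm(50, sd = 0.01))
  expect_lt(choicenet:::oneway_equal(coded)$p, 1e-6)
})

test_that("the one-way equality test matches aov", {
  set.seed(77)
  groups <- lapply(1:4, function(i) rnorm(30, mean = 0.1 * i))
  mine <- choicenet:::oneway_equal(groups)
  d <- data.frame(y = unlist(groups), g = factor(rep(1:4, each = 30)))
  ref <- summary(stats::aov(y ~ g, d))[[1]]
  expect_equal(mine$f, ref[["F value"]][1])
  expect_equal(mine$p, ref[["Pr(>F)"]][1])
})

test_that("the layer trend test reproduces rank arithmetic", {
  separated <- layer_trend_test(c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                                rep(1:3, each = 3))
  expect_equal(separated$statistic, 8)      # tie-corrected H for full separation
  expect_lt(separated$p_value, 0.05)
  flat <- layer_trend_test(rep(c(1, 2, 3), 2), rep(1:2, each = 3))
  expect_equal(flat$statistic, 0)
  degen <- layer_trend_test(rep(5, 9), rep(1:3, each = 3))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  # null calibration at alpha = 0.05
  set.seed(99)
  rej <- mean(vapply(1:1000, function(i)
    layer_trend_test(rnorm(30), rep(1:3, each = 10))$p_value < 0.05, TRUE))
  expect_gt(rej, 0.035); expect_lt(rej, 0.065)
})

test_that("attribute decoding recovers linearly coded populations", {
  set.seed(210)
  n <- 400
  trials <- make_trials(n)
  trials$choose_left <- rbinom(n, 1, 0.5)
  trials$ev_chosen <- ifelse(trials$choose_left == 1, trials$ev_left,
                             trials$ev_right)
  mix <- matrix(rnorm(12), 2, 6)
  acts <- cbind(matrix(rnorm(n * 6), n, 6),
                cbind(trials$r_left, trials$p_left) %*% mix +
                  matrix(rnorm(n * 6, sd = 0.1), n, 6),
                matrix(0, n, 4))
  colnames(acts) <- choicenet:::unit_names(c(4, 6, 6, 2, 2))
  fit <- fake_fit(acts, trials, c(4, 6, 6, 2, 2))
  dec2 <- decode_attributes(fit, layer = 2)
  expect_setequal(dec2$variable, c("rew_L", "prob_L"))
  expect_true(all(dec2$r_squared > 0.9))
  dec1 <- decode_attributes(fit, layer = 1)   # pure noise layer
  expect_true(all(dec1$r_squared < 0.2))
})
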