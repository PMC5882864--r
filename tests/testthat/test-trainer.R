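test_that("the compiled trial loop matches the pure-R reference", {
  for (norm in c("max_bound", "absmax", "none")) {
    n <- 30
    set.seed(101)
    w0 <- init_weights()
    trials <- make_trials(n)
    tie_u <- runif(n); out_u <- runif(n)
    fit <- choicenet:::cpp_train_loop(
      w0, trial_inputs(trials), tie_u, out_u, eta = 0.05, slope = 3,
      derivative = 0L,
      normalization = match(norm, c("max_bound", "absmax", "signed_max", "none")) - 1L,
      record_from = 1L, learn = TRUE)
    w <- w0
    inputs <- trial_inputs(trials)
    err_gap <- 0
    for (t in seq_len(n)) {
      st <- ref_train_step(w, inputs[t, ], tie_u[t], out_u[t], eta = 0.05,
                           normalization = norm)
      w <- st$weights
      expect_identical(fit$choose_left[t], st$chosen - 1L)
      err_gap <- max(err_gap, abs(fit$error[t] - st$error))
    }
    expect_lt(err_gap, 1e-9)
    w_gap <- max(vapply(1:4, function(l) max(abs(fit$weights[[l]] - w[[l]])), 0))
    expect_lt(w_gap, 1e-9)
  }
})

test_that("training is bit-reproducible per seed", {
  f1 <- train_network(n_trials = 150, analysis_window = 50, seed = 77)
  f2 <- train_network(n_trials = 150, analysis_window = 50, seed = 77)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$trials, f2$trials)
  expect_identical(f1$activities, f2$activities)
})

test_that("only the chosen output unit learns on a trial", {
  set.seed(55)
  inputs <- trial_inputs(make_trials(30))
  w <- init_weights()
  for (t in 1:30) {
    st <- ref_train_step(w, inputs[t, ], runif(1), runif(1),
                         normalization = "none")
    unchosen <- 3L - st$chosen
    # incoming weights of the unchosen output unit are bitwise unchanged
    expect_identical(st$weights[[4]][unchosen, ], w[[4]][unchosen, ])
    expect_identical(st$deltas[[4]][unchosen], 0)
    if (st$error == 0) for (l in 1:4) expect_equal(st$deltas[[l]],
                                                   rep(0, nrow(w[[l]])),
                                                   ignore_attr = TRUE)
    w <- st$weights
  }
})

test_that("gated deltas equal finite-difference gradients of the loss", {
  set.seed(300)
  for (i in 1:25) {
    sizes <- c(4, sample(2:4, 1), sample(2:4, 1), 2)
    w <- init_weights(sizes, init_range = 0.5)
    x <- c(runif(1, 0, 2), runif(1), runif(1, 0, 2), runif(1))
    st <- ref_train_step(w, x, runif(1), runif(1), eta = 0,
                         normalization = "none")
    num <- ref_numeric_gradient(w, x, st$chosen, st$outcome)
    fw <- ref_forward(w, x)
    for (l in 1:3) {
      analytic <- -outer(st$deltas[[l]], fw$ys[[l]])
      expect_lt(max(abs(analytic - num[[l]])), 1e-5)
    }
  }
})

test_that("an update step descends the per-trial loss", {
  set.seed(12)
  w <- init_weights(init_range = 0.5)
  x <- c(1.2, 0.7, 0.4, 0.9)
  st <- ref_train_step(w, x, 0.3, 0.99, eta = 1e-3, normalization = "none")
  before <- 0.5 * st$error^2
  y_after <- ref_forward(st$weights, x)$ys[[5]][st$chosen]
  after <- 0.5 * (st$outcome - y_after)^2
  expect_lte(after, before)
  # eta = 0 leaves weights untouched
  st0 <- ref_train_step(w, x, 0.3, 0.99, eta = 0, normalization = "none")
  expect_identical(st0$weights, w)
})

test_that("layer normalisation modes behave as documented", {
  set.seed(4)
  w <- list(matrix(runif(12, -3, 3), 3, 4), matrix(0.005, 2, 3))
  # absmax: every layer ends with max |w| = 1, signs preserved, idempotent
  n1 <- lapply(w, function(m) m / max(abs(m)))
  expect_equal(max(abs(n1[[1]])), 1)
  expect_equal(n1[[2]], matrix(1, 2, 3))          # constant layer becomes 1
  expect_identical(sign(n1[[1]]), sign(w[[1]]))
  n2 <- lapply(n1, function(m) m / max(abs(m)))
  expect_equal(n1, n2)                            # idempotent
  # max_bound leaves small layers untouched and bounds large ones
  st <- ref_train_step(w, c(1, 1, 1, 1), 0.2, 0.2, eta = 0,
                       normalization = "max_bound")
  expect_equal(max(abs(st$weights[[1]])), 1)
  expect_equal(st$weights[[2]], w[[2]])
})

test_that("without learning the network performs at chance on average", {
  # a single untrained network is a fixed arbitrary readout whose accuracy
  # fluctuates around chance; the ensemble mean settles at 50%
  accs <- vapply(1:10, function(s)
    train_network(n_trials = 1000, eta = 0, seed = 30 + s)$accuracy, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("training lifts accuracy well above chance with errors near ties", {
  accs <- vapply(1:4, function(s) {
    fit <- train_network(seed = 400 + s)
    w <- tidy(fit)
    w <- w[w$trial > 2000 & !is.na(w$correct), ]
    dev_err <- mean(abs(w$ev_diff)[!w$correct])
    dev_ok  <- mean(abs(w$ev_diff)[w$correct])
    expect_lt(dev_err, dev_ok)
    fit$accuracy
  }, 0)
  expect_true(all(accs > 0.65))
  expect_gt(mean(accs), 0.75)
})

test_that("ensembles are deterministic and summarise per network", {
  e1 <- run_ensemble(2, base_seed = 9, n_trials = 200, analysis_window = 100)
  e2 <- run_ensemble(2, base_seed = 9, n_trials = 200, analysis_window = 100)
  expect_identical(e1$fits[[1]]$weights, e2$fits[[1]]$weights)
  expect_false(identical(e1$fits[[1]]$weights, e1$fits[[2]]$weights))
  td <- tidy(e1)
  expect_equal(nrow(td), 2)
  expect_equal(td$seed, c(10, 11))
  g <- glance(e1)
  expect_equal(g$mean_accuracy, mean(td$accuracy))
})
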