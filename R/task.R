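#' Reward and probability grids of the gamble task
#'
#' Each gamble is a (reward, probability) pair drawn from discrete grids:
#' reward on the 11-level grid \{0, 0.2, ..., 2.0\} (arbitrary units) and win
#' probability on the 11-level grid \{0, 0.1, ..., 1.0\}.  Grid values are
#' represented internally by integer indices 0..10 so that grid membership and
#' expected-value ties can be tested exactly, without floating-point drift:
#' two gambles have equal expected value iff the integer products
#' `reward_idx * prob_idx` are equal.
#'
#' @return A list with numeric vectors `reward` and `probability` (the grid
#'   levels) and `ev` (the sorted set of attainable expected values, i.e. all
#'   121 products).
#' @export
#' @examples
#' gamble_grids()$reward
gamble_grids <- function() {
  list(
    reward      = (0:10) / 5,
    probability = (0:10) / 10,
    ev          = sort(unique(as.vector(outer(0:10, 0:10)) / 50))
  )
}

#' Sample gambles from the discrete grids
#'
#' Reward and probability indices are drawn independently and uniformly from
#' their 11-level grids using the current R random stream (two `runif()`
#' columns, reward first).
#'
#' @param n Number of gambles.
#' @return A tibble with columns `reward`, `probability`, `reward_idx`,
#'   `prob_idx`, `ev`.
#' @export
#' @examples
#' set.seed(1)
#' sample_gambles(5)
sample_gambles <- function(n) {
  ridx <- grid_index(n)
  pidx <- grid_index(n)
  tibble::tibble(
    reward      = ridx / 5,
    probability = pidx / 10,
    reward_idx  = ridx,
    prob_idx    = pidx,
    ev          = (ridx * pidx) / 50
  )
}

# uniform draw of a grid index 0..10
grid_index <- function(n) {
  pmin(floor(stats::runif(n) * 11L), 10L)
}

#' Generate two-gamble trials
#'
#' Each trial presents an independent gamble on the right and on the left.
#' The network input vector is `(r_R, p_R, r_L, p_L)`: right-offer reward and
#' probability first.  The four grid indices per trial are drawn in the fixed
#' order right-reward, right-probability, left-reward, left-probability
#' (vectorised over trials, one `runif` block per column), so a given seed
#' always produces the same trial sequence.
#'
#' @param n_trials Number of trials.
#' @return A tibble with one row per trial: the two offers (`r_right`,
#'   `p_right`, `r_left`, `p_left` and their grid indices), expected values
#'   `ev_right`, `ev_left`, their difference `ev_diff = ev_left - ev_right`,
#'   and `ev_tie` (exact expected-value tie, decided on the integer grid).
#' @export
#' @examples
#' set.seed(1)
#' make_trials(3)
make_trials <- function(n_trials) {
  ridx_r <- grid_index(n_trials)
  pidx_r <- grid_index(n_trials)
  ridx_l <- grid_index(n_trials)
  pidx_l <- grid_index(n_trials)
  tibble::tibble(
    trial      = seq_len(n_trials),
    r_right    = ridx_r / 5,
    p_right    = pidx_r / 10,
    r_left     = ridx_l / 5,
    p_left     = pidx_l / 10,
    ridx_right = ridx_r,
    pidx_right = pidx_r,
    ridx_left  = ridx_l,
    pidx_left  = pidx_l,
    ev_right   = (ridx_r * pidx_r) / 50,
    ev_left    = (ridx_l * pidx_l) / 50,
    ev_diff    = (ridx_l * pidx_l - ridx_r * pidx_r) / 50,
    ev_tie     = ridx_r * pidx_r == ridx_l * pidx_l
  )
}

#' Input matrix of a trial table
#'
#' @param trials A tibble from [make_trials()].
#' @return A numeric matrix with one row per trial and columns
#'   `(r_right, p_right, r_left, p_left)`, the network input vectors.
#' @export
trial_inputs <- function(trials) {
  m <- as.matrix(trials[, c("r_right", "p_right", "r_left", "p_left")])
  dimnames(m) <- list(NULL, c("r_right", "p_right", "r_left", "p_left"))
  m
}

#' Sample Bernoulli outcomes of gambles
#'
#' Returns the gamble's reward with its win probability, otherwise 0.  One
#' uniform draw per gamble is consumed from the current random stream.
#'
#' @param gambles A data frame with columns `reward` and `probability`.
#' @return Numeric vector of realised rewards.
#' @export
#' @examples
#' set.seed(1)
#' sample_outcomes(sample_gambles(5))
sample_outcomes <- function(gambles) {
  stopifnot(all(c("reward", "probability") %in% names(gambles)))
  u <- stats::runif(nrow(gambles))
  ifelse(u < gambles$probability, gambles$reward, 0)
}
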