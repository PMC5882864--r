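#' Run the full study pipeline
#'
#' Trains an ensemble, runs all population analyses (tuning fractions,
#' layer-wise beta correlations, choice probability correlations, the fixed
#' expected-value probe) and the lesion sweep, and optionally writes the
#' tidy result tables plus a JSON summary and run manifest to `out_dir`.
#'
#' @param n_networks Ensemble size (study default 300).
#' @param n_trials Training trials per network (default 3000).
#' @param seed Base seed for the whole study.
#' @param out_dir Optional output directory; when given, writes
#'   `tuning.csv`, `correlations.csv`, `cpc.csv`, `common_currency.csv`,
#'   `lesions.csv`, `summary.json` and `manifest.json`.
#' @param lesions Run the lesion sweep (default `TRUE`).
#' @param smoke If `TRUE`, overrides sizes with a seconds-scale smoke
#'   configuration (3 networks, 300 trials, a reduced sweep).
#' @param ... Passed to [train_network()] (e.g. `normalization`).
#' @return A `choicenet_summary` list with the ensemble, all result tables
#'   and the headline statistics.
#' @export
#' @examples
#' s <- run_study(smoke = TRUE, seed = 1)
#' s$headline$mean_accuracy
run_study <- function(n_networks = 300, n_trials = 3000, seed = 1,
                      out_dir = NULL, lesions = TRUE, smoke = FALSE, ...) {
  analysis_window <- min(1000, n_trials)
  lesion_trials <- 1000
  if (smoke) {
    n_networks <- 3; n_trials <- 300; analysis_window <- 200
    lesion_trials <- 300
  }
  ens <- run_ensemble(n_networks, base_seed = seed, n_trials = n_trials,
                      analysis_window = analysis_window, ...)
  tuning <- compute_tuning(ens)
  fractions <- tuning_fractions(tuning)
  pairs <- list(c("EV_L", "EV_R"), c("rew_L", "rew_R"), c("prob_L", "prob_R"),
                c("rew_L", "prob_L"), c("rew_R", "prob_R"))
  correlations <- dplyr::bind_rows(
    purrr::map_dfr(pairs, ~ beta_correlation(tuning, .x[1], .x[2], "signed")),
    beta_correlation(tuning, "pos", "EV_L", "unsigned", pool_layers = TRUE),
    beta_correlation(tuning, "EV_L", "EV_R", "unsigned", pool_layers = TRUE),
    beta_correlation(tuning, "EV_L", "chosen_value", "unsigned",
                     pool_layers = TRUE))
  cpc <- choice_probability(ens)
  currency <- common_currency_probe(ens, seed = seed + 5000)
  lesion_tbl <- if (lesions)
    lesion_sweep(ens, n_trials = lesion_trials,
                 fractions = if (smoke) c(0.25, 0.75) else
                   c(0.05, 0.1, 0.25, 0.5, 0.75),
                 targets = if (smoke) c("3", "all") else
                   c("1", "2", "3", "all"))
  else NULL

  eg <- glance(ens)
  currency_units <- currency |>
    dplyr::distinct(.data$network, .data$unit, .keep_all = TRUE)
  headline <- list(
    mean_accuracy = eg$mean_accuracy,
    sd_accuracy = eg$sd_accuracy,
    min_tuned_fraction = min(fractions$fraction),
    ev_anticorrelation = stats::setNames(
      correlations$rho[correlations$var_x == "EV_L" &
                         correlations$var_y == "EV_R" &
                         correlations$mode == "signed"],
      paste0("layer", correlations$layer[correlations$var_x == "EV_L" &
                         correlations$var_y == "EV_R" &
                         correlations$mode == "signed"])),
    cpc_by_layer = tapply(abs(cpc$cpc), cpc$layer, mean, na.rm = TRUE),
    currency_rejection_rate = mean(currency_units$p_value < 0.05)
  )
  out <- structure(list(ensemble = ens, tuning = tuning,
                        fractions = fractions, correlations = correlations,
                        cpc = cpc, common_currency = currency,
                        lesions = lesion_tbl, headline = headline,
                        config = c(ens$config, list(n_networks = n_networks,
                                                    base_seed = seed))),
                   class = "choicenet_summary")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

write_study <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$tuning, file.path(out_dir, "tuning.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$cpc, file.path(out_dir, "cpc.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$common_currency,
                   file.path(out_dir, "common_currency.csv"), row.names = FALSE)
  if (!is.null(summary$lesions))
    utils::write.csv(summary$lesions, file.path(out_dir, "lesions.csv"),
                     row.names = FALSE)
  jsonlite::write_json(summary$headline, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(summary$config[setdiff(names(summary$config), "seed")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Reference values of the headline statistics
#'
#' The published values the study pipeline is compared against, with the
#' tolerance band used by [report()].
#'
#' @return A tibble `statistic`, `layer`, `reference`, `tolerance`.
#' @export
reference_statistics <- function() {
  tibble::tribble(
    ~statistic,          ~layer, ~reference, ~tolerance,
    "accuracy_pct",      NA,     85,   5,
    "rho_EV",            1,     -0.58, 0.15,
    "rho_EV",            2,     -0.90, 0.15,
    "rho_EV",            3,     -0.93, 0.15,
    "rho_rew",           1,     -0.42, 0.15,
    "rho_rew",           2,     -0.71, 0.15,
    "rho_rew",           3,     -0.79, 0.15,
    "rho_prob",          1,     -0.19, 0.15,
    "rho_prob",          2,     -0.48, 0.15,
    "rho_prob",          3,     -0.66, 0.15,
    "rho_int_left",      3,      0.53, 0.15,
    "rho_int_right",     3,      0.54, 0.15,
    "rho_pos_EV_uns",    NA,     0.20, 0.10,
    "rho_offers_uns",    NA,     0.08, 0.10,
    "rho_off_chosen_uns", NA,    0.35, 0.15
  )
}

#' Compare a study summary with the reference values
#'
#' @param summary A `choicenet_summary` from [run_study()].
#' @param tolerance Optional named tolerance overrides
#'   (`statistic` -> band half-width).
#' @return A tibble of computed versus reference statistics with a
#'   `within_band` flag, printed as a report; statistics that the run did
#'   not produce are listed as absent, and under-powered runs (fewer than 10
#'   networks) are flagged as not evaluated.
#' @export
report <- function(summary, tolerance = NULL) {
  stopifnot(inherits(summary, "choicenet_summary"))
  ref <- reference_statistics()
  if (!is.null(tolerance))
    ref$tolerance <- ifelse(ref$statistic %in% names(tolerance),
                            unname(tolerance[ref$statistic]), ref$tolerance)
  co <- summary$correlations
  pick <- function(vx, vy, md, ly) {
    r <- co$rho[co$var_x == vx & co$var_y == vy & co$mode == md &
                  (if (is.na(ly)) is.na(co$layer) else co$layer == ly)]
    if (length(r) == 0) NA_real_ else r
  }
  value <- purrr::map2_dbl(ref$statistic, ref$layer, function(s, l)
    switch(s,
      accuracy_pct = 100 * summary$headline$mean_accuracy,
      rho_EV = pick("EV_L", "EV_R", "signed", l),
      rho_rew = pick("rew_L", "rew_R", "signed", l),
      rho_prob = pick("prob_L", "prob_R", "signed", l),
      rho_int_left = pick("rew_L", "prob_L", "signed", l),
      rho_int_right = pick("rew_R", "prob_R", "signed", l),
      rho_pos_EV_uns = pick("pos", "EV_L", "unsigned", NA),
      rho_offers_uns = pick("EV_L", "EV_R", "unsigned", NA),
      rho_off_chosen_uns = pick("EV_L", "chosen_value", "unsigned", NA)))
  out <- dplyr::mutate(ref, value = value,
                       within_band = abs(value - .data$reference) <= .data$tolerance)
  n_net <- length(summary$ensemble$fits)
  out$within_band[is.na(out$value)] <- NA
  if (n_net < 10) {
    out$within_band <- NA
    message("report: fewer than 10 networks; statistics not evaluated ",
            "(n too small)")
  }
  for (i in seq_len(nrow(out))) {
    cat(sprintf("%-20s %s  value %7s  reference %6.2f +/- %.2f  %s\n",
                out$statistic[i],
                ifelse(is.na(out$layer[i]), "     ",
                       sprintf("(L%d) ", out$layer[i])),
                ifelse(is.na(out$value[i]), "absent",
                       sprintf("%7.2f", out$value[i])),
                out$reference[i], out$tolerance[i],
                ifelse(is.na(out$within_band[i]), "not evaluated",
                       ifelse(out$within_band[i], "ok", "OUTSIDE"))))
  }
  invisible(out)
}
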