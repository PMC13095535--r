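#' Sweep the selection-incentive coefficient lambda
#'
#' Trains the full model once per candidate `lambda` and reports held-out
#' discrimination together with the mean selection probability, so the
#' effect of the `-lambda * mean(S_d)` incentive on selection sparsity can
#' be inspected.
#'
#' @param cohort,signals Training data ([cohort_table()],
#'   [temporal_signals()]).
#' @param test_cohort,test_signals Held-out data for the reported metrics;
#'   `NULL` evaluates on the training data (flagged in the output).
#' @param lambdas Numeric vector of lambda values.
#' @param cfg Base [train_config()]; its `lambda` field is overridden.
#' @return Data frame with one row per lambda: `lambda`, `critic_auc`,
#'   `baseline_auc`, `S_d_mean` (final epoch), `L_total` (final epoch),
#'   `on_test`.
#' @export
sweep_lambda <- function(cohort, signals, lambdas = c(0, 0.01, 0.1, 1),
                         cfg = train_config(), test_cohort = NULL,
                         test_signals = NULL) {
  on_test <- !is.null(test_cohort)
  rows <- lapply(lambdas, function(lam) {
    cfg_l <- cfg
    cfg_l$lambda <- lam
    fit <- train_model(NULL, cohort, signals, cfg_l)
    ev <- if (on_test) {
      evaluate_model(fit, test_cohort, test_signals)
    } else {
      evaluate_model(fit, cohort, signals)
    }
    last <- fit$history[nrow(fit$history), ]
    data.frame(lambda = lam, critic_auc = ev$critic$auc,
               baseline_auc = ev$baseline$auc, S_d_mean = last$S_d_mean,
               L_total = last$L_total, on_test = on_test)
  })
  do.call(rbind, rows)
}
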