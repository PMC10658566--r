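#' Root mean square error
#'
#' `sqrt(mean((y - yhat)^2))`; smaller is better, in the units of the
#' response.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return Single non-negative numeric.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0) stop("empty input", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of `y`. Unit-free; 1 is a perfect fit, 0 matches the mean-only
#' predictor, and values can be negative on test data (reported as
#' computed, never clipped).
#'
#' @param y Observed values (length >= 2, non-zero variance).
#' @param yhat Predicted values, same length.
#' @return Single numeric <= 1.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2) stop("need at least two observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero variance in y", call. = FALSE)
  1 - sum((yhat - y)^2) / ss_tot
}

metric_row <- function(method, target, y, yhat) {
  data.frame(method = method, target = target,
             rmse = rmse(y, yhat), r2 = r_squared(y, yhat),
             n_test = length(y), stringsAsFactors = FALSE)
}

#' Compare the prediction methods on one random train/test split
#'
#' Splits the records 7:3 (by default), fits MLR, random forest and
#' XGBoost on the training rows with the published hyperparameters, and
#' evaluates RMSE and R-squared on the test rows for each requested
#' target. When per-drug simulation configs are supplied, Fick's-law
#' predictions for the test rows are evaluated on the same split without
#' any training; otherwise the Fick column is omitted (its per-drug
#' diffusion coefficients come from literature, not from the data).
#'
#' @param records Permeation records with the response column(s).
#' @param seed Integer seed driving the split and the ensemble fits.
#' @param targets Character subset of `c("amount", "percentage")`.
#' @param ratio Training fraction (default 0.7).
#' @param fick_configs Optional named list (by drug) of
#'   [simulation_config()] templates for the Fick's-law column; see
#'   [fick_predict()].
#' @return Data frame with one row per method x target: `method`,
#'   `target`, `rmse`, `r2`, `n_test`. Fully reproducible for a given
#'   seed.
#' @export
compare_methods <- function(records, seed,
                            targets = c("amount", "percentage"),
                            ratio = 0.7, fick_configs = NULL) {
  targets <- match.arg(targets, several.ok = TRUE)
  split <- split_train_test(records, ratio = ratio, seed = seed)
  out <- list()
  for (tg in targets) {
    ycol <- target_column(tg)
    if (!ycol %in% names(records)) {
      stop("records lack the '", ycol, "' column needed for the ", tg,
           " target", call. = FALSE)
    }
    test <- split$test[!is.na(split$test[[ycol]]), , drop = FALSE]
    y <- test[[ycol]]
    mlr <- suppressWarnings(fit_mlr(split$train, tg))
    rf <- fit_tree_model(split$train, tree_model_spec("rf", tg), seed = seed)
    xgb <- fit_tree_model(split$train, tree_model_spec("xgboost", tg),
                          seed = seed)
    out[[paste0("mlr_", tg)]] <- metric_row("MLR", tg, y, predict(mlr, test))
    out[[paste0("rf_", tg)]] <- metric_row("RF", tg, y, predict(rf, test))
    out[[paste0("xgb_", tg)]] <-
      metric_row("XGBoost", tg, y, predict(xgb, test))
    if (!is.null(fick_configs)) {
      fick <- fick_predict(test, fick_configs)
      yhat <- if (tg == "amount") fick$amount else fick$percentage
      out[[paste0("fick_", tg)]] <- metric_row("Fick", tg, y, yhat)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Fick's-law predictions for a set of records
#'
#' Runs the diffusion simulator once per drug (using the supplied config
#' template, which fixes the literature diffusion coefficient and the
#' patch geometry) and interpolates the curve at each record's permeation
#' time; the amount is rescaled to the record's drug loading (the model is
#' linear in the load). No training is involved.
#'
#' @param records Records to predict.
#' @param fick_configs Named list mapping each drug label to a
#'   [simulation_config()] whose `t_end` covers the record times.
#' @return Data frame with `amount` and `percentage` predictions, one row
#'   per record.
#' @export
fick_predict <- function(records, fick_configs) {
  drugs <- unique(as.character(records$drug))
  miss <- setdiff(drugs, names(fick_configs))
  if (length(miss)) {
    stop("no Fick config for drug(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  amount <- pct <- rep(NA_real_, nrow(records))
  for (dg in drugs) {
    cfg <- fick_configs[[dg]]
    curve <- run_simulation(cfg)
    rows <- which(records$drug == dg)
    t_h <- records$permeation_time[rows]
    frac <- stats::approx(curve$time_h, curve$percentage / 100, xout = t_h,
                          rule = 2)$y
    m_total <- records$drug_loading[rows]
    amount[rows] <- frac * m_total / window_area_cm2(cfg$device)
    pct[rows] <- 100 * frac
  }
  data.frame(amount = amount, percentage = pct)
}

#' Leave-one-drug-out validation
#'
#' Removes every record of one drug from the data, trains the model on the
#' remaining drugs, predicts the held-out drug's rows and reports RMSE and
#' R-squared. Probes extrapolation to unseen compounds: when the held-out
#' drug's loading lies outside the range spanned by the others, predictions
#' degrade markedly relative to a random split.
#'
#' @param records Permeation records.
#' @param drug Drug label to hold out (must be present).
#' @param spec A [tree_model_spec()], or `"mlr"` for the linear model.
#' @param seed Seed for the ensemble fit.
#' @return List with `predictions` (data frame of the held-out rows plus a
#'   `predicted` column) and `metrics` (one-row data frame).
#' @export
leave_one_drug_out <- function(records, drug,
                               spec = tree_model_spec("xgboost", "amount"),
                               seed = 1) {
  drugs <- as.character(records$drug)
  if (!drug %in% drugs) stop("unknown drug: ", drug, call. = FALSE)
  hold <- records[drugs == drug, , drop = FALSE]
  train <- records[drugs != drug, , drop = FALSE]
  if (identical(spec, "mlr")) {
    tg <- "amount"
    model <- suppressWarnings(fit_mlr(train, tg))
    label <- "MLR"
  } else {
    stopifnot(inherits(spec, "tree_model_spec"))
    tg <- spec$target
    model <- fit_tree_model(train, spec, seed = seed)
    label <- spec$family
  }
  ycol <- target_column(tg)
  hold <- hold[!is.na(hold[[ycol]]), , drop = FALSE]
  pred <- predict(model, hold)
  out <- as.data.frame(hold)
  out$predicted <- pred
  list(predictions = out,
       metrics = metric_row(paste0(label, " (LODO ", drug, ")"), tg,
                            hold[[ycol]], pred))
}
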