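#' Calibration statistics
#'
#' `R2 = 1 - RSS/TSS`, `RMSE_C = sqrt(RSS/n)`, `MAE = mean(|e|)` on the
#' training set. RMSEs divide by `n`, not `n - p`, matching common QSAR
#' reporting (set `df_correct` for the residual-df variant).
#'
#' @param y Observed values.
#' @param y_hat Fitted values.
#' @param df_correct Optional residual degrees of freedom to divide the
#'   RSS by instead of `n`.
#' @return List with `R2`, `RMSE_C`, `MAE`.
#' @export
calibration_stats <- function(y, y_hat, df_correct = NULL) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("zero total sum of squares; R2 undefined",
                     call. = FALSE)
  rss <- sum((y - y_hat)^2)
  denom <- if (is.null(df_correct)) length(y) else df_correct
  list(R2 = 1 - rss / tss,
       RMSE_C = sqrt(rss / denom),
       MAE = mean(abs(y - y_hat)))
}

#' Leave-one-out cross-validation via the hat-matrix shortcut
#'
#' PRESS residuals `e_(i) = e_i / (1 - h_i)` from a single fit;
#' `Q2_CV = 1 - PRESS/TSS`, `RMSE_CV = sqrt(PRESS/n)`. For any row with
#' `h_i = 1` (an exactly self-determining observation) the shortcut is
#' invalid and that fold is refit explicitly, with a warning.
#'
#' @param X Predictor matrix or `descriptor_matrix`.
#' @param y Endpoint vector.
#' @return List with `Q2_CV`, `RMSE_CV`, `press_residuals`.
#' @export
loo_cv <- function(X, y) {
  if (inherits(X, "descriptor_matrix")) X <- dm_values(X)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L)
    stop("leave-one-out needs n > p + 2", call. = FALSE)
  Xc <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xc)
  if (qx$rank < ncol(Xc)) stop("singular design", call. = FALSE)
  h <- rowSums(qr.Q(qx)^2)
  e <- drop(y - Xc %*% qr.coef(qx, y))
  press_res <- e / (1 - h)
  bad <- which(h >= 1 - 1e-12)
  if (length(bad)) {
    warning("hat diagonal = 1 for row(s) ",
            paste(bad, collapse = ", "), "; refitting those folds",
            call. = FALSE)
    for (i in bad) {
      f <- stats::lsfit(X[-i, , drop = FALSE], y[-i])
      press_res[i] <- y[i] - sum(c(1, X[i, ]) * f$coefficients)
    }
  }
  tss <- sum((y - mean(y))^2)
  press <- sum(press_res^2)
  list(Q2_CV = 1 - press / tss,
       RMSE_CV = sqrt(press / n),
       press_residuals = press_res)
}

#' External validation statistics
#'
#' `Q2_EXT = 1 - sum((y - y_hat)^2) / sum((y - y_bar_train)^2)` over the
#' validation compounds only, with the training-set mean in the
#' denominator (the F1 form); `RMSE_EXT = sqrt(mean((y - y_hat)^2))`.
#'
#' @param y_val Observed validation values.
#' @param y_hat_val Predicted validation values.
#' @param y_train_mean Mean endpoint of the training set.
#' @return List with `Q2_EXT`, `RMSE_EXT`.
#' @export
external_stats <- function(y_val, y_hat_val, y_train_mean) {
  stopifnot(length(y_val) == length(y_hat_val), length(y_val) >= 1L)
  denom <- sum((y_val - y_train_mean)^2)
  if (denom == 0)
    stop("validation values all equal the training mean; Q2_EXT undefined",
         call. = FALSE)
  list(Q2_EXT = 1 - sum((y_val - y_hat_val)^2) / denom,
       RMSE_EXT = sqrt(mean((y_val - y_hat_val)^2)))
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 * S_xy / (S_xx + S_yy + n * (x_bar - y_bar)^2)` with
#' uncentered (divide-by-nothing) sums of squares about the means:
#' agreement of predictions with observations around the identity line.
#' Always in `[-1, 1]` and never larger in magnitude than the Pearson
#' correlation.
#'
#' @param x Observed values.
#' @param y Predicted values.
#' @return The coefficient.
#' @export
ccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 && syy == 0)
    stop("both sequences constant; CCC undefined", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  2 * sxy / (sxx + syy + length(x) * (mean(x) - mean(y))^2)
}

# Through-origin regression pieces used by r2m and the Tropsha checklist,
# in the Golbraikh--Tropsha formulation: the slope k of resp on pred
# through the origin, and r0^2 = 1 - sum((pred - k*pred)^2) /
# sum((pred - mean(pred))^2). Note the numerator compares the predictor
# sequence with its own k-scaled version, so r0^2 < 1 whenever the
# through-origin line deviates from identity -- including for perfectly
# proportional (but rescaled) predictions, which is exactly the behavior
# the checklist relies on.
origin_fit <- function(resp, pred) {
  k <- sum(resp * pred) / sum(pred^2)
  r0sq <- 1 - sum((pred - k * pred)^2) / sum((pred - mean(pred))^2)
  list(k = k, r0sq = r0sq)
}

#' Roy's modified r-squared
#'
#' `r2m = r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r^2` is the squared
#' Pearson correlation of observed and predicted values and `r0^2` is the
#' Golbraikh--Tropsha through-origin coefficient for the regression of
#' observed on predicted (see the methods vignette for the exact form;
#' it penalizes any deviation of the through-origin slope from 1,
#' including pure rescaling). The reverse direction (predicted on
#' observed) is reported too, with their mean and absolute difference.
#'
#' @param y_obs Observed values.
#' @param y_pred Predicted values.
#' @return List with `r2m`, `r2m_reverse`, `r2m_mean`, `delta`.
#' @export
r2m <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3L)
  if (stats::var(y_obs) == 0 || stats::var(y_pred) == 0)
    stop("zero variance; r2m undefined", call. = FALSE)
  r2 <- stats::cor(y_obs, y_pred)^2
  fwd <- origin_fit(y_obs, y_pred)
  rev <- origin_fit(y_pred, y_obs)
  m1 <- r2 * (1 - sqrt(abs(r2 - fwd$r0sq)))
  m2 <- r2 * (1 - sqrt(abs(r2 - rev$r0sq)))
  list(r2m = m1, r2m_reverse = m2, r2m_mean = (m1 + m2) / 2,
       delta = abs(m1 - m2))
}

#' Golbraikh--Tropsha external-validation checklist
#'
#' Evaluates, on the external set: `Q2_CV > 0.5`; squared Pearson
#' correlation of observed vs predicted `> 0.6`; `(r2 - r0^2)/r2 < 0.1`
#' in at least one regression direction; through-origin slopes `k` and
#' `k'` within `[0.85, 1.15]` (inclusive bounds); and
#' `|r0^2 - r0'^2| < 0.3`. Every criterion is reported with its value and
#' pass flag even when it fails.
#'
#' @param y_val Observed validation values.
#' @param y_hat_val Predicted validation values.
#' @param q2_cv Leave-one-out `Q2_CV` of the model.
#' @return A data frame with columns `criterion`, `value`, `threshold`,
#'   `pass`.
#' @export
tropsha_checklist <- function(y_val, y_hat_val, q2_cv) {
  r2 <- stats::cor(y_val, y_hat_val)^2
  fwd <- origin_fit(y_val, y_hat_val)
  rev <- origin_fit(y_hat_val, y_val)
  frac_fwd <- (r2 - fwd$r0sq) / r2
  frac_rev <- (r2 - rev$r0sq) / r2
  rows <- list(
    c("Q2_CV > 0.5", q2_cv, "> 0.5", q2_cv > 0.5),
    c("R2_ext > 0.6", r2, "> 0.6", r2 > 0.6),
    c("(r2 - r0^2)/r2 < 0.1 (either direction)", min(frac_fwd, frac_rev),
      "< 0.1", frac_fwd < 0.1 || frac_rev < 0.1),
    c("0.85 <= k <= 1.15", fwd$k, "[0.85, 1.15]",
      fwd$k >= 0.85 && fwd$k <= 1.15),
    c("0.85 <= k' <= 1.15", rev$k, "[0.85, 1.15]",
      rev$k >= 0.85 && rev$k <= 1.15),
    c("|r0^2 - r0'^2| < 0.3", abs(fwd$r0sq - rev$r0sq), "< 0.3",
      abs(fwd$r0sq - rev$r0sq) < 0.3))
  data.frame(criterion = vapply(rows, `[[`, "", 1),
             value = as.numeric(vapply(rows, `[[`, "", 2)),
             threshold = vapply(rows, `[[`, "", 3),
             pass = as.logical(vapply(rows, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Toth F-test for influential training points
#'
#' `F = (1 - Q2_CV) / (1 - R2)`, compared with the upper critical value
#' of the F distribution at level `alpha` with `(n - p - 1, n - p - 1)`
#' degrees of freedom. The raw ratio is always returned so any other
#' threshold can be applied post hoc.
#'
#' @param q2_cv Leave-one-out `Q2_CV`.
#' @param r2 Calibration `R2` (must be `< 1`).
#' @param n Training-set size.
#' @param p Number of model descriptors.
#' @param alpha Significance level (default 0.05).
#' @return List with `F`, `critical`, `pass` (`TRUE` when no influential
#'   points are flagged, i.e. `F` below the critical value).
#' @export
toth_f <- function(q2_cv, r2, n, p, alpha = 0.05) {
  if (r2 >= 1) stop("R2 = 1: F ratio undefined", call. = FALSE)
  f <- (1 - q2_cv) / (1 - r2)
  df <- n - p - 1
  crit <- stats::qf(1 - alpha, df, df)
  list(F = f, critical = crit, pass = f < crit)
}

#' Full validation report for a fitted model
#'
#' Runs the whole statistic battery: calibration (R2, RMSE_C, MAE),
#' leave-one-out cross-validation (Q2_CV, RMSE_CV), external validation
#' (Q2_EXT, RMSE_EXT), concordance correlation and modified r2 on the
#' pooled train+validation predictions, the Golbraikh--Tropsha checklist
#' and the Toth F-test.
#'
#' @param model A `qsar_model` (its descriptors must be present in `m`).
#' @param m A `descriptor_matrix` covering the training and validation
#'   ILs.
#' @param y Named endpoint vector (names = il_id) or vector aligned with
#'   `m`.
#' @param train_ids,valid_ids Disjoint IL id sets partitioning the rows
#'   used.
#' @return A `validation_report` list; see the fields above, plus
#'   `n_train`, `n_valid`, `p` and the per-compound predictions.
#' @export
validate_model <- function(model, m, y, train_ids, valid_ids) {
  if (length(intersect(train_ids, valid_ids)))
    stop("training and validation ids overlap", call. = FALSE)
  if (is.null(names(y))) names(y) <- m$il_id
  X <- dm_values(m)[, model$descriptor_names, drop = FALSE]
  rownames(X) <- m$il_id
  miss <- setdiff(c(train_ids, valid_ids), m$il_id)
  if (length(miss))
    stop("ids not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y_tr <- y[train_ids]; y_va <- y[valid_ids]
  pred_tr <- predict(model, m[match(train_ids, m$il_id), , drop = FALSE])
  pred_va <- predict(model, m[match(valid_ids, m$il_id), , drop = FALSE])
  cal <- calibration_stats(y_tr, pred_tr)
  cv <- loo_cv(X[train_ids, , drop = FALSE], y_tr)
  ext <- external_stats(y_va, pred_va, mean(y_tr))
  pooled_obs <- c(y_tr, y_va)
  pooled_pred <- c(pred_tr, pred_va)
  rep <- list(R2 = cal$R2, RMSE_C = cal$RMSE_C, MAE = cal$MAE,
              Q2_CV = cv$Q2_CV, RMSE_CV = cv$RMSE_CV,
              Q2_EXT = ext$Q2_EXT, RMSE_EXT = ext$RMSE_EXT,
              CCC = ccc(pooled_obs, pooled_pred),
              r2m_overall = r2m(pooled_obs, pooled_pred),
              tropsha = tropsha_checklist(y_va, pred_va, cv$Q2_CV),
              toth = tryCatch(
                toth_f(cv$Q2_CV, cal$R2, length(y_tr),
                       length(model$descriptor_names)),
                error = function(e)  # R2 = 1: 0/0 ratio, nothing to flag
                  list(F = NA_real_, critical = NA_real_, pass = NA)),
              n_train = length(y_tr), n_valid = length(y_va),
              p = length(model$descriptor_names),
              predictions = data.frame(
                il_id = c(train_ids, valid_ids),
                set = rep(c("train", "valid"),
                          c(length(train_ids), length(valid_ids))),
                observed = unname(pooled_obs),
                predicted = unname(pooled_pred),
                stringsAsFactors = FALSE))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report (n_train = %d, n_valid = %d, p = %d)\n",
    x$n_train, x$n_valid, x$p))
  cat(sprintf("  R2 = %.4f  RMSE_C = %.4f  MAE = %.4f\n",
              x$R2, x$RMSE_C, x$MAE))
  cat(sprintf("  Q2_CV = %.4f  RMSE_CV = %.4f\n", x$Q2_CV, x$RMSE_CV))
  cat(sprintf("  Q2_EXT = %.4f  RMSE_EXT = %.4f\n", x$Q2_EXT, x$RMSE_EXT))
  cat(sprintf("  CCC = %.4f  r2m(overall) = %.4f  Toth F = %.3f (%s)\n",
              x$CCC, x$r2m_overall$r2m_mean, x$toth$F,
              if (isTRUE(x$toth$pass)) "pass"
              else if (isFALSE(x$toth$pass)) "FAIL" else "n/a"))
  cat("  Tropsha criteria passed:", sum(x$tropsha$pass), "/",
      nrow(x$tropsha), "\n")
  invisible(x)
}
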