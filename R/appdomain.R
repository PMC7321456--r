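#' Applicability domain by the standardization approach
#'
#' Each descriptor of each query compound is standardized against the
#' training set: `s_ki = |x_ki - mean_i(train)| / sd_i(train)` (sample
#' standard deviations). A compound is inside the domain if its largest
#' `s` is at most 3, an X-outlier if its smallest `s` exceeds 3, and
#' otherwise judged by `s_new = mean_k(s) + 1.28 * sd_k(s)` (again the
#' sample sd over its own `s` values): outlier iff `s_new > 3`.
#'
#' @param X_train Training descriptor matrix (model-descriptor space
#'   only).
#' @param X_query Query rows, same columns.
#' @return A data frame per query compound: `id`, `s_max`, `s_min`,
#'   `s_new` (`NA` when the max/min rule already decides), and `class`
#'   (`"inside"` / `"outlier"`).
#' @export
ad_standardization <- function(X_train, X_query) {
  if (inherits(X_train, "descriptor_matrix")) X_train <- dm_values(X_train)
  if (inherits(X_query, "descriptor_matrix")) X_query <- dm_values(X_query)
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  stopifnot(identical(colnames(X_train), colnames(X_query)))
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero-spread training column(s): ",
         paste(colnames(X_train)[sdv == 0], collapse = ", "),
         "; filter constants before AD assessment", call. = FALSE)
  ids <- rownames(X_query) %||% as.character(seq_len(nrow(X_query)))
  out <- data.frame(id = ids, s_max = NA_real_, s_min = NA_real_,
                    s_new = NA_real_, class = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(X_query))) {
    s <- abs(X_query[k, ] - mu) / sdv
    out$s_max[k] <- max(s); out$s_min[k] <- min(s)
    if (max(s) <= 3) {
      out$class[k] <- "inside"
    } else if (min(s) > 3) {
      out$class[k] <- "outlier"
    } else {
      s_new <- mean(s) + 1.28 * stats::sd(s)
      out$s_new[k] <- s_new
      out$class[k] <- if (s_new > 3) "outlier" else "inside"
    }
  }
  out
}

#' Applicability domain by leverage
#'
#' Leverages `h = x (X'X)^{-1} x'` with intercept-augmented rows, warning
#' threshold `h* = 3 p' / n` (`p'` = number of model variables plus one,
#' `n` = training-set size), and standardized residuals `e / rmse` using
#' the single training calibration RMSE as sigma for training and query
#' compounds alike, so the +-3 sigma band is well defined across sets.
#' Classes: `inside`; `good_leverage` (`h > h*`, residual within the
#' band -- an extrapolated, less reliable prediction); `response_outlier`
#' (|standardized residual| > 3); `structural_response_outlier` (both).
#'
#' @param X_train Training descriptor matrix (model-descriptor space).
#' @param X_query Query rows, same columns (may be the training matrix
#'   itself).
#' @param residuals Residuals of the query compounds under the model.
#' @param rmse Training calibration RMSE used as sigma.
#' @return A data frame per query compound: `id`, `h`, `h_star`,
#'   `std_residual`, `class`.
#' @export
ad_leverage <- function(X_train, X_query, residuals, rmse) {
  if (inherits(X_train, "descriptor_matrix")) X_train <- dm_values(X_train)
  if (inherits(X_query, "descriptor_matrix")) X_query <- dm_values(X_query)
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  stopifnot(identical(colnames(X_train), colnames(X_query)),
            nrow(X_query) == length(residuals), rmse > 0)
  A <- cbind(1, X_train)
  XtX <- crossprod(A)
  inv <- tryCatch(solve(XtX), error = function(e)
    stop("singular training design; leverage undefined", call. = FALSE))
  Q <- cbind(rep(1, nrow(X_query)), X_query)
  h <- rowSums((Q %*% inv) * Q)
  p_prime <- ncol(A)
  h_star <- 3 * p_prime / nrow(X_train)
  sr <- residuals / rmse
  cls <- ifelse(abs(sr) > 3,
                ifelse(h > h_star, "structural_response_outlier",
                       "response_outlier"),
                ifelse(h > h_star, "good_leverage", "inside"))
  data.frame(id = rownames(X_query) %||%
               as.character(seq_len(nrow(X_query))),
             h = h, h_star = rep(h_star, nrow(X_query)),
             std_residual = sr, class = as.character(cls),
             stringsAsFactors = FALSE)
}

#' Williams-plot data
#'
#' Per-compound leverage and standardized residual, plus the two domain
#' boundaries (`h*` and +-3), ready for plotting; the core package does
#' no rendering.
#'
#' @param leverage_results Output of [ad_leverage()] (possibly several
#'   row-bound sets).
#' @return List with `points` (id, h, std_residual, class) and
#'   `thresholds` (`h_star`, `sigma_band = 3`).
#' @export
williams_data <- function(leverage_results) {
  pts <- leverage_results[, c("id", "h", "std_residual", "class"),
                          drop = FALSE]
  list(points = pts,
       thresholds = list(h_star = unique(leverage_results$h_star),
                         sigma_band = 3))
}

#' Applicability-domain report for a fitted model
#'
#' Applies both AD methods in the model's selected-descriptor space (the
#' domain is defined by the model's variables, which is also what the
#' `h* = 3p'/n` threshold presumes) to training and validation compounds.
#'
#' @param model A `qsar_model` with a fit cache (from [fit_ols()] or
#'   [stepwise_select()]), or any `qsar_model` plus explicit `y`.
#' @param m A `descriptor_matrix` covering all compounds.
#' @param y Named endpoint vector.
#' @param train_ids,valid_ids Compound id sets.
#' @return An `ad_report`: data frame with one row per compound carrying
#'   both methods' results, plus attribute `"h_star"`.
#' @export
assess_ad <- function(model, m, y, train_ids, valid_ids = character(0)) {
  if (is.null(names(y))) names(y) <- m$il_id
  vals <- dm_values(m)[, model$descriptor_names, drop = FALSE]
  rownames(vals) <- m$il_id
  X_tr <- vals[train_ids, , drop = FALSE]
  all_ids <- c(train_ids, valid_ids)
  X_all <- vals[all_ids, , drop = FALSE]
  pred <- predict(model, m[match(all_ids, m$il_id), , drop = FALSE])
  res <- y[all_ids] - pred
  rmse <- sqrt(mean((y[train_ids] -
                       predict(model,
                               m[match(train_ids, m$il_id), ,
                                 drop = FALSE]))^2))
  std <- ad_standardization(X_tr, X_all)
  lev <- ad_leverage(X_tr, X_all, unname(res), rmse)
  out <- data.frame(id = all_ids,
                    set = rep(c("train", "valid"),
                              c(length(train_ids), length(valid_ids))),
                    std_class = std$class, s_max = std$s_max,
                    s_min = std$s_min, s_new = std$s_new,
                    h = lev$h, std_residual = lev$std_residual,
                    lev_class = lev$class,
                    stringsAsFactors = FALSE)
  attr(out, "h_star") <- lev$h_star[1]
  class(out) <- c("ad_report", "data.frame")
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf("ad_report: %d compounds, h* = %.4f\n", nrow(x),
              attr(x, "h_star")))
  cat("  standardization outliers:", sum(x$std_class == "outlier"),
      "| leverage classes:",
      paste(names(table(x$lev_class)), table(x$lev_class),
            collapse = ", "), "\n")
  NextMethod()
}
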