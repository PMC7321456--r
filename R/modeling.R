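#' Construct a QSAR model object
#'
#' @param descriptor_names Ordered descriptor labels (block tags included).
#' @param coefficients Numeric coefficients, same order.
#' @param intercept Intercept.
#' @param training_ids IL ids the model was trained on (may be empty for a
#'   literature equation).
#' @param criterion_used Label of the selection criterion (or `"fixed"`).
#' @param representation Representation tag (`"separate_ions"`,
#'   `"ionic_pair"`, or `NA`).
#' @param fit Internal fit cache (residuals, fitted, hat, sigma); optional.
#' @return A `qsar_model`.
#' @export
qsar_model <- function(descriptor_names, coefficients, intercept,
                       training_ids = character(0),
                       criterion_used = "fixed",
                       representation = NA_character_, fit = NULL) {
  stopifnot(length(coefficients) == length(descriptor_names))
  structure(list(descriptor_names = descriptor_names,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                descriptor_names),
                 intercept = as.numeric(intercept),
                 training_ids = training_ids,
                 criterion_used = criterion_used,
                 representation = representation,
                 fit = fit),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, digits = 4, ...) {
  terms <- paste(sprintf("%+g %s", signif(x$coefficients, digits),
                         x$descriptor_names), collapse = " ")
  cat("qsar_model: y =", signif(x$intercept, digits), terms, "\n")
  cat("  criterion:", x$criterion_used,
      " n_train:", length(x$training_ids), "\n")
  invisible(x)
}

#' Fit an ordinary least-squares MLR model
#'
#' Intercept-augmented least squares via [stats::lm()]. Residuals, fitted
#' values and the hat diagonal are cached on the model for the validation
#' and applicability-domain stages.
#'
#' @param X Numeric matrix or `descriptor_matrix` of predictors.
#' @param y Endpoint vector (log10 EC50 in mM in the intended use).
#' @param ids Row identifiers (defaults to rownames / il_id).
#' @param representation Representation tag stored on the model.
#' @return A `qsar_model` with a populated `fit` cache.
#' @export
fit_ols <- function(X, y, ids = NULL, representation = NA_character_) {
  if (inherits(X, "descriptor_matrix")) {
    if (is.null(ids)) ids <- X$il_id
    if (is.na(representation))
      representation <- attr(X, "representation")
    X <- dm_values(X)
  }
  X <- as.matrix(X)
  if (is.null(ids)) ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in design", call. = FALSE)
  p <- ncol(X)
  if (nrow(X) <= p + 1L)
    stop("need n > p + 1 (", nrow(X), " rows, ", p, " descriptors)",
         call. = FALSE)
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = dat)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    bad <- names(beta)[is.na(beta)]
    stop("singular design; collinear column(s): ",
         paste(sub("^`|`$", "", bad), collapse = ", "), call. = FALSE)
  }
  res <- stats::residuals(fit)
  cache <- list(residuals = unname(res),
                fitted = unname(stats::fitted(fit)),
                hat = unname(stats::lm.influence(fit)$hat),
                y = unname(y),
                rmse_c = sqrt(mean(res^2)))
  qsar_model(colnames(X), beta[-1], beta[1], ids,
             criterion_used = "ols", representation = representation,
             fit = cache)
}

#' Predict endpoint values from a QSAR model
#'
#' @param object A `qsar_model`.
#' @param newdata A `descriptor_matrix`, data frame or matrix containing
#'   every descriptor the model uses (block tags must match).
#' @param ... Unused.
#' @return Numeric vector of predictions, named by `il_id` when available.
#' @examples
#' m4 <- load_fixture_models()[["M4"]]
#' predict(m4, data.frame(GMTI = 1000, MDDD = 5, AMW = 10,
#'                        check.names = FALSE))
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  ids <- if (inherits(newdata, "descriptor_matrix")) newdata$il_id else
    rownames(newdata)
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$descriptor_names, names(newdata))
    if (length(miss))
      stop("descriptor(s) absent from new data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    M <- as.matrix(newdata[, object$descriptor_names, drop = FALSE])
  } else {
    miss <- setdiff(object$descriptor_names, colnames(newdata))
    if (length(miss))
      stop("descriptor(s) absent from new data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    M <- newdata[, object$descriptor_names, drop = FALSE]
  }
  out <- drop(object$intercept + M %*% object$coefficients)
  if (!is.null(ids)) names(out) <- ids
  out
}

# Selection criteria: each returns a value to MINIMIZE for a candidate
# descriptor set (character vector of column names).
stepwise_criterion <- function(criterion, X, y) {
  force(X); force(y)
  n <- nrow(X)
  switch(criterion,
    mae = function(cols) {
      f <- stats::lsfit(X[, cols, drop = FALSE], y)
      mean(abs(f$residuals))
    },
    press = function(cols) {
      Xc <- cbind(1, X[, cols, drop = FALSE])
      qx <- qr(Xc)
      if (qx$rank < ncol(Xc)) return(Inf)
      h <- rowSums(qr.Q(qx)^2)
      e <- y - Xc %*% qr.coef(qx, y)
      if (any(h >= 1 - 1e-10)) return(Inf)
      sum((e / (1 - h))^2)
    },
    aic = function(cols) {
      f <- stats::lsfit(X[, cols, drop = FALSE], y)
      rss <- sum(f$residuals^2)
      n * log(rss / n) + 2 * (length(cols) + 2)
    },
    stop("unknown criterion '", criterion, "'", call. = FALSE))
}

#' Bidirectional stepwise descriptor selection for MLR
#'
#' Starts from the empty model. At each iteration every model with one
#' additional descriptor and every model with one descriptor fewer is
#' scored, and the best move is accepted if it strictly improves the
#' criterion; otherwise the search stops. Additions that would raise the
#' absolute pairwise Pearson correlation among selected descriptors above
#' `corr_max` are ineligible, and no addition is considered once
#' `max_features` is reached. Ties are broken by the canonical column
#' order of `X`, so the procedure is deterministic.
#'
#' @param X Numeric matrix or `descriptor_matrix` (constants already
#'   filtered out).
#' @param y Endpoint vector.
#' @param criterion `"press"` (leave-one-out predictive residual sum of
#'   squares; the default, since a purely training-error criterion never
#'   favors the removal branch), `"mae"` (training mean absolute error) or
#'   `"aic"`.
#' @param max_features Maximum number of descriptors in the model.
#' @param corr_max Within-model absolute-correlation cap.
#' @return A list with `model` (a `qsar_model`) and `trace` (a
#'   `stepwise_trace` data frame: iteration, action, candidate, criterion
#'   value, accepted flag).
#' @export
stepwise_select <- function(X, y, criterion = c("press", "mae", "aic"),
                            max_features = 3L, corr_max = 0.7) {
  criterion <- match.arg(criterion)
  ids <- NULL
  representation <- NA_character_
  if (inherits(X, "descriptor_matrix")) {
    ids <- X$il_id
    representation <- attr(X, "representation")
    X <- dm_values(X)
  }
  X <- as.matrix(X)
  stopifnot(max_features >= 1L, nrow(X) == length(y))
  score <- stepwise_criterion(criterion, X, y)
  cmat <- abs(suppressWarnings(stats::cor(X)))
  pool <- colnames(X)
  selected <- character(0)
  best <- Inf
  trace <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    moves <- list()
    if (length(selected) < max_features &&
        length(selected) + 2L < nrow(X)) {
      for (cand in setdiff(pool, selected)) {
        if (length(selected) &&
            any(cmat[cand, selected] > corr_max, na.rm = FALSE)) next
        moves[[length(moves) + 1L]] <-
          list(action = "add", candidate = cand,
               set = c(selected, cand))
      }
    }
    if (length(selected) > 1L) {
      for (cand in selected)
        moves[[length(moves) + 1L]] <-
          list(action = "remove", candidate = cand,
               set = setdiff(selected, cand))
    }
    if (!length(moves)) {
      if (!length(selected))
        stop("no admissible first descriptor", call. = FALSE)
      break
    }
    vals <- vapply(moves, function(m) score(m$set), numeric(1))
    k <- which.min(vals)   # first minimum = canonical tie-break
    improved <- vals[k] < best - 1e-12
    for (j in seq_along(moves))
      trace[[length(trace) + 1L]] <-
        data.frame(iteration = it, action = moves[[j]]$action,
                   candidate = moves[[j]]$candidate,
                   criterion_value = vals[j],
                   accepted = improved && j == k,
                   stringsAsFactors = FALSE)
    if (!improved) break
    best <- vals[k]
    selected <- moves[[k]]$set
  }
  if (!length(selected))
    stop("stepwise selection found no model that beats the empty model",
         call. = FALSE)
  model <- fit_ols(X[, selected, drop = FALSE], y, ids = ids,
                   representation = representation)
  model$criterion_used <- criterion
  trace <- do.call(rbind, trace)
  class(trace) <- c("stepwise_trace", "data.frame")
  list(model = model, trace = trace)
}

#' Replay a stepwise trace to its final descriptor set
#'
#' Applies the accepted moves of a [stepwise_select()] trace in order,
#' reproducing the selected descriptor set (used to audit a selection
#' run).
#'
#' @param trace A `stepwise_trace`.
#' @return Character vector of descriptor names.
#' @export
replay_trace <- function(trace) {
  sel <- character(0)
  acc <- trace[trace$accepted, , drop = FALSE]
  for (i in seq_len(nrow(acc)))
    sel <- if (acc$action[i] == "add") c(sel, acc$candidate[i])
           else setdiff(sel, acc$candidate[i])
  sel
}

#' The six literature model equations as executable models
#'
#' Fixed MLR equations for predicting log10 EC50 (mM) of ionic liquids
#' toward *E. coli*, exactly as printed (rounded coefficients): three
#' models on separate-ion descriptors (M1--M3) and three on ionic-pair
#' descriptors (M4--M6). Block tags: `^A` anion, `^C` cation, none =
#' ionic pair.
#'
#' @return Named list of six `qsar_model` objects, `"M1"` ... `"M6"`.
#' @examples
#' load_fixture_models()[["M1"]]
#' @export
load_fixture_models <- function() {
  spec <- list(
    M1 = list(int = 2.49,
              b = c("Psi_i_0^A" = -0.14, "SMTIV^C" = -0.001),
              repr = "separate_ions", type = "2D"),
    M2 = list(int = 2.52,
              b = c("L1m^C" = -0.12, "L1i^A" = -0.19),
              repr = "separate_ions", type = "3D"),
    M3 = list(int = 2.304,
              b = c("Psi_i_0^A" = -0.142, "QZZm^C" = -0.006),
              repr = "separate_ions", type = "2D,3D"),
    M4 = list(int = 4.15,
              b = c("GMTI" = -0.001, "MDDD" = -0.09, "AMW" = -0.16),
              repr = "ionic_pair", type = "2D"),
    M5 = list(int = 6.91,
              b = c("L/Bw" = -0.24, "RTv" = -1.05, "L3u" = 0.53),
              repr = "ionic_pair", type = "3D"),
    M6 = list(int = 3.49,
              b = c("GMTI" = -0.001, "E1e" = -3.21, "DISPm" = 0.04),
              repr = "ionic_pair", type = "2D,3D"))
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    m <- qsar_model(names(s$b), unname(s$b), s$int,
                    criterion_used = "fixed", representation = s$repr)
    m$descriptor_type <- s$type
    m
  })
  stats::setNames(out, names(spec))
}

#' Serialize a QSAR model to JSON
#'
#' Writes names, coefficients (full precision), intercept, training ids
#' and settings with stable key order; [read_model_json()] restores a
#' model that predicts identically.
#'
#' @param model A `qsar_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  obj <- list(descriptor_names = model$descriptor_names,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              training_ids = model$training_ids,
              criterion_used = model$criterion_used,
              representation = model$representation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qsar_model(obj$descriptor_names, obj$coefficients, obj$intercept,
             obj$training_ids %||% character(0),
             obj$criterion_used %||% "fixed",
             obj$representation %||% NA_character_)
}
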