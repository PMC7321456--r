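#' Benchmark configuration
#'
#' Describes the representation x descriptor-set grid to compare, the
#' stepwise settings, the variable pre-filter, and the train/validation
#' split. The split is always recorded in the result, since
#' reproducibility of the comparison depends on it.
#'
#' @param representations Subset of `c("separate_ions", "ionic_pair")`.
#' @param descriptor_sets Subset of `c("2d", "3d", "2d3d")`; `"3d"` and
#'   `"2d3d"` require imported descriptor tables and are never silently
#'   substituted by computed values.
#' @param criterion,max_features,corr_max Stepwise settings (see
#'   [stepwise_select()]).
#' @param filter_corr_max,const_tol Pool-stage filter settings (see
#'   [filter_variables()]).
#' @param split_ratio Training fraction (stratified by anion).
#' @param train_ids,valid_ids Explicit split (overrides `split_ratio`).
#' @param seed Seed for the split (and any other randomness).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(representations = c("separate_ions",
                                                 "ionic_pair"),
                             descriptor_sets = "2d",
                             criterion = "press",
                             max_features = 3L,
                             corr_max = 0.7,
                             filter_corr_max = 0.95,
                             const_tol = 1e-12,
                             split_ratio = 0.75,
                             train_ids = NULL, valid_ids = NULL,
                             seed = 1L) {
  representations <- match.arg(representations, several.ok = TRUE)
  descriptor_sets <- match.arg(descriptor_sets, c("2d", "3d", "2d3d"),
                               several.ok = TRUE)
  if (!length(representations) || !length(descriptor_sets))
    stop("need at least one representation and one descriptor set",
         call. = FALSE)
  structure(list(representations = representations,
                 descriptor_sets = descriptor_sets,
                 criterion = criterion,
                 max_features = as.integer(max_features),
                 corr_max = corr_max,
                 filter_corr_max = filter_corr_max,
                 const_tol = const_tol,
                 split_ratio = split_ratio,
                 train_ids = train_ids, valid_ids = valid_ids,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

# Stratified train/validation split by anion: within each anion stratum
# a split_ratio share (floor, but at least 1) goes to training.
stratified_split <- function(ils, ratio, seed) {
  withr::with_seed(seed, {
    train <- character(0)
    for (an in unique(ils$anion_id)) {
      ids <- ils$il_id[ils$anion_id == an]
      k <- max(1L, floor(ratio * length(ids)))
      train <- c(train, sample(ids, k))
    }
  })
  valid <- setdiff(ils$il_id, train)
  if (!length(valid))
    stop("split left no validation compounds; lower split_ratio",
         call. = FALSE)
  list(train_ids = ils$il_id[ils$il_id %in% train],
       valid_ids = ils$il_id[ils$il_id %in% valid])
}

assemble_config_matrix <- function(repr, set, ils, idesc, imported) {
  imp <- switch(set,
    "2d" = NULL,
    "3d" = ,
    "2d3d" = {
      if (!length(imported))
        stop("descriptor set '", set, "' requires imported descriptor ",
             "tables; none supplied", call. = FALSE)
      imported
    })
  own <- if (set == "3d") {
    # imported columns only: strip the computed table to its keys so the
    # assembly has a consistent interface
    empty <- idesc[, c("ion_id", "role"), drop = FALSE]
    attr(empty, "ion_totals") <- attr(idesc, "ion_totals")
    attr(empty, "provenance") <- "computed-2D"
    empty
  } else idesc
  if (repr == "separate_ions") assemble_separate(ils, own, imported = imp)
  else assemble_pair_additive(ils, own, imported = imp)
}

#' Run the representation x descriptor-set benchmark
#'
#' For every configuration in the grid: assemble the descriptor matrix,
#' pre-filter, run stepwise selection on the training split, then compute
#' the full validation report and applicability-domain report. The same
#' split is used for every configuration so the comparison is paired.
#' Deterministic given the config seed.
#'
#' @param data List with `registry` (an `ion_registry`), `ils` (an
#'   `il_table` with endpoints), and optionally `imported` (list of
#'   [import_descriptor_table()] outputs).
#' @param config A `benchmark_config`.
#' @return A `benchmark_result`: per-configuration list (`matrix` size,
#'   `filter` report, `model`, `validation`, `ad`, `pool_size`), plus
#'   `split`, `config` and the comparison from [compare_report()] when
#'   two or more configurations ran.
#' @export
run_benchmark <- function(data, config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  ils <- data$ils
  if (anyNA(ils$endpoint))
    stop("every IL needs an endpoint for benchmarking", call. = FALSE)
  y <- stats::setNames(ils$endpoint, ils$il_id)
  idesc <- ion_descriptors(data$registry)
  split <- if (!is.null(config$train_ids))
    list(train_ids = config$train_ids,
         valid_ids = config$valid_ids %||%
           setdiff(ils$il_id, config$train_ids))
  else stratified_split(ils, config$split_ratio, config$seed)
  configs <- expand.grid(repr = config$representations,
                         set = config$descriptor_sets,
                         stringsAsFactors = FALSE)
  runs <- list()
  pool_tabs <- list()
  for (i in seq_len(nrow(configs))) {
    repr <- configs$repr[i]; set <- configs$set[i]
    label <- paste0(if (repr == "separate_ions") "sep" else "pair",
                    "-", set)
    m <- assemble_config_matrix(repr, set, ils, idesc, data$imported)
    pool_tabs[[label]] <- m
    flt <- filter_variables(m, config$const_tol, config$filter_corr_max)
    m_tr <- flt$matrix[match(split$train_ids, flt$matrix$il_id), ,
                       drop = FALSE]
    sw <- stepwise_select(m_tr, y[split$train_ids],
                          criterion = config$criterion,
                          max_features = config$max_features,
                          corr_max = config$corr_max)
    val <- validate_model(sw$model, flt$matrix, y,
                          split$train_ids, split$valid_ids)
    ad <- assess_ad(sw$model, flt$matrix, y,
                    split$train_ids, split$valid_ids)
    runs[[label]] <- list(representation = repr, descriptor_set = set,
                          pool_size = ncol(m) - 1L,
                          filter = flt$report, model = sw$model,
                          trace = sw$trace, validation = val, ad = ad)
  }
  out <- list(runs = runs, split = split, config = config,
              pool_report = variable_pool_report(pool_tabs))
  out$comparison <- if (length(runs) >= 2L) compare_report(runs) else NULL
  class(out) <- "benchmark_result"
  out
}

#' Variable-pool accounting per configuration
#'
#' Column counts of the assembled (pre-filter) matrices: total, anion
#' block and cation block (both zero for the pair representation, whose
#' columns are untagged).
#'
#' @param matrices Named list of `descriptor_matrix` objects.
#' @return Data frame with `configuration`, `n_total`, `n_anion`,
#'   `n_cation`.
#' @export
variable_pool_report <- function(matrices) {
  rows <- lapply(names(matrices), function(nm) {
    cols <- setdiff(names(matrices[[nm]]), "il_id")
    data.frame(configuration = nm,
               n_total = length(cols),
               n_anion = sum(grepl("\\^A$", cols)),
               n_cation = sum(grepl("\\^C$", cols)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Comparative report over benchmark runs
#'
#' Side-by-side metric table sorted by external predictivity (highest
#' `Q2_EXT` first; ties broken by lower `RMSE_EXT`), the observed-vs-
#' predicted scatter data per configuration, and a short markdown
#' summary naming the best configuration.
#'
#' @param runs Named list of per-configuration results (as in
#'   `benchmark_result$runs`); at least two.
#' @return List with `table`, `best`, `scatter`, `markdown`.
#' @export
compare_report <- function(runs) {
  if (length(runs) < 2L)
    stop("comparison needs at least two configurations", call. = FALSE)
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    v <- runs[[nm]]$validation
    data.frame(configuration = nm,
               descriptors = paste(runs[[nm]]$model$descriptor_names,
                                   collapse = " + "),
               pool_size = runs[[nm]]$pool_size,
               R2 = v$R2, RMSE_C = v$RMSE_C, MAE = v$MAE,
               Q2_CV = v$Q2_CV, RMSE_CV = v$RMSE_CV,
               Q2_EXT = v$Q2_EXT, RMSE_EXT = v$RMSE_EXT,
               CCC = v$CCC, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$Q2_EXT, tab$RMSE_EXT), , drop = FALSE]
  rownames(tab) <- NULL
  scatter <- do.call(rbind, lapply(names(runs), function(nm)
    cbind(configuration = nm, runs[[nm]]$validation$predictions)))
  md <- c("# Benchmark comparison", "",
          sprintf("Best configuration by Q2_EXT (tie-break RMSE_EXT): **%s** (Q2_EXT = %.4f, RMSE_EXT = %.4f).",
                  tab$configuration[1], tab$Q2_EXT[1], tab$RMSE_EXT[1]),
          "",
          paste(utils::capture.output(print(
            tab[, c("configuration", "pool_size", "R2", "Q2_CV",
                    "Q2_EXT", "RMSE_EXT")], row.names = FALSE)),
            collapse = "\n"))
  list(table = tab, best = tab$configuration[1], scatter = scatter,
       markdown = paste(md, collapse = "\n"))
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result:", length(x$runs), "configuration(s);",
      length(x$split$train_ids), "train /", length(x$split$valid_ids),
      "validation ILs\n")
  if (!is.null(x$comparison))
    print(x$comparison$table[, c("configuration", "pool_size", "R2",
                                 "Q2_CV", "Q2_EXT", "RMSE_EXT")],
          row.names = FALSE)
  invisible(x)
}
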