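## Assembly of IL x descriptor matrices under the two representation
## strategies. A descriptor_matrix is a data.frame whose first column is
## il_id, with one column per descriptor; column labels carry the block tag
## of the model equations: suffix ^A = anion block, ^C = cation block, no
## suffix = ionic-pair level. Attributes: "representation" and per-column
## "provenance" (computed-2D / imported-3D / imported-other).

new_descriptor_matrix <- function(df, representation, provenance) {
  stopifnot(names(df)[1] == "il_id")
  vals <- df[, -1, drop = FALSE]
  if (any(!vapply(vals, is.numeric, logical(1))))
    stop("descriptor columns must be numeric", call. = FALSE)
  if (anyNA(vals))
    stop("descriptor matrix has missing values after assembly",
         call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate column labels: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  attr(df, "representation") <- representation
  attr(df, "provenance") <- provenance
  class(df) <- c("descriptor_matrix", "data.frame")
  df
}

#' Numeric value matrix of a descriptor matrix
#' @param m A `descriptor_matrix`.
#' @return Numeric matrix, rows named by `il_id`.
#' @export
dm_values <- function(m) {
  out <- as.matrix(m[, setdiff(names(m), "il_id"), drop = FALSE])
  rownames(out) <- m$il_id
  out
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("descriptor_matrix [%s]: %d ILs x %d descriptors\n",
              attr(x, "representation"), nrow(x), ncol(x) - 1L))
  NextMethod()
}

block_tag <- function(names, role) {
  paste0(names, if (role == "anion") "^A" else "^C")
}

# Role-specific sub-table of an ion-level descriptor table: keeps columns
# with complete values for that role, in alphabetical order.
role_block <- function(tab, role) {
  sub <- tab[tab$role == role, , drop = FALSE]
  desc <- setdiff(names(sub), c("ion_id", "role"))
  keep <- desc[vapply(desc, function(cl) !anyNA(sub[[cl]]), logical(1))]
  sub[, c("ion_id", sort(keep)), drop = FALSE]
}

#' Assemble the separate-ion (A|B) descriptor matrix
#'
#' Each IL row is the concatenation of its anion's descriptor block
#' (columns suffixed `^A`) and its cation's block (`^C`); ILs sharing an
#' ion share that block verbatim. The anion block precedes the cation
#' block and descriptors are alphabetical within a block, which makes the
#' downstream greedy filtering deterministic.
#'
#' @param ils An `il_table`.
#' @param ion_desc Ion-level descriptor table from [ion_descriptors()]
#'   (columns `ion_id`, `role`, descriptors).
#' @param imported Optional list of tables from
#'   [import_descriptor_table()]; ion-level tables contribute role-specific
#'   columns, pair-level tables contribute untagged columns joined by
#'   `il_id`.
#' @return A `descriptor_matrix` with `representation = "separate_ions"`.
#' @export
assemble_separate <- function(ils, ion_desc, imported = NULL) {
  tabs <- c(list(ion_desc), imported_of_level(imported, "ion"))
  blocks <- list()
  prov <- character(0)
  for (role in c("anion", "cation")) {
    ids <- ils[[paste0(role, "_id")]]
    cols <- list()
    for (tab in tabs) {
      blk <- role_block(tab, role)
      miss <- setdiff(unique(ids), blk$ion_id)
      desc <- setdiff(names(blk), "ion_id")
      if (!length(desc)) next
      if (length(miss))
        stop("no ", role, " descriptor row for ion(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      got <- blk[match(ids, blk$ion_id), desc, drop = FALSE]
      names(got) <- block_tag(desc, role)
      cols[[length(cols) + 1L]] <- got
      prov[names(got)] <- table_provenance(tab)
    }
    if (length(cols)) {
      blk_df <- do.call(cbind, cols)
      blocks[[role]] <- blk_df[, sort(names(blk_df)), drop = FALSE]
    }
  }
  df <- cbind(data.frame(il_id = ils$il_id, stringsAsFactors = FALSE),
              blocks$anion, blocks$cation)
  df <- append_pair_imports(df, ils, imported, prov)
  new_descriptor_matrix(df$df, "separate_ions", df$prov)
}

#' Assemble the ionic-pair ([A+B]) descriptor matrix by the additive scheme
#'
#' Generic descriptors are weighted sums of the two ion values:
#' stoichiometric weighting `d = n_A d_A + n_C d_C` (the default; a plain
#' sum for 1:1 salts) or mole-fraction weighting `d = x_A d_A + x_C d_C`
#' with `x = n / (n_A + n_C)`. Two descriptors are intensive and always
#' recombined exactly rather than weighted: AMW is recomputed as total
#' mass over total atoms of the whole salt, and MDDD as the heavy-atom-
#' weighted mean of the ion values -- both equal the value computed
#' directly on the disconnected union graph.
#'
#' @param ils An `il_table`.
#' @param ion_desc Ion-level table from [ion_descriptors()].
#' @param weighting `"stoichiometric"` or `"mole_fraction"`.
#' @param imported Optional list from [import_descriptor_table()]:
#'   pair-level tables join by `il_id`; ion-level tables are weight-summed
#'   (columns lacking a value for either ion are dropped with a warning).
#' @return A `descriptor_matrix` with `representation = "ionic_pair"`.
#' @export
assemble_pair_additive <- function(ils, ion_desc,
                                   weighting = c("stoichiometric",
                                                 "mole_fraction"),
                                   imported = NULL) {
  weighting <- match.arg(weighting)
  tabs <- c(list(ion_desc), imported_of_level(imported, "ion"))
  cols <- list()
  prov <- character(0)
  for (tab in tabs) {
    desc <- sort(setdiff(names(tab), c("ion_id", "role")))
    ai <- match(ils$anion_id, tab$ion_id)
    ci <- match(ils$cation_id, tab$ion_id)
    if (anyNA(ai) || anyNA(ci)) {
      miss <- unique(c(ils$anion_id[is.na(ai)], ils$cation_id[is.na(ci)]))
      stop("no descriptor row for ion(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    totals <- attr(tab, "ion_totals")
    for (nm in desc) {
      dA <- tab[[nm]][ai]; dC <- tab[[nm]][ci]
      if (anyNA(dA) || anyNA(dC)) {
        warning("pair assembly drops column '", nm,
                "': not defined for both ions", call. = FALSE)
        next
      }
      val <- pair_column(nm, dA, dC, ils, totals, ai, ci, weighting)
      cols[[nm]] <- val
      prov[nm] <- table_provenance(tab)
    }
  }
  df <- cbind(data.frame(il_id = ils$il_id, stringsAsFactors = FALSE),
              as.data.frame(cols, check.names = FALSE, optional = TRUE))
  df <- append_pair_imports(df, ils, imported, prov)
  new_descriptor_matrix(df$df, "ionic_pair", df$prov)
}

pair_column <- function(nm, dA, dC, ils, totals, ai, ci, weighting) {
  nA <- ils$n_anion; nC <- ils$n_cation
  if (!is.null(totals) && nm == "AMW") {
    ta <- totals[ai, ]; tc <- totals[ci, ]
    return((nA * ta$total_mass + nC * tc$total_mass) /
             (nA * ta$total_atoms + nC * tc$total_atoms))
  }
  if (!is.null(totals) && nm == "MDDD") {
    ta <- totals[ai, ]; tc <- totals[ci, ]
    return((nA * ta$n_heavy * dA + nC * tc$n_heavy * dC) /
             (nA * ta$n_heavy + nC * tc$n_heavy))
  }
  if (weighting == "stoichiometric") nA * dA + nC * dC
  else (nA * dA + nC * dC) / (nA + nC)
}

table_provenance <- function(tab) attr(tab, "provenance") %||% "imported-other"

imported_of_level <- function(imported, level) {
  if (is.null(imported)) return(list())
  if (inherits(imported, "imported_descriptors")) imported <- list(imported)
  Filter(function(t) attr(t, "level") == level, imported)
}

append_pair_imports <- function(df, ils, imported, prov) {
  for (tab in imported_of_level(imported, "pair")) {
    desc <- sort(setdiff(names(tab), "il_id"))
    if (!length(desc) || !nrow(tab)) next   # empty import: no-op
    i <- match(ils$il_id, tab$il_id)
    if (anyNA(i))
      stop("imported pair table lacks rows for IL(s): ",
           paste(ils$il_id[is.na(i)], collapse = ", "), call. = FALSE)
    clash <- intersect(desc, names(df))
    if (length(clash))
      stop("imported column(s) duplicate existing descriptors: ",
           paste(clash, collapse = ", "), call. = FALSE)
    for (nm in desc) {
      df[[nm]] <- tab[[nm]][i]
      prov[nm] <- table_provenance(tab)
    }
  }
  list(df = df, prov = prov)
}

#' Read an externally computed descriptor table
#'
#' Consumes descriptor values produced outside this package (typically 3D
#' descriptors from dedicated software), keyed by `ion_id` (ion level) or
#' `il_id` (pair level). Values are never recomputed or silently
#' substituted; provenance is recorded per column.
#'
#' @param path CSV file. First column must be the key (`ion_id` or
#'   `il_id`); an ion-level table may carry a `role` column (it is derived
#'   from the registry otherwise).
#' @param level `"ion"` or `"pair"`.
#' @param registry Required for ion level when the CSV has no `role`
#'   column.
#' @param provenance Provenance label for the columns
#'   (default `"imported-3D"`).
#' @return An `imported_descriptors` data frame tagged with its level;
#'   pass it to the `imported` argument of the assembly functions.
#' @examples
#' reg <- load_ion_registry(ilqsar_example("ions.csv"))
#' t4 <- import_descriptor_table(ilqsar_example("table4_pair_descriptors.csv"),
#'                               level = "pair")
#' @export
import_descriptor_table <- function(path, level = c("ion", "pair"),
                                    registry = NULL,
                                    provenance = "imported-3D") {
  level <- match.arg(level)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  key <- if (level == "ion") "ion_id" else "il_id"
  if (!nrow(df) || ncol(df) < 2L) {
    warning("imported descriptor table '", path,
            "' is empty; nothing merged", call. = FALSE)
    df <- stats::setNames(data.frame(character(0)), key)
  }
  if (!key %in% names(df))
    stop("imported ", level, "-level table must be keyed by '", key, "'",
         call. = FALSE)
  if (level == "ion" && !"role" %in% names(df)) {
    if (is.null(registry))
      stop("ion-level import needs a 'role' column or a registry",
           call. = FALSE)
    i <- match(df$ion_id, registry$ion_id)
    if (anyNA(i))
      stop("imported ions not in registry: ",
           paste(df$ion_id[is.na(i)], collapse = ", "), call. = FALSE)
    df$role <- registry$role[i]
  }
  desc <- setdiff(names(df), c("ion_id", "il_id", "role"))
  for (nm in desc) df[[nm]] <- suppressWarnings(as.numeric(df[[nm]]))
  attr(df, "level") <- level
  attr(df, "provenance") <- provenance
  class(df) <- c("imported_descriptors", "data.frame")
  df
}

#' Pre-filter descriptor columns: constants and correlated pairs
#'
#' First drops columns whose variance is at most `const_tol`; then walks
#' the remaining columns in their canonical order and drops any column
#' whose absolute Pearson correlation with an already kept column exceeds
#' `corr_max` (the earlier column is kept, so the result is
#' deterministic). Applying the filter to its own output changes nothing.
#'
#' @param m A `descriptor_matrix`.
#' @param const_tol Variance threshold for the constant filter.
#' @param corr_max Absolute-correlation threshold for the pairwise filter.
#' @return A list with `matrix` (the filtered `descriptor_matrix`) and
#'   `report` (a `filter_report`: `dropped_constant`,
#'   `dropped_correlated` with columns kept/dropped/abs_r, and the
#'   thresholds used).
#' @export
filter_variables <- function(m, const_tol = 1e-12, corr_max = 0.95) {
  vals <- dm_values(m)
  vars <- apply(vals, 2, stats::var)
  dropped_constant <- colnames(vals)[vars <= const_tol]
  keep <- setdiff(colnames(vals), dropped_constant)
  if (!length(keep))
    stop("all descriptor columns dropped as constant", call. = FALSE)
  kept <- character(0)
  dropped_correlated <- data.frame(kept = character(0), dropped = character(0),
                                   abs_r = numeric(0),
                                   stringsAsFactors = FALSE)
  for (cl in keep) {
    r <- if (length(kept))
      abs(stats::cor(vals[, cl], vals[, kept, drop = FALSE]))[1, ]
    else numeric(0)
    if (length(r) && max(r) > corr_max) {
      partner <- kept[which.max(r)]
      dropped_correlated <- rbind(dropped_correlated,
        data.frame(kept = partner, dropped = cl, abs_r = max(r),
                   stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, cl)
    }
  }
  if (!length(kept))
    stop("all descriptor columns dropped by filtering", call. = FALSE)
  out <- m[, c("il_id", kept), drop = FALSE]
  prov <- attr(m, "provenance")[kept]
  report <- structure(list(dropped_constant = dropped_constant,
                           dropped_correlated = dropped_correlated,
                           const_tol = const_tol, corr_max = corr_max),
                      class = "filter_report")
  list(matrix = new_descriptor_matrix(out, attr(m, "representation"), prov),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", length(x$dropped_constant), " constant, ",
      nrow(x$dropped_correlated), " correlated column(s) dropped ",
      sprintf("(const_tol = %g, corr_max = %g)\n", x$const_tol, x$corr_max),
      sep = "")
  invisible(x)
}

#' Range (max minus min) of a descriptor column
#' @param m A `descriptor_matrix`.
#' @param column Column label (with block tag if any).
#' @return `max - min` over the ILs in `m`.
#' @export
column_range <- function(m, column) {
  if (!column %in% names(m))
    stop("no column '", column, "'", call. = FALSE)
  diff(range(m[[column]]))
}
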