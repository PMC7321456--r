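#' Parse a SMILES string into a hydrogen-depleted molecular graph
#'
#' The SMILES is converted by OpenBabel (via \pkg{ChemmineOB}) to a
#' kekulized structure with all hydrogens made explicit; hydrogens are then
#' folded back into per-atom attached-H counts, so the returned graph covers
#' heavy atoms only. Formal charges are preserved. Bond orders are
#' deliberately discarded: none of the topological descriptors computed by
#' this package uses them, only connectivity.
#'
#' @param smiles A single SMILES string. Formal charges must be written
#'   explicitly (e.g. `"[S-]C#N"`, `"CCCC[n+]1ccccc1"`).
#' @return An object of class `molecular_graph`: a list with
#'   \describe{
#'     \item{element}{character, element symbol per heavy atom}
#'     \item{charge}{integer formal charge per heavy atom}
#'     \item{n_h}{integer count of attached hydrogens per heavy atom}
#'     \item{edges}{two-column integer matrix of heavy-atom bonds
#'       (each undirected bond once)}
#'     \item{component}{integer connected-component label per heavy atom}
#'     \item{smiles}{the input string}
#'   }
#' @examples
#' g <- parse_ion("[S-]C#N")   # thiocyanate
#' g$charge                    # -1 on sulfur
#' @export
parse_ion <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  if (!nzchar(trimws(smiles)))
    stop("empty SMILES string", call. = FALSE)
  mol <- smiles_to_molfile(smiles)
  g <- molfile_to_graph(mol)
  if (length(g$element) < 1L)
    stop("SMILES '", smiles, "' contains no heavy atoms", call. = FALSE)
  g$smiles <- smiles
  class(g) <- "molecular_graph"
  g
}

# SMILES -> V2000 molfile text with explicit hydrogens, via OpenBabel.
# OpenBabel also kekulizes aromatic SMILES and validates valence; a string
# it cannot read yields an empty conversion, which we turn into an error
# naming the input.
smiles_to_molfile <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    )),
    error = function(e) ""
  )
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L || !grepl("V2000", lines[4]))
    stop("cannot parse SMILES '", smiles, "'", call. = FALSE)
  lines
}

# Read the atom block, bond block and M CHG properties of a V2000 molfile
# written by OpenBabel, then drop explicit hydrogens into attached-H counts.
# Note: ChemmineR's molfile reader collapses single-atom molecules (e.g.
# bromide), so the few fixed-format fields needed here are read directly.
molfile_to_graph <- function(lines) {
  counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n_atom <- as.integer(counts[1])
  n_bond <- as.integer(counts[2])
  if (is.na(n_atom) || n_atom < 1L)
    stop("molfile with no atoms", call. = FALSE)
  at <- strsplit(trimws(lines[4L + seq_len(n_atom)]), "\\s+")
  element <- vapply(at, `[`, character(1), 4L)
  # old-style charge codes (field 6): 1..3 -> +3..+1, 5..7 -> -1..-3
  code <- suppressWarnings(as.integer(vapply(at, `[`, character(1), 6L)))
  charge <- integer(n_atom)
  known <- !is.na(code) & code %in% c(1L, 2L, 3L, 5L, 6L, 7L)
  charge[known] <- 4L - code[known]
  # M CHG property lines are authoritative when present
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    v <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- v[1]
    charge[v[2L * seq_len(k)]] <- v[2L * seq_len(k) + 1L]
  }
  bonds <- if (n_bond > 0L) {
    b <- strsplit(trimws(lines[4L + n_atom + seq_len(n_bond)]), "\\s+")
    cbind(as.integer(vapply(b, `[`, character(1), 1L)),
          as.integer(vapply(b, `[`, character(1), 2L)))
  } else {
    matrix(integer(), 0L, 2L)
  }
  heavy <- which(element != "H")
  n_h <- vapply(heavy, function(i) {
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    sum(element[nb] == "H")
  }, integer(1))
  new_index <- match(seq_len(n_atom), heavy)
  keep <- element[bonds[, 1]] != "H" & element[bonds[, 2]] != "H"
  edges <- cbind(new_index[bonds[keep, 1]], new_index[bonds[keep, 2]])
  storage.mode(edges) <- "integer"
  g <- list(element = element[heavy], charge = charge[heavy], n_h = n_h,
            edges = edges)
  g$component <- graph_components(length(g$element), edges)
  g
}

# Connected-component labels, numbered in order of first appearance.
graph_components <- function(n, edges) {
  parent <- seq_len(n)
  root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- root(edges[k, 1]); b <- root(edges[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  lab <- vapply(seq_len(n), root, integer(1))
  match(lab, unique(lab))
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("molecular_graph:", length(x$element), "heavy atoms,",
      nrow(x$edges), "bonds,",
      max(x$component), "component(s), net charge",
      sum(x$charge), "\n")
  invisible(x)
}

#' Net formal charge of a molecular graph
#' @param g A `molecular_graph`.
#' @return Integer net charge over heavy atoms.
#' @export
net_charge <- function(g) sum(g$charge)

#' Combine molecular graphs into one disconnected graph
#'
#' Used to build the heavy-atom graph of a whole ionic pair (or any salt)
#' as the disjoint union of its ion graphs, with stoichiometric replication.
#'
#' @param graphs List of `molecular_graph` objects.
#' @param counts Integer replication count per graph (default all 1).
#' @return A `molecular_graph` whose components are the inputs.
#' @export
graph_union <- function(graphs, counts = rep(1L, length(graphs))) {
  stopifnot(length(graphs) == length(counts), all(counts >= 1L))
  element <- character(0); charge <- integer(0); n_h <- integer(0)
  edges <- matrix(integer(), 0L, 2L)
  offset <- 0L
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    for (r in seq_len(counts[i])) {
      element <- c(element, g$element)
      charge <- c(charge, g$charge)
      n_h <- c(n_h, g$n_h)
      if (nrow(g$edges)) edges <- rbind(edges, g$edges + offset)
      offset <- offset + length(g$element)
    }
  }
  out <- list(element = element, charge = charge, n_h = n_h, edges = edges)
  out$component <- graph_components(length(element), edges)
  out$smiles <- paste(vapply(graphs, function(g) g$smiles %||% "?", ""),
                      collapse = ".")
  class(out) <- "molecular_graph"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an ion registry from CSV
#'
#' The registry CSV must have columns `ion_id`, `role`, `smiles` and may
#' have `name`. Every SMILES is parsed eagerly, so a registry that loads is
#' guaranteed usable by every downstream stage. Role/charge consistency is
#' enforced: cations must carry net charge >= +1, anions <= -1.
#'
#' @param path CSV file path.
#' @return An `ion_registry`: a data frame with columns `ion_id`, `role`,
#'   `smiles`, `name`, plus a list-column `graph` of parsed
#'   `molecular_graph`s.
#' @examples
#' reg <- load_ion_registry(ilqsar_example("ions.csv"))
#' nrow(reg)
#' @export
load_ion_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ion_id", "role", "smiles")
  if (!all(need %in% names(df)))
    stop("ion registry must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$ion_id
  build_ion_registry(df)
}

# Shared constructor for CSV-loaded and programmatically built registries.
build_ion_registry <- function(df) {
  errs <- character(0)
  dup <- df$ion_id[duplicated(df$ion_id)]
  for (d in unique(dup)) {
    rows <- which(df$ion_id == d)
    errs <- c(errs, sprintf("duplicate ion_id '%s' at rows %s", d,
                            paste(rows, collapse = ", ")))
  }
  bad_role <- which(!df$role %in% c("cation", "anion"))
  for (r in bad_role)
    errs <- c(errs, sprintf("row %d: unknown role '%s'", r, df$role[r]))
  graphs <- vector("list", nrow(df))
  for (r in seq_len(nrow(df))) {
    if (r %in% bad_role) next
    g <- tryCatch(parse_ion(df$smiles[r]), error = function(e) e)
    if (inherits(g, "error")) {
      errs <- c(errs, sprintf("row %d (%s): %s", r, df$ion_id[r],
                              conditionMessage(g)))
      next
    }
    q <- net_charge(g)
    if (df$role[r] == "cation" && q < 1L)
      errs <- c(errs, sprintf(
        "row %d: cation '%s' has net charge %d (expected >= +1)",
        r, df$ion_id[r], q))
    if (df$role[r] == "anion" && q > -1L)
      errs <- c(errs, sprintf(
        "row %d: anion '%s' has net charge %d (expected <= -1)",
        r, df$ion_id[r], q))
    graphs[[r]] <- g
  }
  if (length(errs))
    stop("ion registry errors:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  out <- df[, c("ion_id", "role", "smiles", "name")]
  out$graph <- graphs
  class(out) <- c("ion_registry", "data.frame")
  out
}

#' Write an ion registry back to CSV
#'
#' Writes the four identity columns (not the parsed graphs); reloading the
#' file with [load_ion_registry()] round-trips the records.
#'
#' @param registry An `ion_registry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ion_registry <- function(registry, path) {
  utils::write.csv(registry[, c("ion_id", "role", "smiles", "name")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Look up an ion's parsed graph in a registry
#' @param registry An `ion_registry`.
#' @param ion_id Ion identifier.
#' @return The `molecular_graph` for that ion.
#' @export
ion_graph <- function(registry, ion_id) {
  i <- match(ion_id, registry$ion_id)
  if (is.na(i)) stop("unknown ion '", ion_id, "'", call. = FALSE)
  registry$graph[[i]]
}

#' Load an ionic-liquid composition table from CSV
#'
#' Expected columns: `il_id`, `cation_id`, `anion_id`, `n_cation`,
#' `n_anion`, and optionally `endpoint` (log10 EC50 in mM; blank allowed).
#' Each row is checked against the registry: both ions must exist with the
#' right roles and the stoichiometric formal charges must balance exactly
#' (`n_cation * q_cation + n_anion * q_anion = 0`).
#'
#' @param path CSV file path.
#' @param registry An `ion_registry` from [load_ion_registry()].
#' @return An `il_table`: data frame with the columns above (endpoint `NA`
#'   when absent).
#' @examples
#' reg <- load_ion_registry(ilqsar_example("ions.csv"))
#' ils <- load_il_table(ilqsar_example("ils_synthetic24.csv"), reg)
#' head(ils)
#' @export
load_il_table <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("il_id", "cation_id", "anion_id", "n_cation", "n_anion")
  if (!all(need %in% names(df)))
    stop("IL table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"endpoint" %in% names(df)) df$endpoint <- NA_real_
  df$endpoint <- suppressWarnings(as.numeric(df$endpoint))
  build_il_table(df, registry)
}

build_il_table <- function(df, registry) {
  errs <- character(0)
  dup <- unique(df$il_id[duplicated(df$il_id)])
  if (length(dup))
    errs <- c(errs, paste("duplicate il_id:", paste(dup, collapse = ", ")))
  for (r in seq_len(nrow(df))) {
    for (side in c("cation", "anion")) {
      id <- df[[paste0(side, "_id")]][r]
      i <- match(id, registry$ion_id)
      if (is.na(i)) {
        errs <- c(errs, sprintf("row %d: unresolved %s '%s'", r, side, id))
      } else if (registry$role[i] != side) {
        errs <- c(errs, sprintf(
          "row %d: ion '%s' has role %s but is used as %s",
          r, id, registry$role[i], side))
      }
    }
    if (df$n_cation[r] < 1L || df$n_anion[r] < 1L)
      errs <- c(errs, sprintf("row %d: stoichiometric counts must be >= 1", r))
  }
  if (!length(errs)) {
    for (r in seq_len(nrow(df))) {
      qc <- net_charge(ion_graph(registry, df$cation_id[r]))
      qa <- net_charge(ion_graph(registry, df$anion_id[r]))
      tot <- df$n_cation[r] * qc + df$n_anion[r] * qa
      if (tot != 0L)
        errs <- c(errs, sprintf(
          "row %d (%s): charge imbalance %+d from %d x (%+d) + %d x (%+d)",
          r, df$il_id[r], tot, df$n_cation[r], qc, df$n_anion[r], qa))
    }
  }
  if (length(errs))
    stop("IL table errors:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  out <- df[, c("il_id", "cation_id", "anion_id", "n_cation", "n_anion",
                "endpoint")]
  class(out) <- c("il_table", "data.frame")
  out
}

#' Path to a packaged example/fixture file
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists available files.
#' @return A file path (or a character vector of file names).
#' @export
ilqsar_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "ilqsar")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("no packaged file '", file, "'; available: ",
         paste(list.files(dir), collapse = ", "), call. = FALSE)
  path
}
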