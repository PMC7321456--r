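#' Distance context for topological descriptors
#'
#' Precomputes everything the 2D topological descriptors need from a
#' hydrogen-depleted graph: the adjacency matrix, all-pairs shortest-path
#' (topological) distances, simple vertex degrees (delta), Kier--Hall
#' valence vertex degrees (delta_v), distance degrees (sigma, the row sums
#' of the distance matrix within a component) and Kier--Hall intrinsic
#' states. Distances between atoms in different connected components are
#' `Inf` -- flagged as unreachable, never silently large.
#'
#' @param g A `molecular_graph` from [parse_ion()].
#' @return A `distance_context`: list with `A` (adjacency), `D` (distance
#'   matrix), `delta`, `delta_v`, `sigma`, `I` (intrinsic states),
#'   `component`, and per-atom element data (`L`, `mass`, `n_h`).
#' @export
distance_context <- function(g) {
  n <- length(g$element)
  stopifnot(n >= 1L)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1
    A[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  if (n > 1L) {
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    D <- igraph::distances(ig)
  } else {
    D <- matrix(0, 1L, 1L)
  }
  dimnames(D) <- NULL
  ei <- element_index(g$element)
  tab <- element_table()
  delta <- rowSums(A)
  dv <- valence_degree(g$element, g$charge, g$n_h)
  Dfin <- D
  Dfin[!is.finite(Dfin)] <- 0   # sigma is a within-component row sum
  sigma <- rowSums(Dfin)
  L <- tab$L[ei]
  # Intrinsic state I = ((2/L)^2 * delta_v + 1) / delta. For an isolated
  # heavy atom (monatomic ion) delta = 0 and I is formally undefined; the
  # packaged convention treats delta as 1 there so monatomic anions such
  # as bromide still contribute a finite row (callers are warned at the
  # descriptor level).
  delta_eff <- ifelse(delta == 0, 1, delta)
  I <- ((2 / L)^2 * dv + 1) / delta_eff
  structure(list(A = A, D = D, delta = delta, delta_v = dv, sigma = sigma,
                 I = I, component = g$component, L = L,
                 mass = tab$mass[ei], n_h = g$n_h,
                 n = n, isolated = delta == 0),
            class = "distance_context")
}

#' Kier--Hall valence vertex degree
#'
#' For valence-shell quantum number `L = 2` (B through F):
#' `delta_v = Zv_eff - h`. For higher rows: `delta_v = (Zv_eff - h) /
#' (Z - Zv - 1)`, with the neutral valence-electron count in the
#' denominator. `Zv_eff = Zv - q` adjusts the electron count by the formal
#' charge `q`, which keeps the degree finite and charge-sensitive for ions
#' (an interpretation documented in the methods vignette, with examples:
#' S^- in thiocyanate gives 7/9, Br^- gives 8/27).
#'
#' @param element Character vector of element symbols.
#' @param charge Integer formal charges (default 0).
#' @param n_h Attached-hydrogen counts (default 0).
#' @return Numeric vector of valence degrees.
#' @examples
#' valence_degree("C", 0, 3)           # CH3 carbon: 1
#' valence_degree("S", -1, 0)          # thiocyanate sulfur: 7/9
#' @export
valence_degree <- function(element, charge = 0L, n_h = 0L) {
  ei <- element_index(element)
  tab <- element_table()
  if (any(element == "H"))
    stop("valence degree is defined for heavy atoms only", call. = FALSE)
  Zv_eff <- tab$Zv[ei] - charge
  ifelse(tab$L[ei] <= 2,
         Zv_eff - n_h,
         (Zv_eff - n_h) / (tab$Z[ei] - tab$Zv[ei] - 1))
}

check_connected <- function(ctx, what) {
  if (max(ctx$component) > 1L)
    stop(what, " requires a connected graph; found ",
         max(ctx$component), " components (compute per component and ",
         "combine, as the pair representation does)", call. = FALSE)
}

#' Average molecular weight
#'
#' Total atomic mass (hydrogens included) divided by total atom count
#' (hydrogens included). Defined for connected and disconnected graphs
#' alike, so the ionic-pair value is the union form, never an average of
#' ion AMWs.
#'
#' @param g A `molecular_graph`.
#' @return The AMW, in atomic mass units per atom.
#' @examples
#' amw(parse_ion("C"))   # methane: 16.043 / 5
#' @export
amw <- function(g) {
  ei <- element_index(g$element)
  h_mass <- element_table()$mass[element_table()$symbol == "H"]
  total_mass <- sum(element_table()$mass[ei]) + h_mass * sum(g$n_h)
  total_mass / (length(g$element) + sum(g$n_h))
}

#' Gutman molecular topological index
#'
#' `GMTI = sum over unordered atom pairs i < j of delta_i * delta_j * d_ij`.
#' Integer-valued on any connected graph. `ordered_pairs = TRUE` doubles
#' the value (the ordered-pair convention used by some software).
#'
#' @param ctx A `distance_context` over a connected graph.
#' @param ordered_pairs Sum over ordered pairs instead (doubles the value).
#' @return The index value (0 for a single atom).
#' @export
gmti <- function(ctx, ordered_pairs = FALSE) {
  check_connected(ctx, "GMTI")
  if (ctx$n < 2L) return(0)
  w <- outer(ctx$delta, ctx$delta) * ctx$D
  v <- sum(w[upper.tri(w)])
  if (ordered_pairs) 2 * v else v
}

#' Mean distance degree deviation
#'
#' `MDDD = mean(|sigma_i - mean(sigma)|)` where `sigma_i` is the row sum of
#' the topological distance matrix.
#'
#' @param ctx A `distance_context` over a connected graph.
#' @return The deviation (0 for highly symmetric graphs and single atoms).
#' @export
mddd <- function(ctx) {
  check_connected(ctx, "MDDD")
  mean(abs(ctx$sigma - mean(ctx$sigma)))
}

#' Schultz molecular topological index by valence vertex degrees
#'
#' `SMTIV = sum_i sum_j (A_ij + d_ij) * delta_v_j`: the Schultz MTI with
#' the simple degree vector replaced by Kier--Hall valence degrees.
#'
#' @param ctx A `distance_context` over a connected graph.
#' @return The index value (0 for a single atom).
#' @export
smtiv <- function(ctx) {
  check_connected(ctx, "SMTIV")
  if (anyNA(ctx$delta_v))
    stop("valence degree undefined for some atom", call. = FALSE)
  sum((ctx$A + ctx$D) %*% ctx$delta_v)
}

#' Intrinsic-state pseudoconnectivity index, type 0
#'
#' `Psi_i_0 = sum_i I_i^(-1/2)` over Kier--Hall intrinsic states
#' `I_i = ((2/L_i)^2 * delta_v_i + 1) / delta_i`. For a monatomic ion
#' (`delta = 0`) the packaged convention sets `delta = 1` and warns.
#'
#' @param ctx A `distance_context` over a connected graph.
#' @return The index value.
#' @export
psi_i_0 <- function(ctx) {
  check_connected(ctx, "Psi_i_0")
  if (any(ctx$isolated))
    warning("isolated heavy atom: intrinsic state uses the monatomic ",
            "convention delta = 1", call. = FALSE)
  if (any(ctx$I <= 0))
    stop("non-positive intrinsic state; Psi_i_0 undefined", call. = FALSE)
  sum(ctx$I^(-0.5))
}

#' Registry of computable 2D descriptors
#'
#' @return Named list of descriptor functions, each taking a
#'   `molecular_graph` plus its `distance_context` and returning a single
#'   numeric value. Names are the descriptor codes used in model equations.
#' @export
descriptor_registry <- function() {
  list(
    AMW     = function(g, ctx) amw(g),
    GMTI    = function(g, ctx) gmti(ctx),
    MDDD    = function(g, ctx) mddd(ctx),
    SMTIV   = function(g, ctx) smtiv(ctx),
    Psi_i_0 = function(g, ctx) psi_i_0(ctx)
  )
}

#' Compute a set of 2D descriptors for one molecular graph
#'
#' @param g A `molecular_graph`.
#' @param names Descriptor codes drawn from [descriptor_registry()]
#'   (default: all of them). Output order equals input order.
#' @param on_disconnected How to treat a multi-component graph for the
#'   distance-based descriptors: `"error"` (default; the caller must split
#'   components) or `"combine"` (per-component computation combined the way
#'   the ionic-pair representation defines: extensive indices summed, MDDD
#'   atom-weighted, AMW already union-level).
#' @return Named numeric vector, one value per requested descriptor.
#' @examples
#' compute_all(parse_ion("CCC"), c("GMTI", "MDDD"))
#' @export
compute_all <- function(g, names = NULL,
                        on_disconnected = c("error", "combine")) {
  on_disconnected <- match.arg(on_disconnected)
  reg <- descriptor_registry()
  if (is.null(names)) names <- base::names(reg)
  unknown <- setdiff(names, base::names(reg))
  if (length(unknown))
    stop("unknown descriptor(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(base::names(reg), collapse = ", "),
         call. = FALSE)
  if (!length(names)) return(stats::setNames(numeric(0), character(0)))
  multi <- max(g$component) > 1L
  if (!multi || on_disconnected == "error") {
    ctx <- distance_context(g)
    return(vapply(stats::setNames(names, names),
                  function(nm) reg[[nm]](g, ctx), numeric(1)))
  }
  pair_combine_descriptors(split_components(g), names)
}

# Split a molecular_graph into its connected components.
split_components <- function(g) {
  lapply(seq_len(max(g$component)), function(k) {
    keep <- which(g$component == k)
    idx <- match(seq_along(g$element), keep)
    sel <- g$edges[g$component[g$edges[, 1]] == k, , drop = FALSE]
    comp <- list(element = g$element[keep], charge = g$charge[keep],
                 n_h = g$n_h[keep],
                 edges = matrix(idx[sel], ncol = 2),
                 component = rep(1L, length(keep)), smiles = g$smiles %||% "?")
    class(comp) <- "molecular_graph"
    comp
  })
}

# Combine per-component descriptor values the way the ionic-pair
# representation defines them: extensive distance-based indices (GMTI,
# SMTIV, Psi_i_0) are summed over components; MDDD is the heavy-atom-count
# weighted mean of component MDDDs (i.e. total absolute deviation over
# total heavy atoms); AMW is recomputed on the union.
pair_combine_descriptors <- function(comps, names) {
  per <- lapply(comps, function(cg) {
    ctx <- distance_context(cg)
    reg <- descriptor_registry()
    vals <- vapply(stats::setNames(names, names),
                   function(nm) reg[[nm]](cg, ctx), numeric(1))
    list(vals = vals, n_heavy = length(cg$element), graph = cg)
  })
  n_heavy <- vapply(per, `[[`, numeric(1), "n_heavy")
  out <- stats::setNames(numeric(length(names)), names)
  for (nm in names) {
    v <- vapply(per, function(p) p$vals[[nm]], numeric(1))
    out[nm] <- switch(nm,
      MDDD = sum(v * n_heavy) / sum(n_heavy),
      AMW  = amw(graph_union(lapply(per, `[[`, "graph"))),
      sum(v))
  }
  out
}

#' Compute 2D descriptors for every ion in a registry
#'
#' @param registry An `ion_registry`.
#' @param names Descriptor codes (default: the full computable set).
#' @return A data frame, one row per ion (`ion_id`, `role`, then one
#'   column per descriptor). Carries the per-ion totals needed by the
#'   additive pair assembly (total mass, total atom count, heavy-atom
#'   count) as attribute `"ion_totals"`.
#' @examples
#' reg <- load_ion_registry(ilqsar_example("ions.csv"))
#' head(ion_descriptors(reg))
#' @export
ion_descriptors <- function(registry, names = NULL) {
  reg <- descriptor_registry()
  if (is.null(names)) names <- base::names(reg)
  vals <- t(vapply(registry$graph, function(g)
    suppressWarnings(compute_all(g, names, on_disconnected = "combine")),
    numeric(length(names))))
  if (length(names) == 1L) vals <- matrix(vals, ncol = 1L)
  colnames(vals) <- names
  out <- data.frame(ion_id = registry$ion_id, role = registry$role,
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  h_mass <- element_table()$mass[element_table()$symbol == "H"]
  totals <- t(vapply(registry$graph, function(g) {
    ei <- element_index(g$element)
    c(total_mass = sum(element_table()$mass[ei]) + h_mass * sum(g$n_h),
      total_atoms = length(g$element) + sum(g$n_h),
      n_heavy = length(g$element))
  }, numeric(3)))
  attr(out, "ion_totals") <- data.frame(ion_id = registry$ion_id, totals,
                                        stringsAsFactors = FALSE)
  attr(out, "provenance") <- "computed-2D"
  out
}
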