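#' Specification for the synthetic ionic-liquid generator
#'
#' The generator emulates the statistical structure the modeling pipeline
#' assumes: a small IL library built from alkyl-substituted ring-core
#' cation families crossed with common anions, an endpoint produced by a
#' sparse linear model in computed 2D descriptors plus Gaussian noise,
#' and a pool padded with uninformative descriptor columns standing in
#' for the large blocks a descriptor package would add.
#'
#' Defaults give 24 ILs: four cation families (imidazolium, pyridinium,
#' pyrrolidinium, piperidinium) x alkyl chain lengths {4, 8} = 8 cations,
#' crossed with three anions (bromide, thiocyanate,
#' bis(trifluoromethylsulfonyl)amide). The default true model,
#' `y = 11.5 - 0.45 MDDD + 0.14 Psi_i_0 - 1.20 AMW` on ionic-pair 2D
#' descriptors with `noise_sd = 0.2` log units, is designed for
#' identifiability on this 24-IL design: the three generating descriptors
#' are pairwise admissible under the within-model collinearity cap
#' (|r| <= 0.56 on the design, below the 0.7 default), and each
#' coefficient gives a partial-effect standard deviation of about 1.0
#' log unit, five times the noise level, keeping every true partial
#' effect above the greedy-selection noise floor of a 20-descriptor pool
#' at n = 24 (see the methods vignette).
#'
#' @param n_ils Number of ILs (at most #cations x #anions).
#' @param chain_lengths Integer alkyl chain lengths used per cation
#'   family.
#' @param families Subset of `c("imidazolium", "pyridinium",
#'   "pyrrolidinium", "piperidinium")`.
#' @param anions Subset of `c("Br", "SCN", "NTf2")`.
#' @param true_model List with `descriptors`, `beta`, `intercept`.
#' @param representation Representation under which the truth is defined
#'   (`"ionic_pair"` default, so the headline pair-2D configuration is
#'   the well-specified one; `"separate_ions"` available to study
#'   misspecification).
#' @param noise_sd Endpoint noise standard deviation (log10 EC50 units).
#' @param n_noise_descriptors Number of uninformative pair-level
#'   descriptor columns added to the selection pool.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_ils = 24L,
                           chain_lengths = c(4L, 8L),
                           families = c("imidazolium", "pyridinium",
                                        "pyrrolidinium", "piperidinium"),
                           anions = c("Br", "SCN", "NTf2"),
                           true_model = list(
                             descriptors = c("MDDD", "Psi_i_0", "AMW"),
                             beta = c(-0.45, 0.14, -1.20),
                             intercept = 11.5),
                           representation = c("ionic_pair",
                                              "separate_ions"),
                           noise_sd = 0.2,
                           n_noise_descriptors = 15L,
                           seed) {
  representation <- match.arg(representation)
  if (missing(seed)) stop("generator seed is mandatory", call. = FALSE)
  families <- match.arg(families, several.ok = TRUE)
  anions <- match.arg(anions, several.ok = TRUE)
  stopifnot(length(true_model$descriptors) == length(true_model$beta),
            all(chain_lengths >= 1L))
  n_cations <- length(families) * length(chain_lengths)
  if (n_ils > n_cations * length(anions))
    stop("n_ils exceeds #cations x #anions = ",
         n_cations * length(anions), call. = FALSE)
  structure(list(n_ils = as.integer(n_ils),
                 chain_lengths = as.integer(chain_lengths),
                 families = families, anions = anions,
                 true_model = true_model,
                 representation = representation,
                 noise_sd = noise_sd,
                 n_noise_descriptors = as.integer(n_noise_descriptors),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# SMILES templates. The N-alkyl chain is written first, then the
# (kekulizable aromatic or saturated) ring core carrying the +1 nitrogen.
cation_template <- function(family, chain) {
  core <- switch(family,
    imidazolium   = "n1cc[n+](C)c1",   # 1-alkyl-3-methylimidazolium
    pyridinium    = "[n+]1ccccc1",     # 1-alkylpyridinium
    pyrrolidinium = "[N+]1(C)CCCC1",   # 1-alkyl-1-methylpyrrolidinium
    piperidinium  = "[N+]1(C)CCCCC1",  # 1-alkyl-1-methylpiperidinium
    stop("unknown cation family '", family, "'", call. = FALSE))
  if (chain < 1L)
    stop("chain length must be >= 1 for family ", family, call. = FALSE)
  paste0(strrep("C", chain), core)
}

family_suffix <- c(imidazolium = "mim", pyridinium = "py",
                   pyrrolidinium = "mpyrr", piperidinium = "mpip")

anion_smiles <- c(Br = "[Br-]", SCN = "[S-]C#N",
                  NTf2 = "O=S(=O)(C(F)(F)F)[N-]S(=O)(=O)C(F)(F)F")

#' Generate the ion registry of a synthetic library
#'
#' Builds cation SMILES from the family templates at every requested
#' chain length, plus the anion set; all SMILES are parsed eagerly by the
#' registry constructor, so charges and valences are verified.
#'
#' @param spec A `generator_spec`.
#' @return An `ion_registry`.
#' @export
generate_ions <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  rows <- list()
  for (fam in spec$families)
    for (ch in spec$chain_lengths)
      rows[[length(rows) + 1L]] <- data.frame(
        ion_id = paste0("C", ch, family_suffix[[fam]]),
        role = "cation",
        smiles = cation_template(fam, ch),
        name = sprintf("1-C%d-alkyl %s", ch, fam),
        stringsAsFactors = FALSE)
  for (an in spec$anions)
    rows[[length(rows) + 1L]] <- data.frame(
      ion_id = an, role = "anion", smiles = anion_smiles[[an]],
      name = an, stringsAsFactors = FALSE)
  build_ion_registry(do.call(rbind, rows))
}

#' Generate a synthetic IL dataset with known ground truth
#'
#' Crosses the generated cations and anions, keeps `n_ils` combinations
#' (a seeded sample when fewer than the full cross), computes the 2D
#' descriptors, assembles the matrix under the truth representation and
#' draws `y = intercept + X beta + N(0, noise_sd^2)`. Also generates the
#' uninformative pair-level noise-descriptor table.
#'
#' @param spec A `generator_spec`.
#' @return List with `registry`, `ils` (an `il_table` with endpoints),
#'   `noise_descriptors` (an `imported_descriptors` table, pair level;
#'   `NULL` when `n_noise_descriptors = 0`), and `truth` (descriptors,
#'   beta, intercept, representation, per-IL noiseless values).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  registry <- generate_ions(spec)
  cations <- registry$ion_id[registry$role == "cation"]
  anions <- registry$ion_id[registry$role == "anion"]
  combos <- expand.grid(cation_id = cations, anion_id = anions,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  withr::with_seed(spec$seed, {
    if (spec$n_ils < nrow(combos))
      combos <- combos[sort(sample.int(nrow(combos), spec$n_ils)), ,
                       drop = FALSE]
    ils <- build_il_table(data.frame(
      il_id = paste0("[", combos$cation_id, "][", combos$anion_id, "]"),
      cation_id = combos$cation_id, anion_id = combos$anion_id,
      n_cation = 1L, n_anion = 1L, endpoint = NA_real_,
      stringsAsFactors = FALSE), registry)
    idesc <- ion_descriptors(registry)
    m <- if (spec$representation == "ionic_pair")
      assemble_pair_additive(ils, idesc)
    else
      assemble_separate(ils, idesc)
    miss <- setdiff(spec$true_model$descriptors, names(m))
    if (length(miss))
      stop("true-model descriptor(s) not computable under ",
           spec$representation, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
    Xt <- dm_values(m)[, spec$true_model$descriptors, drop = FALSE]
    noiseless <- spec$true_model$intercept +
      drop(Xt %*% spec$true_model$beta)
    ils$endpoint <- noiseless + stats::rnorm(nrow(ils), 0, spec$noise_sd)
    noise_tab <- NULL
    if (spec$n_noise_descriptors > 0L) {
      nd <- matrix(stats::rnorm(nrow(ils) * spec$n_noise_descriptors),
                   nrow(ils))
      colnames(nd) <- sprintf("ND%02d", seq_len(spec$n_noise_descriptors))
      noise_tab <- data.frame(il_id = ils$il_id, nd,
                              stringsAsFactors = FALSE)
      attr(noise_tab, "level") <- "pair"
      attr(noise_tab, "provenance") <- "imported-other"
      class(noise_tab) <- c("imported_descriptors", "data.frame")
    }
  })
  list(registry = registry, ils = ils, noise_descriptors = noise_tab,
       truth = list(descriptors = spec$true_model$descriptors,
                    beta = stats::setNames(spec$true_model$beta,
                                           spec$true_model$descriptors),
                    intercept = spec$true_model$intercept,
                    representation = spec$representation,
                    noise_sd = spec$noise_sd,
                    noiseless = stats::setNames(noiseless, ils$il_id)))
}

#' Packaged literature fixtures
#'
#' The printed reference values shipped with the package: the six model
#' equations, the ion-level descriptor examples (anion `L1i`, cation
#' `L1m`), the eight pair-level rows of `L/Bw`, `RTv`, `L3u` with their
#' printed ranges, and the named-ion registry. Values are stored as
#' 2-decimal text in `extdata` CSVs, exactly as printed.
#'
#' @return A `fixture_bundle` list: `models`, `table3` (ion-level
#'   `imported_descriptors`), `table4` (pair-level
#'   `imported_descriptors`), `table4_printed_range`, `registry`, `ils`.
#' @examples
#' fx <- load_fixtures()
#' fx$table4[fx$table4$il_id == "[C8mim][NTf2]", "RTv"]
#' @export
load_fixtures <- function() {
  reg <- load_ion_registry(ilqsar_example("ions.csv"))
  out <- list(
    models = load_fixture_models(),
    table3 = import_descriptor_table(
      ilqsar_example("table3_ion_descriptors.csv"), level = "ion",
      registry = reg),
    table4 = import_descriptor_table(
      ilqsar_example("table4_pair_descriptors.csv"), level = "pair"),
    table4_printed_range = c("L/Bw" = 1.17, RTv = 0.69, L3u = 1.02),
    registry = reg,
    ils = load_il_table(ilqsar_example("ils_synthetic24.csv"), reg))
  class(out) <- "fixture_bundle"
  out
}
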