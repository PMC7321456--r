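---
title: "Representing ionic-liquid structure in QSAR models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing ionic-liquid structure in QSAR models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An ionic liquid (IL) is a salt of a discrete organic cation and an anion —
structurally a *disconnected* ion pair. That disconnection makes the usual
first step of QSAR modeling, "compute molecular descriptors for the
compound", ambiguous: one can describe the two ions separately and
concatenate their descriptor blocks (the A|B, *separate-ion*
representation), or describe the pair as one object, here by the additive
scheme in which a pair descriptor is the stoichiometry-weighted sum of the
ion values (the [A+B], *ionic-pair* representation). `ilqsar` implements
both representations over a small engine of 2D topological descriptors,
the stepwise-MLR model building that is standard in this field, the full
internal/external validation battery, and two applicability-domain (AD)
methods, so that the representations can be compared end to end on the
same data.

The endpoint the package has in mind is log10 EC50 (mM) of ILs against
*Escherichia coli*, modeled as a linear function of two or three
descriptors, but nothing in the machinery is specific to that endpoint.

## Molecular graphs and descriptors

SMILES strings are parsed by OpenBabel (through `ChemmineOB`), which
kekulizes aromatic rings and makes hydrogens explicit; the package then
folds hydrogens into per-atom attached-H counts, producing a
hydrogen-depleted heavy-atom graph with formal charges. Bond orders are
discarded: every computed descriptor uses connectivity only, so
kekulization cannot affect any downstream value (asserted by test).
Atomic constants (mass, atomic number `Z`, valence electron count `Zv`,
valence-shell quantum number `L`) live in one packaged table
(`element_table()`), IUPAC 2021 conventional atomic weights, so numeric
expectations in examples are traceable to a single source.

The computed descriptor set is the 2D core that appears in the fixed model
equations:

* **AMW** — average molecular weight: total mass over total atom count,
  hydrogens included in both.
* **GMTI** — Gutman molecular topological index,
  $\sum_{i<j} \delta_i \delta_j d_{ij}$ over heavy-atom pairs, with
  $\delta$ the simple degree and $d_{ij}$ the shortest-path distance.
  Summation is over unordered pairs; an `ordered_pairs` flag doubles it,
  because descriptor software differs on this convention and the
  literature equation's scale does not disambiguate it.
* **MDDD** — mean distance degree deviation,
  $\tfrac1n \sum_i |\sigma_i - \bar\sigma|$ with $\sigma_i$ the row sums
  of the distance matrix.
* **SMTIV** — Schultz MTI with the degree vector replaced by Kier–Hall
  valence degrees: $\sum_i \sum_j (A_{ij} + d_{ij})\,\delta^v_j$.
* **Psi_i_0** — intrinsic-state pseudoconnectivity index, type 0:
  $\sum_i I_i^{-1/2}$ over Kier–Hall intrinsic states
  $I_i = ((2/L_i)^2 \delta^v_i + 1)/\delta_i$. The $-1/2$ exponent is
  fixed by analogy with the order-0 connectivity index.

Valence degrees follow the Kier–Hall scheme,
$\delta^v = Z^v_{\mathrm{eff}} - h$ for second-row atoms and
$\delta^v = (Z^v_{\mathrm{eff}} - h)/(Z - Z^v - 1)$ beyond, with
$Z^v_{\mathrm{eff}} = Z^v - q$ adjusted by the formal charge $q$. The
charge adjustment is an interpretation, not a literature formula: it
keeps intrinsic states finite and charge-sensitive for ions (thiocyanate
sulfur: $7/9$; bromide: $8/27$). Note that the *neutral* $Z^v$ stays in
the denominator, so the charge shifts the electron count, not the core
screening.

Two degenerate-input conventions are deliberate:

* **Monatomic ions** (bromide). Distance-based descriptors are 0, and the
  intrinsic state uses $\delta = 1$ in place of the undefined $\delta = 0$,
  with a warning. Anions must contribute *some* finite row — a registry
  containing bromide would otherwise poison every matrix.
* **Disconnected pairs.** Cross-ion topological distances do not exist,
  so pair-level computed descriptors are defined per connected component
  and recombined: extensive indices (GMTI, SMTIV, Psi_i_0) are summed,
  MDDD is the heavy-atom-weighted mean of component values (equivalently,
  total absolute deviation over total heavy atoms), and AMW is recomputed
  on the union — never averaged. Whether external descriptor software
  uses the same convention for disconnected structures is not
  documented there; this package's convention is at least exactly the
  additive scheme, and it is cross-checked against direct computation on
  the union graph.

## Representations

`assemble_separate()` concatenates the anion block (columns tagged `^A`)
and cation block (`^C`); ILs sharing an ion share that block verbatim,
which is what makes the separate-ion AD "exact" — every IL with the same
anion sits at the same anion-block coordinates. `assemble_pair_additive()`
computes $d = n_A d_A + n_C d_C$ (stoichiometric weighting, a plain sum
for 1:1 salts) or the mole-fraction variant $x_A d_A + x_C d_C$; the
weighted-sum reading and the plain-sum reading of the additive scheme are
one flag apart because the phrase "weighted by the molar fraction" is
genuinely ambiguous for 1:1 salts. AMW and MDDD bypass the weighting and
are recombined exactly (they are intensive).

Columns are ordered canonically — anion block before cation block,
alphabetical within a block — so the greedy correlation filter and the
stepwise tie-breaks are deterministic. Externally computed descriptors
(3D WHIM/GETAWAY-type values this package does not compute) are imported
from CSV at ion or pair level, never recomputed, with per-column
provenance.

`filter_variables()` drops near-constant columns (variance at most
`const_tol`, default 1e-12), then walks the column order dropping any
column with |Pearson r| above `corr_max` (default 0.95) against an
already-kept column. The filter is idempotent; the pool-stage 0.95 is
loose on purpose — the tight "uncorrelated descriptors" requirement
(default 0.7) is enforced *within* models by the stepwise procedure,
where it belongs.

## Model building

`fit_ols()` is ordinary least squares with an intercept; residuals,
fitted values and the hat diagonal are cached because the validation and
AD layers reuse them. `stepwise_select()` starts from the empty model
and, at each iteration, scores every model with one added and one removed
descriptor, accepting the best move only on strict improvement.
Additions breaching the within-model correlation cap are ineligible;
ties break by column order. The default criterion is leave-one-out PRESS
rather than training MAE: a pure training-error criterion can never favor
the removal branch, so a complexity-aware criterion is needed for the
bidirectional search to mean anything (training MAE and AIC are
available). `max_features` defaults to 3, matching the two-to-three
descriptor equations this model family uses. Every evaluated move is
recorded in a trace; `replay_trace()` reproduces the final selection, so
any configuration can be audited.

The six literature equations (M1–M6) ship as executable `qsar_model`
fixtures with their exactly-printed rounded coefficients — useful as
regression oracles and for propagating reference descriptor tables
through `predict()`.

## Validation battery

`validate_model()` reports: calibration $R^2$, RMSE, MAE; leave-one-out
$Q^2_{CV}$ and RMSE$_{CV}$ via the hat-diagonal PRESS shortcut (proved
equal to explicit refits in the tests, with an explicit-refit fallback
when some $h_i = 1$); external $Q^2_{EXT}$ in the train-mean (F1) form —
the denominator centers validation observations on the *training* mean,
which is the form consistent with "computed only on the validation set"
given training information; Lin's concordance correlation coefficient on
the pooled train+validation pairs; the modified $r^2_m$ statistics; the
Golbraikh–Tropsha checklist; and the Toth F-test
$F = (1 - Q^2_{CV})/(1 - R^2)$.

Numerical notes, all deliberate:

* RMSEs divide by $n$, not $n-p$, matching common QSAR reporting; a
  df-corrected variant is a parameter away.
* The through-origin $r_0^2$ uses the Golbraikh–Tropsha published form
  $r_0^2 = 1 - \sum(\hat y - k\hat y)^2 / \sum(\hat y - \bar{\hat y})^2$,
  which penalizes *any* deviation of the through-origin slope from 1 —
  including perfectly proportional, rescaled predictions, for which a
  naive through-origin $R^2$ would be exactly 1 and the statistic would
  lose its point.
* Slope bounds $0.85 \le k \le 1.15$ are inclusive.
* The F-test's degrees of freedom are not fixed by the formula's source;
  the package uses $(n-p-1, n-p-1)$ at $\alpha = 0.05$ and always reports
  the raw ratio so any other threshold can be applied afterwards. As
  noise vanishes the ratio tends not to 1 but to roughly
  $\big(\tfrac{n}{n-p-1}\big)^2$ (PRESS residuals carry a $1/(1-h)$
  inflation), which is why the test asserts "modestly above 1 and below
  the critical value" for clean data.
* When $R^2 = 1$ to machine precision the F ratio is 0/0; the report
  carries `NA` rather than failing, since a perfectly calibrated model
  has nothing to flag.

## Applicability domain

Both AD methods work in the model's selected-descriptor space only — the
domain is defined by the model's variables, which is also what the
leverage threshold $h^* = 3p'/n$ (with $p'$ = variables + 1) presumes.

The standardization approach computes
$s_{ki} = |x_{ki} - \bar x_i|/s_i$ against training means and *sample*
standard deviations (the source method's convention on this point is not
restated in the QSAR literature consistently; sample sd is used for both
the column sd and the compound-level sd of the $s$ profile). A compound
with $\max_i s_{ki} \le 3$ is inside; $\min_i s_{ki} > 3$ is an outlier;
otherwise $s_{new} = \bar s_k + 1.28\, \mathrm{sd}(s_k)$ decides at the
same cutoff of 3. The whole construction is invariant to affine
rescaling of any descriptor column.

The leverage approach computes $h = x (X^TX)^{-1} x^T$ on
intercept-augmented rows and standardizes residuals by the single
training calibration RMSE for training and validation compounds alike —
one $\sigma$ makes the $\pm 3\sigma$ band well defined across sets.
Compounds beyond $h^*$ but within the band are *good leverage* points
(extrapolated, hence less reliable, but not misfitted); residuals beyond
$\pm 3\sigma$ are response outliers. `williams_data()` exports the
points and both thresholds; the core does no plotting.

## The synthetic benchmark

There is no public per-IL data table to regress against, so the package
generates its own data with known truth. `generator_spec()` defaults
emulate the study design: 24 ILs from four cation families
(1-alkyl-3-methylimidazolium, 1-alkylpyridinium,
1-alkyl-1-methylpyrrolidinium, 1-alkyl-1-methylpiperidinium) at chain
lengths 4 and 8, crossed with bromide, thiocyanate and
bis(trifluoromethylsulfonyl)amide — the C4/C8 homolog design spreads the
size-driven descriptors the way the real library does. Endpoints are
drawn from a sparse linear model in computed pair-level 2D descriptors
plus Gaussian noise (`noise_sd = 0.2` log units), and the selection pool
is padded with 15 uninformative standard-normal "descriptor" columns so
that selection runs against a 20-column pool at $n = 24$. All randomness
flows from one mandatory seed.

**Why the default truth is
$y = 11.5 - 0.45\,\mathrm{MDDD} + 0.14\,\Psi^0_I - 1.20\,\mathrm{AMW}$.**
A support-recovery benchmark is only meaningful if the generating model
is *identifiable by the procedure under study*; otherwise it measures the
design's pathologies, not the selector. Three facts about the 24-IL
design drive the choice:

1. *Admissibility.* The five computed pair descriptors are strongly
   inter-correlated on this design (GMTI–MDDD $r = 0.80$,
   GMTI–$\Psi^0_I$ $r = 0.89$, SMTIV–$\Psi^0_I$ $r = 0.98$). A truth
   containing a pair with $|r| > 0.7$ can never be selected under the
   within-model collinearity cap — it is outside the search space by
   construction. The only admissible computed triple is
   (MDDD, $\Psi^0_I$, AMW), all pairwise $|r| \le 0.56$.
2. *Proxy exclusion.* GMTI correlates positively with all three of those
   descriptors, so any same-signed combination of them is proxied by
   GMTI alone; the greedy search then takes GMTI first and the cap locks
   the true descriptors out — a local optimum the strictly-improving
   bidirectional search cannot leave, at any signal strength. Making the
   large effect the GMTI-orthogonal one (AMW, $r = 0.29$ with GMTI) and
   giving MDDD and $\Psi^0_I$ opposite signs cancels the proxy: the
   correlation between GMTI and the generating signal drops enough that
   GMTI loses every greedy step.
3. *Effect sizes.* Each coefficient is scaled so the partial-effect
   standard deviation on the design (1.8, 1.0 and 0.6 sd-units for AMW,
   MDDD, $\Psi^0_I$) stays well above both the noise (0.2) and the
   spurious-correlation floor of a 20-column pool at $n = 24$.

The intercept centers the endpoint in a realistic logEC50 range. These
are generator design choices, fixed once; the recovery and benchmark
properties in the acceptance suite are then measured, not assumed.

**What the generator does and does not emulate.** It reproduces the
combinatorial cation × anion structure, realistic ion chemistry (every
SMILES parses, charges balance), descriptor collinearity of the kind real
IL libraries produce, and a linear structure–activity relationship with
homoscedastic noise. It does not emulate: real 3D descriptor values
(the packaged reference tables cover those), measurement-error structure
of biological EC50s, activity cliffs or any nonlinearity, or the actual
(unpublished) composition and train/validation split of the motivating
dataset — the packaged 24-IL table is explicitly a synthetic completion
of the eleven ILs named in the published reference tables, and is flagged
as such in its filename. Passing tests therefore demonstrate correctness
of the machinery and qualitative behavior of the representations, not
predictive performance on real ILs.

## The benchmark comparison

`run_benchmark()` crosses representations with descriptor sets
(computed-2D, imported-3D, both), using one stratified-by-anion 75/25
split for all configurations (the motivating study's split is
unpublished, so the split is always recorded in the result), and reports
per configuration the variable-pool accounting, the stepwise model, the
full validation report and both AD classifications. Configurations
requiring imported tables fail loudly rather than substituting computed
values. `compare_report()` ranks by $Q^2_{EXT}$ with RMSE$_{EXT}$ as the
documented tie-break.

On synthetic data whose truth is pair-level 2D, the pair-2D configuration
is the well-specified one: the separate-ion matrix can only mimic the
additive truth by spending two coefficients per true descriptor, which a
three-feature budget does not allow — hence the expectation, verified in
the acceptance suite across seeds, that pair-2D attains the highest
$Q^2_{EXT}$ in the large majority of runs. The pool accounting shows the
second, structural advantage: the pair pool is half the size of the
separate-ion pool for the same descriptor list.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated or
packaged data: descriptor oracles sweep all labeled connected graphs on
up to 5 vertices exhaustively plus seeded random connected graphs at 6–7
vertices; the recovery experiment uses 100 seeds and the benchmark
comparison 50 seeds at the default 24-IL size. These sizes give stable
estimates of the binary success rates (a true rate of 0.95 is estimated
within about ±0.05) while keeping a full run in tens of seconds.
Identical seeds reproduce every result bit for bit; nothing reads global
RNG state outside `withr::with_seed()` scopes.

## Known limitations

* The computed descriptor set is the five-code 2D core; other 2D families
  (ETA indices, walk counts, information indices) are importable but not
  computed. The registry (`descriptor_registry()`) is the extension
  point.
* Pair-level computed descriptors assume the additive/component-wise
  convention described above; if a reference implementation handles
  disconnected structures differently, imported values should be used
  for comparisons against it.
* Mixture (ternary, deep-eutectic) compositions are out of scope; the IL
  table is strictly one cation, one anion, integer stoichiometry.
* The AD and validation layers assume a fitted linear model with an
  intercept; regularized or nonlinear learners are out of scope.
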