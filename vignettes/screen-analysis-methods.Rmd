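---
title: "Methods: growth-curve hit calling, phenotype mapping and fingerprint-based ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth-curve hit calling, phenotype mapping and fingerprint-based ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algscreen)
```

# Scope

`algscreen` analyses high-throughput small-molecule phenotypic screens on
microalgae of the kind run on *Chlamydomonas reinhardtii*: a chronic
(~80-hour) growth assay read as optical-density time courses in 96- or
384-well plates, acute (4-8 h) phototaxis and chlorophyll-fluorescence
assays, and a cheminformatic layer - similarity networks and a naive Bayes
ranking model over circular substructure fingerprints - that turns the hit
lists into a prioritization tool for unscreened libraries. Because raw
screen data of this kind is rarely redistributable, the package ships
synthetic-data generators that emulate the campaign end to end; every
statistical claim the test suite makes is made against those generators,
and this vignette is explicit about what they do and do not emulate.

# Fitness scoring from growth curves

Each well's readout is an OD time series. The activity score is the area
under the growth curve (AUC, OD x hours, trapezoidal rule) relative to the
mean AUC of the same plate's solvent (DMSO) controls:

\[
\text{growth ratio} = \frac{\mathrm{AUC}_{\text{compound}}}
                           {\overline{\mathrm{AUC}}_{\text{controls}}}
\]

Ratios are averaged over replicate plates (sample SD reported when
n >= 2), and a compound is a *fitness inhibitor* when its mean ratio is
**0.65 or less**, i.e. at least 35% growth inhibition. The threshold
comparison is inclusive and configurable (`call_fitness_hit(inclusive =)`),
since screening practice varies between "0.65 or less" and "< 0.65"; the
inclusive reading is the default.

Numerical and design choices:

* **Baseline subtraction** (default): each well's initial OD is subtracted
  before integration, floored at zero. Integrating raw OD makes the ratio
  depend on the inoculum; subtracting the t = 0 reading makes ratios
  scale-robust across plates with slightly different starting densities.
  `baseline = "raw"` restores plain integration. A consequence worth
  knowing: a fully inhibited well (flat curve) scores exactly 0 only under
  baseline subtraction.
* **Integration window**: the full recorded time course by default. Runs
  are expected to extend past control saturation; an explicit
  `window = c(t0, t1)` is available when only part of the run should count.
  No automatic saturation detection is attempted - there is no robust
  universal rule, and the window is an explicit analysis choice.
* **Control QC**: the control AUC must be positive, and plates whose
  control coefficient of variation exceeds 20% (configurable) are flagged
  with a warning rather than silently averaged.
* **Replicate SD** is the sample (n - 1) standard deviation: triplicates
  are a sample of plate-level noise, not a population.

# Acute phenotype classification

The acute assays probe phenotypes within one cell cycle:

* **Phototaxis**: wells are photographed after directional light exposure
  and scored categorically. Untreated cells are negatively phototactic, so
  `no_movement`/`lysed` maps to *motility inhibited* (lysed cells cannot
  respond, and lysis is how highly toxic motility actives present),
  movement opposite the control direction to *sign reversed*, and movement
  with the control to *normal*. Plates are imaged twice from opposite
  sides; the two scores are reconciled by agreement, and disagreement
  yields a missing call - with no stated adjudication rule, refusing to
  guess is the conservative choice.
* **Photosynthesis**: chlorophyll-fluorescence induction at the
  photosystem II emission maximum. Light not used for photochemistry is
  re-emitted, so *higher* fluorescence relative to in-plate controls means
  *reduced* photosynthetic capacity. The hit rule is a control-relative
  ratio with default threshold **1.35**. This value is a package
  convention, not an instrument constant: it mirrors the 35% effect size
  of the fitness threshold on the fluorescence scale, and it is exposed as
  `hit_ratio_threshold` because any given instrument/gain combination may
  warrant a different operating point.
* **Cytotoxicity**: after treatment, cells are pinned onto compound-free
  agar. Growth-inhibited wells that fail to regrow are *cytocidal*, those
  that regrow are *cytostatic*, and uninhibited wells are *reversible*.

The overlap accounting (`summarize_acute()`) counts motility and
photosynthesis actives, their intersection and union, and the union's
overlap with fitness hits; the inclusion-exclusion identity
`unique = motility + photosynthesis - both` holds by construction and is
property-tested. Overlaps are counted on raw acute calls, without first
conditioning on fitness status.

# Circular fingerprints and the similarity network

Fingerprints are sparse sets of hashed circular atom environments of radius
0..2 bonds (diameter 4, the ECFP_4-equivalent). Atom invariants are atomic
number, total degree, attached hydrogens, formal charge and ring
membership; each iteration rehashes an atom's identifier with the sorted
(bond type, neighbor identifier) pairs, and environments at radius >= 1
whose bond set duplicates an already-recorded environment are discarded.
On a fixed 10-molecule fixture the per-molecule feature-set sizes
reproduce an independent reference implementation exactly, including the
duplicate-environment edge cases; raw feature identifiers are
implementation-defined, as for any reimplementation of this family, so
only similarity-level quantities should be compared across toolkits.

Molecule normalisation is delegated to OpenBabel (SMILES to canonical
SMILES to SDF with explicit hydrogens, read back via ChemmineR), so two
spellings of one molecule always fingerprint identically. Aromatic bond
typing is recovered from the canonical SMILES atom tokens; this matches
standard perception on benzenoid and pyridine-type systems, which is the
chemistry the synthetic grammar generates. Stereochemistry is ignored, the
standard convention at this fingerprint radius. Fingerprints are kept as
sparse identifier sets rather than folded bit vectors - Tanimoto on sets
avoids folding-length artifacts.

The network connects compounds whose Tanimoto similarity **strictly
exceeds 0.5** (a pair at exactly 0.5 is not connected). Singletons are
retained but flagged `isolated`. "Clusters" are connected components at
the cutoff - i.e. single linkage - which is the simplest reading of a
thresholded similarity graph. Phenotypes map onto node color (green = both
photosynthesis and motility/phototaxis, red = photosynthesis only,
blue = motility/phototaxis only, white = neither) and shape
(circle = fitness hit, diamond = not); exports are SIF plus a
node-attribute CSV, and GraphML, both loadable by Cytoscape-class tools.

# The naive Bayes ranking model

For feature F with total count \(T_F\), active count \(A_F\) and training
base rate \(P_a\), the model stores the Laplacian-corrected log-weight

\[
w(F) = \log\frac{A_F + 1}{(T_F + 1/P_a)\,P_a}
\]

and a compound's score is the sum of its features' weights. Properties
that make this estimator the right default for sparse substructure data:

* a feature never seen in training contributes exactly
  \(\log 1 = 0\) - unseen chemistry is neutral, not penalized;
* a feature whose active fraction equals the base rate
  (\(A_F = T_F P_a\)) has weight exactly 0 for *every* \(T_F\), since the
  correction cancels algebraically;
* low-count features are shrunk toward zero evidence, so rare
  substructures cannot dominate the ranking.

Scores are relative ranks, not calibrated probabilities, and are exposed
as such. Ties are broken by compound identifier so rankings are
deterministic. A vanilla Bernoulli naive Bayes (`nb_train_bernoulli()`) is
provided as an alternative backend for comparison. Labels are generic
booleans: fitness, motility/phototaxis and photosynthesis models are three
instances of the same training operation.

# Evaluation by repeated holdout

`evaluate_model()` implements the four-fifths/one-fifth scheme: 5
stratified folds, each held out once, the model trained on the rest, the
held-out fifth ranked, and the enrichment factor computed at the top 10%:

\[
\mathrm{EF}@f = \frac{\text{actives in top } \lceil f n \rceil / \lceil f n \rceil}
                     {n_{\text{active}} / n}
\]

Reported as mean and standard error (SD over folds / sqrt(k)) across the
five folds. Choices logged in the output metadata because they are not
universal conventions: folds are **stratified** by label (stabilizes
per-fold EF), and the top-fraction cut uses **ceiling**. EF at fraction 1
is identically 1; a perfect ranking attains the combinatorial maximum
\(\min(m, n_{\text{active}})/(m\, n_{\text{active}}/n)\) with
\(m = \lceil f n\rceil\); both are tested. `expected_hits()` exposes the
screening-budget arithmetic (e.g. the top 10% of a 10,000-compound library
at a 44% hit rate yields 440 hits at random versus 704 at EF 1.6), capping
at the number of compounds screened: an EF whose implied hit count exceeds
the selection size is combinatorially impossible and triggers a warning.

# What the synthetic generators emulate - and what they do not

**Growth plates** (`simulate_plate()`): logistic curves
\(OD(t) = OD_0 + K/(1 + e^{-r(t - t_m)})\) with defaults
\(OD_0 = 0.1\), \(K = 0.9\) OD, \(r = 0.15\,h^{-1}\), \(t_m = 30\) h,
sampled every 0.5 h for 80 h - the shape and cadence of a robotic algal
fitness assay. Inhibition is a planted factor \(\varphi \in [0,1]\)
multiplying the carrying capacity, with rate slowed to
\(r(0.5 + 0.5\varphi)\), so partial inhibitors change curve *shape*, not
just scale, and exercise the windowing logic. Gaussian measurement noise
(default SD 0.005 OD) is floored at zero. Plates carry 8 solvent-control
wells by default - comfortably above the minimum of 4 the layout
validator enforces, and enough for a stable control mean. The logistic
family was chosen as the simplest saturating model; real screens show
sigmoidal curves but fit no model, and the generator makes no claim about
lag-phase structure, aggregation artifacts of non-motile cells, edge
effects, or evaporation - hit-calling robustness to those failure modes
is *not* demonstrated by these tests.

With \(\sigma = 0\) the pipeline is deterministic and the recovered ratio
has a closed form (the logistic integrates to
\(\tfrac{K}{r}\log(1+e^{r(t-t_m)})\)). One numerical point: at the default
0.5 h sampling, the trapezoid-versus-exact-integral discrepancy of the
AUC *ratio* is itself about 1e-6 (pure grid bias, quadratic in the
interval), so the oracle test that demands 1e-6 agreement samples at
0.1 h, where grid bias (~5e-8) is negligible against the tolerance and
the comparison isolates implementation error. All other uses keep the
0.5 h default.

**Libraries** (`generate_library()`): compounds are assembled from a
fragment grammar - a scaffold, up to two linkers, a closing terminal -
in which every fragment ends in an atom with free valence, so plain
concatenation always yields valid SMILES (validity is still checked, and
failed assemblies would be resampled and counted). A planted
"pharmacophore" fragment (default: an aryl sulfonamide or a fluorinated
anilide) is attached to 30% of compounds; activity is Bernoulli(0.8) for
carriers and Bernoulli(0.1) otherwise, giving an expected hit rate of
0.31 - deliberately in the regime of a bioactivity-enriched collection
rather than a diversity library. Under these defaults the realized
5-fold EF@10% is ~2.5 (the population ceiling is
\(p_1/\bar{p} \approx 2.6\)), and with \(p_0 = p_1\) the library is an
exact null where EF calibrates to 1. The grammar's chemistry is benzenoid
and aliphatic; it does not emulate stereochemistry, charge diversity,
tautomerism, or scaffold classes outside the fragment set, so fingerprint
behavior on exotic heterocycles is untested by construction.

**Acute readouts** (`simulate_acute()`): planted mechanisms map directly
to the readouts the classifiers consume (elevated fluorescence for
photosynthesis inhibitors, `no_movement` for motility inhibitors,
`toward_light` for sign reversal, regrowth drawn per a planted cytocidal
fraction). This exercises classification and accounting logic; it does not
model fluorescence-induction kinetics or imaging noise.

# Problem sizes and determinism

The test suite and the acceptance script run the statistical checks at
n = 2,000 compounds per library (the scale at which binomial noise on
EF@10% is ~0.05) and the end-to-end pipeline at a few hundred compounds;
these sizes were chosen so the full campaign remains a minutes-scale
desktop computation while keeping Monte-Carlo error well below the
tolerances being asserted. Every stochastic step draws from a seeded
generator scoped to the call (the caller's RNG state is untouched), and
the pipeline orchestrator (`run_pipeline()`) writes no timestamps, so a
configuration reproduces its run directory byte for byte; reruns skip
stages whose configuration hash is unchanged.

# Known limitations

* Hit calling assumes the in-plate control mean is a valid denominator;
  systematic plate-position effects are only caught indirectly by the
  control-CV flag.
* The photosynthesis hit threshold (1.35) is a convention pending
  instrument calibration data.
* Fingerprint aromaticity perception is SMILES-token based and agrees
  with standard models on the chemistry generated here; unusual
  heterocycles may be typed differently than by other toolkits.
* The naive Bayes model inherits naive Bayes' feature-independence
  assumption; correlated substructures (as produced by any fragment
  grammar) make scores overconfident in rank spacing, though rank order -
  the only quantity used - is robust in practice.
* Enrichment factors measured on synthetic planted-SAR libraries
  characterize the pipeline's correctness, not expected performance on
  real screening collections.
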