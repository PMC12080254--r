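---
title: "PMT/vPvM screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PMT/vPvM screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `pmtscreen`, the
choices that were genuinely open when the package was designed, and what
its validation does — and does not — establish.

## The screening problem

Compounds that are persistent (resist degradation), mobile (barely sorb
to organic carbon, so they travel with water) and toxic — PMT — or very
persistent and very mobile — vPvM — are a water-quality hazard class:
once released they pass natural and engineered barriers and persist in
drinking-water systems. Screening a monitoring-derived compound list for
these properties faces a structural problem: only a minority of detected
compounds have reliable experimental half-lives, sorption coefficients
or toxicity dossiers. The pipeline therefore works in three strict
steps: previously assessed compounds are taken from a reference list;
compounds with experimental evidence are classified by cutoff rules; and
the remainder is predicted by a structure-based classifier, with an
applicability-domain gate deciding whether the prediction is
trustworthy at all. Each compound is decided by exactly the first step
that can resolve it.

This is deliberately a *screening* scheme — cutoff comparisons on
aggregated values — not the weight-of-evidence protocol a regulatory
dossier would apply. Every rule-based verdict carries that caveat in its
audit trail.

## Rule screen

Tiers are computed per criterion and combined:

* **Persistence.** Freshwater half-life above 40 d → P, above 60 d →
  vP; at or below 40 d the criterion definitively fails. Multiple
  reported values are aggregated by the **median** (robust against a
  single outlying study); a worst-case `max` aggregation is available in
  the configuration. The cutoffs are exposed in `pmt_config()` so a
  regulatory revision is a configuration change.
* **Mobility.** Experimental log K~oc~ values within pH 4–9 are
  aggregated by the **minimum** — the most mobile observed speciation —
  which is the conservative choice for water protection. Strictly below
  3.0 → M, strictly below 2.0 → vM; the boundary values themselves do
  not satisfy the criterion (the cutoffs are printed as strict
  inequalities). Values at pH outside 4–9 are dropped at ingestion.
* **Toxicity.** Flag-based only: CMR, aquatic toxicity, STOT RE or
  endocrine disruption. Flags are presence-only evidence — an empty flag
  set with experimental evidence means "not established", never "proven
  non-toxic"; with no evidence at all the tier is unknown.

The combination logic treats a definitive failure (not-P or not-M) as
final regardless of the other tiers; an unknown persistence or mobility
tier routes the compound onward to the ML screen; vP∧vM yields vPvM with
no toxicity requirement (and even under unknown toxicity, since the
class is already established); PMT additionally requires T. A compound
with complete experimental data therefore can never end up as a mere
model candidate. The full 48-combination mapping is pinned by an
enumerated truth table in the test suite.

## Descriptors and fingerprints

The proprietary descriptor engine used in parts of the PMT/vPvM QSAR
literature is not redistributable, so the package computes an **open
descriptor set** (~114 values): constitutional counts (atoms, halogens,
heteroatoms, rings, branching), OpenBabel bulk properties (an
atom-contribution logP estimate, molar refractivity, TPSA, H-bond donor
and acceptor counts), classical topological indices (Wiener, Zagreb,
Randić, diameter), information indices (IC0/SIC0 over the element
composition including hydrogens) and 2D autocorrelations (Broto–Moreau
ATS, Moran MATS, Geary GATS; lags 1–8; atomic mass, electronegativity
and polarizability weights relative to carbon) on the
hydrogen-suppressed graph. A name map
(`descriptor_name_map()`) documents the proxies for descriptor names
common in that literature: the consensus logP maps to `logP_estimate`,
C% to `carbon_fraction` (carbons over all atoms including hydrogens),
GATS8m/MATS1m/SIC0 carry the same definitions, and intrinsic-state
weighted autocorrelations have no open equivalent — the
electronegativity weighting is the nearest analogue. Numeric equality
with the proprietary implementations is explicitly not claimed.

Two numerical choices matter:

* **Missing values are explicit.** An autocorrelation at a lag longer
  than a molecule's topological diameter does not exist; it is `NaN`,
  never a silent 0. The model's imputation (training-set medians) deals
  with it downstream.
* **Minimum support for ratio statistics.** Moran and Geary
  autocorrelations are variance-normalized ratios; evaluated on one or
  two atom pairs they can take arbitrarily extreme values that say
  nothing about chemistry but dominate any Euclidean distance computed
  from them. Lags supported by fewer than three atom pairs are therefore
  reported as missing; the unnormalized Broto–Moreau sum is kept
  whenever at least one pair exists.

MACCS 166-key fingerprints use the public SMARTS dictionary (shipped as
`inst/extdata/maccs_keys.tsv`) with bits indexed by the original key
numbering — key 134 halogens, 103 chlorine, 46 bromine, 42 fluorine, 165
any ring, 162 aromatic. Matching is delegated to OpenBabel's MACCS
pattern engine; three keys that a single SMARTS cannot express are
computed structurally: key 125 (more than one aromatic ring, via counts
of distinct 5/6/7-membered all-aromatic rings, which handles fused
systems), key 166 (more than one fragment, via disconnection in the
canonical SMILES) and key 1 (isotope; always 0 in the public dialect).
Keys involving aromaticity follow OpenBabel's aromaticity model; for
heteroaromatic edge cases other toolkits may disagree on individual
bits. The test suite verifies the full bit matrix against per-key
brute-force substructure counting on a 50-compound fixture.

## Classifier, applicability domain, interpretation

The classifier is a gradient-boosted tree ensemble (xgboost, binary
logistic; depth 4, learning rate 0.1, 200 rounds, row/column subsampling
0.8, single-threaded and seeded for determinism). The positive class
pools PMT, vPvM and PMT&vPvM — the screening question is "is this a
PMT/vPvM-type compound", and the downstream category for model-decided
compounds is a single *candidate* class. Tree ensembles were chosen
because they admit **exact** SHAP attributions and SHAP interaction
values; the additivity identity (base value + attributions = raw
log-odds output) is asserted to 10^-6^ relative tolerance — relative to
the attribution mass, since a raw margin near zero makes a ratio to it
meaningless. Median imputation and z-scoring are fit on the training
data only and serialized with the model; the bundle (model JSON, scaling
and imputation parameters, column manifest, AD threshold, label
definition, seed, scaled training matrix) round-trips through plain text
files to bit-identical predictions.

The **applicability domain** is distance-based: a query's Euclidean
distance to its nearest training compound, computed in the z-scored
descriptor space (raw mixed-unit descriptors would make the metric
meaningless). The threshold is fixed at training time as
mean + 3·SD of the within-training nearest-neighbour distances
(neighbour count and multiplier configurable). Out-of-domain compounds
remain unresolved whatever their score.

One property of this rule deserves honesty: nearest-neighbour distances
over a sparse chemical space are heavy-tailed, so the training set's own
most isolated compound typically lies beyond mean + 3·SD, and for
independent same-distribution queries *any* threshold tight to the
training set will exclude on the order of 1/(n+1) of fresh draws. In
practice ≈99% of freshly generated same-distribution compounds fall in
domain; literal 100% coverage holds for resampled (bootstrap) queries
and is what the acceptance suite asserts, alongside zero self-distance
and monotonicity in the threshold. A screening user should read
"in domain" as "no more novel than the training data", not as a
guarantee.

## Synthetic studies

The simulator exists so that every stage — ingestion, rules, ML, AD,
prevalence, reporting — can be validated against a known ground truth
without any external data. Structures are assembled from **motif
grammars** rather than random SMILES mutation, which guarantees valid
chemistry and controllable fingerprint signatures: perfluorinated chains
(carboxylic/sulfonic/telomer heads, optional ether oxygen),
organophosphate triesters with variably halogenated side chains,
chlorinated and brominated substituted benzenes, small halogenated
aliphatics (the grammar straddling the planted logP boundary),
terpenoid-like naturals and plain alkanes/alcohols/acids. Origin labels
(synthetic / natural / undefined) follow the motif family; counts follow
largest-remainder apportionment, so the default 542-compound roster
splits exactly 287/130/125.

The planted truth is a monotone two-descriptor rule: a compound is a
true positive iff its logP estimate is below 2 **and** it carries at
least one halogen — small polar halogenated compounds, which is
chemically the right neighbourhood (short-chain perfluoro acids,
chloroethanols, haloacetic acids). Family weights were fixed once, from
the measured per-family rates, so that the default composition yields
roughly a third positives; the default seed gives 36%. True positives
are assigned a subclass (PMT : vPvM : both ≈ 7 : 4 : 4). Property
tables are drawn consistently with the truth (P-band half-lives 45–58 d,
vP 70–400 d, mobile and very mobile log K~oc~ bands with safety margins
around the cutoffs), with a configurable label-noise rate that flips a
record's evidence across the boundary; at zero noise the rule screen
recovers the truth exactly, which the tests assert. Concentrations are
log-normal per compound–site observation with the NER location three
orders of magnitude above the EF (ratio of means ≈ 10^3^), site
latitudes over a plateau-like 30–39° range, a mild south-increasing
location trend, and depths uniform on 0–150 cm.

What passing the closed loop shows: the pipeline's plumbing, step
precedence, rule boundaries, model training, AD gating and reporting
are correct, and the planted positive rate is recovered within binomial
error at realistic scale (542 compounds, 400 training compounds, 5-fold
cross-validation — sizes chosen to exercise the full scale of a
monitoring compilation while keeping the suite fast). What it does not
show: performance on real chemistry. Real rosters contain mixtures,
stereochemistry, charged species, measurement error in structures, and
property data whose errors correlate with compound class — none of
which the generator emulates. The synthetic truth rule is also far
simpler than real PMT/vPvM structure–activity relationships; the
classifier's ~0.99 cross-validated balanced accuracy on planted data is
a recovery check, not an expected real-world figure.

## Other design decisions

* **Deduplication key** is the canonical structure; CAS numbers are a
  secondary cross-check only. When duplicates merge, the first record's
  id wins and origin follows the precedence synthetic > natural >
  undefined — when in doubt, a substance that *could* be anthropogenic
  is treated as such; merges are logged.
* **Tie-breaking** in prevalence tables is count descending, then key
  number ascending — deterministic tables under ties.
* **Display rounding** is integer percent for prevalence tables and one
  decimal for the noncyclic fraction; exact values are always retained
  in machine output.
* **Origin contrast strata** are synthetic vs natural ∪ undefined, the
  grouping used when comparing fingerprint and descriptor profiles by
  provenance.
* **Latitude trend** is reported as a Spearman rank correlation between
  site latitude and the site's summed positive-compound concentration,
  sign only, with no significance claim — a descriptive echo of a weak
  spatial gradient.
* **Seeds** are explicit everywhere (generator spec, training,
  cross-validation, acceptance script); reports embed the configuration
  snapshot and seed, and re-running on identical inputs reproduces the
  JSON report byte for byte.

## Limitations

Beyond the synthetic-data caveats above: the rule screen aggregates
evidence crudely (median/minimum) and does not weight study quality;
toxicity is presence-only flags, so unflagged compounds with poor
dossiers dilute the PMT class toward vPvM; the open descriptor set is a
proxy for the proprietary one, so trained models are not transferable
between the two; and OpenBabel's aromaticity perception differs from
other toolkits on some heteroaromatics, which can flip individual MACCS
bits for such compounds.
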