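---
title: "Modelling co-sensitization to house dust mite allergen components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling co-sensitization to house dust mite allergen components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitebn)
```

## The problem

Component-resolved diagnostics measures a patient's specific IgE (sIgE) not
against a whole allergen extract but against individual allergenic proteins.
For house dust mites (HDM), multiplex panels report sIgE (kU/L) to eleven
*Dermatophagoides* components: Der f 1, Der f 2, Der p 1, Der p 2, Der p 5,
Der p 7, Der p 10, Der p 11, Der p 20, Der p 21 and Der p 23. Sensitizations
to these molecules are strongly dependent — a patient positive to Der p 1 is
far more likely to also carry Der f 1 — and the joint pattern, not any single
marker, is what matters for immunotherapy planning.

`mitebn` provides the full analysis chain for such panels:

1. **Binarization** of concentrations into presence/absence of sensitization.
2. **Descriptive profiling**: per-component counts and shares, child/adult
   splits, age-stratified frequency profiles.
3. **A discrete Bayesian network engine** to model co-sensitization:
   structure learning, conditional-probability-table (CPT) estimation and
   exact conditional queries.
4. **A synthetic cohort generator**, so that every stage can be exercised and
   validated end to end without access to patient-level records, which are
   typically restricted.

## Binarization and descriptive statistics

An entry of the sensitization matrix is 1 exactly when sIgE $\ge$ 0.31 kU/L,
the multiplex assay's reference threshold; the boundary is **inclusive**
because only values *below* the threshold are disregarded as negative. The
threshold is a parameter of `binarize()` for sensitivity analyses, and
binarization is monotone in it: raising the threshold never creates a
positive.

Descriptive outputs follow the conventions of published cohort tables:

* **Shares** are percentages rounded *half-away-from-zero* to two decimals
  (`round_half_out()`), the convention under which every reported share is an
  exact function of its integer numerator and denominator.
* The **denominator** of per-component shares is the whole sensitized sample
  (patients with at least one positive component), *also for the child and
  adult strata*, so that the child and adult shares of a component add up to
  its overall share. A per-stratum denominator is available via
  `cohort_summary(..., stratum_denominator = TRUE)`.
* **Children vs adults**: children are `age < 18`, adults `age >= 18`.
* **Mean ± SD of sIgE** is computed among the positives of the stratum only
  (values at or above the threshold); an SD over fewer than two observations
  is reported as `NA`, never as 0.
* **Age bands** are half-open intervals $[l, u)$ over the cutpoints
  1, 3, 6, 12, 18, 25, 36, 44, 60 years (infant, toddler, preschool, primary
  school, puberty, then adult strata bounded by the start and end of youth,
  an intermediate point at 36, and the end of middle age). Half-openness
  guarantees a partition: a boundary age belongs to the band it opens.
  Because published age profiles do not always state their denominator,
  `group_frequency_table()` emits frequencies both as a percentage of the
  band and of the whole sample; empty bands yield `NA`, not 0.

## The Bayesian network model

A Bayesian network over the 11 binary sensitization indicators
$X_1,\dots,X_{11}$ is a directed acyclic graph (DAG) $G$ plus one CPT per
node, factorizing the joint distribution as

$$P(x_1,\dots,x_{11}) \;=\; \prod_{v} P\!\left(x_v \mid \mathrm{pa}_G(v)\right).$$

All conditional-independence structure of such a model is carried by three
three-node patterns, which `classify_triples()` enumerates: the chain
$X \to Y \to Z$, the fork $X \leftarrow Y \to Z$ (common cause) and the
collider $X \to Y \leftarrow Z$ (common effect). We use the standard
terminology — fork = common cause, collider = common effect — and
`d_separated()` implements the standard graphical criterion (moralized
ancestral graph), which the test suite verifies numerically against
brute-force joint tables.

### Structure learning

Two learners are provided:

* `learn_structure_hc()` — greedy hill climbing over single-edge moves
  (add, delete, reverse) maximizing the **BIC score**
  $\log \hat L - \tfrac{\log n}{2}\,k$ with $k = \sum_v 2^{|\mathrm{pa}(v)|}$
  free parameters. The score is family-decomposable, so each move rescores
  only the families it touches. Search starts from the empty graph;
  `max_parents` defaults to 4, matching the largest conditioning sets that
  are practically interpretable (and estimable) for an 11-variable binary
  panel; `restarts` defaults to 0 so the default run is fully deterministic.
  Ties are broken by enumerating moves in a fixed canonical order and
  accepting only strict improvements.
* `learn_structure_chowliu()` — the Chow–Liu tree: a maximum-weight spanning
  tree on pairwise mutual information, oriented away from a root. It is a
  deterministic, restricted alternative that always honours a root node.

**Root-node semantics.** Analyses of this panel conventionally anchor the
network at Der p 23, the component whose prevalence is stable across all age
groups. "Root" can mean two things, and both are supported: a structural
constraint (no incoming edges — the default, `root = "Der p 23"`), or merely
an orientation root for the Chow–Liu tree. Passing `root = NULL` to
`learn_structure_hc()` removes the constraint entirely; that matters because
conditional queries *about* the root given other components are perfectly
legitimate in either case — a query does not require a particular edge
orientation.

### CPT estimation and inference

`fit_cpds()` estimates $P(X_v = 1 \mid \mathrm{cfg})$ as
$(n_1 + \alpha)/(n + 2\alpha)$ per parent configuration. The default
$\alpha = 1$ (symmetric Laplace prior) keeps every entry defined even for
configurations never observed — with 11 binary variables and up to four
parents, rare configurations are a certainty, not an edge case. $\alpha = 0$
gives plain maximum likelihood, and an unobserved configuration is then an
explicit `NA`, never a silent `0/0`.

`query()` computes $P(\text{target} \mid \text{evidence})$ exactly by
variable elimination: evidence is absorbed by factor reduction, and the
remaining non-query variables are summed out in min-degree order with
canonical-name tie-breaking, so results are deterministic.
`brute_force_query()` enumerates the full joint (up to 16 nodes) and serves
as the independent oracle; the central correctness property of the engine is
`query == brute_force_query` to machine precision, which the suite fuzzes
over hundreds of random networks. Evidence of probability zero yields a
result flagged `undefined` rather than a misleading 0. Probabilities are
reported in pipeline outputs as percentages with two decimals; full
precision is kept internally.

## The synthetic cohort generator

`generate_cohort()` produces panel tables with the statistical structure the
analysis assumes. Its defaults are the study conditions it emulates:

* ~25.81% of patients sensitized to at least one component;
* 68.05% / 31.95% child/adult mix, children averaging ~8 years (the 6–12
  band largest) and adults ~32 years (18–36 dominant);
* dependent binary co-sensitization drawn from the `paper11` ground-truth
  network (below), re-drawing the rare all-negative profile so that every
  patient in the sensitized arm truly has $\ge 1$ positive component;
* log-normal sIgE magnitudes for positives, shifted above the threshold,
  with per-component locations placed so child means match the published
  per-component levels and adult medians are half the child ones
  (`adult_sige_factor = 0.5`); negatives draw a sub-threshold uniform value
  (or exactly 0 with `hard_zeros = TRUE`, for workflows that treat negatives
  as structural zeros);
* log-normal total IgE around 371 kU/L (children) / 223 kU/L (adults).

By construction, `binarize()` at the configured threshold recovers the
sampled binary profiles exactly, and the per-component frequencies among the
sensitized converge to the truth network's conditional marginals.

**What it does not emulate.** Age and sensitization status are drawn
independently (in real cohorts children are over-represented among the
sensitized *and* within-profile composition drifts with age); there is no
regional heterogeneity, no assay noise or upper quantification limit, and
tIgE is independent of the sIgE profile. Passing recovery tests on this
generator therefore demonstrates the *correctness of the machinery* —
estimators converge to the truth that generated the data — not that the
truth network is the true model of any real population.

### The `paper11` truth network

The fixture's DAG follows the reported co-sensitization neighbourhoods for
this panel: group 1/2 components (Der f 1, Der f 2, Der p 2) are driven by
Der p 1, Der p 23 and each other; Der p 21 is an autonomous driver of the
group-5-related cluster (Der p 5, Der p 7, Der p 1, Der f 2); the minor
components Der p 10, Der p 11 and Der p 20 hang off the major ones. Where
those descriptions leave an orientation open, one convention fixes it:
**Der p 23 is kept parentless**, with its connections to Der p 1, Der p 5
and Der p 7 oriented outward. A consequence worth noting is that Der p 1
acquires Der p 23 as a fourth parent beyond the three drivers listed for it;
the alternative (orienting those edges into Der p 23) is equally consistent
with the described neighbourhoods and can be built with `bn_dag()` +
`bn_custom()` if wanted.

CPTs use a logistic parameterization
$P(X_v = 1 \mid \mathrm{pa}) = \mathrm{logit}^{-1}(b_v + 1.5\,m)$, where $m$
is the number of positive parents. The shared slope 1.5 encodes a uniformly
positive, moderate-to-strong association — one positive parent roughly
quadruples the odds. The intercepts were calibrated once, by exact
enumeration of the $2^{11}$ joint, so that each component's prevalence
*among profiles with at least one positive* matches its published share of
the sensitized sample (that is the denominator such tables use); the
calibrated values are frozen in the package, making the fixture fully
deterministic. The all-negative profile has probability 0.163 under the
fixture, which is why the generator's sensitized arm uses rejection.

```{r marginals}
net <- make_truth_net("paper11")
dag_edges(net$dag)[1:5, ]
```

## Numerical choices and problem sizes

* Scores and mutual information use natural logarithms with the
  $0\log 0 = 0$ convention.
* Shares/ratios round half-away-from-zero to 2 decimals; concentrations
  serialize with at most 4 decimals, and the generator rounds to the same
  precision so written panels round-trip losslessly.
* All randomness flows through explicit `seed` arguments; the caller's RNG
  state is always restored.
* Validation checks run at the sizes where their guarantees are sharp:
  structure recovery uses 20,000 samples (10 seeds for the 5-node fixture),
  parameter and query recovery 50,000 samples, inference equivalence
  hundreds of fuzzed 11-node networks, and the synthetic cohort is exercised
  at the study's size of ~20,000 patients.

## Known limitations

* **Rare parent configurations are not estimable.** In `paper11`, minor
  components with several parents have configurations whose probability is
  of order $10^{-4}$ (a handful of rows even at $n = 50{,}000$). No
  estimator pins such CPT entries to within ±0.02; smoothed estimates shrink
  toward 0.5. This is a property of the data-generating process, not a bug:
  well-populated configurations recover tightly, and query answers — which
  average over configurations by their probability — recover to well under
  ±0.02. Interpret individual CPT entries for rare configurations with
  corresponding caution.
* Structure learning returns one member of a likelihood-equivalence class;
  orientations within the class (e.g. a chain's direction) are not
  identifiable from observational data, which is why recovery is asserted at
  skeleton level.
* The network is associational. Queries quantify co-occurrence in profiles,
  not causal or temporal ordering of sensitization acquisition.
* No continuous (Gaussian) nodes, latent variables or interventional
  (do-calculus) semantics.
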