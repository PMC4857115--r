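---
title: "Methods: ligand-based anti-cancer screening of plant compound libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based anti-cancer screening of plant compound libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

herbscreen is an in-silico screen over plant-derived compound libraries of
the kind curated in traditional-medicine databases: thousands of pure
compounds, each annotated to one or more source plants. The pipeline asks
three questions. Which compounds look like anti-cancer actives? Which
plants hold more of those actives than chance would give? And how do the
predicted actives relate, structurally, to anti-cancer drugs already in
development?

This vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic benchmark the package ships, and the numerical
and design choices a maintainer should know about.

## Fingerprints and similarity

All structure comparison uses the 166 public MACCS substructure keys,
computed by Open Babel (via ChemmineOB) and trimmed from its padded 256-bit
vector to the 166 meaningful positions. Similarity is the Tanimoto
coefficient over bit sets, Tc = |A ∩ B| / |A ∪ B|. Two conventions are
fixed package-wide:

* Tc between two all-zero fingerprints is defined as 0 — an absence of
  evidence is never similarity, and this avoids 0/0.
* The "structurally similar" threshold is inclusive, Tc ≥ 0.70. All
  reported drug-similarity counts, and all network edges, use it.

The fingerprint is deliberately not configurable: the 0.70 threshold is
only meaningful against the key set it was calibrated for.

## Activity calling

The activity model is a ligand-based nearest-neighbour scorer over a
reference set of known actives and a decoy set:

* **Bit weights.** Each key b gets
  w(b) = ln((f_act(b) + ε) / (f_dec(b) + ε)), with ε = 0.01 and clipping to
  [−5, 5]. Keys enriched in actives get positive weight, decoy-typical keys
  negative weight. The clip bounds the influence of keys seen in only one
  set; ε makes the ratio finite (an active-only key gets ln(101) ≈ 4.6).
* **Hybrid score.** For query q, the weighted Tanimoto
  wTc(q, a) = Σ w⁺(b)[b ∈ q∧a] / Σ w⁺(b)[b ∈ q∨a] with w⁺ = exp(w) is
  computed against every reference active; the score is
  0.5·max + 0.5·mean(top-5). The max term rewards a single close analogue,
  the top-5 mean requires neighbourhood support; fixed constants keep the
  score reproducible.
* **Empirical P.** Decoys are scored under the fitted model and the query's
  tail probability is the add-one estimator
  p = (1 + #{null ≥ s}) / (1 + n_null). Ties count toward the tail
  (conservative), p is never exactly zero, and the decoy floor of 200
  bounds the smallest reportable p below 0.005. A compound is called active
  when p < 0.05.

These are the published interface and decision rule of confidence-scored
ligand screens; the scorer itself is this package's own, documented
surrogate, and every downstream stage depends only on the per-compound
(score, p, active) contract, so the scorer is swappable.

## Plant enrichment (ACEA)

For each plant we form the 2×2 margin (N, n, m, k): N distinct compounds in
the library, n predicted actives among them, m compounds annotated to the
plant, k predicted actives among those. The plant's P-value is the
hypergeometric upper tail P(X ≥ k); enrichment asks whether the plant's
active fraction beats the library's. Details that matter:

* The tail is summed in log space from `dhyper(log = TRUE)` point masses,
  so P-values at the 1e-40 scale (routine for strongly enriched plants in
  large libraries) keep full relative accuracy. `stats::phyper` and an
  exact binomial-coefficient enumeration serve as independent oracles in
  the tests.
* Compounds annotated to several plants count in each plant's (m, k) but
  once in (N, n): the margins are defined at database level, plant
  membership at plant level.
* Bonferroni: p_adj = min(1, p·Ng) with Ng the number of plants tested.
  The product is capped at 1 — an uncapped "probability" above 1 is
  meaningless. Significance is strict, p_adj < 0.05. One consequence of cap
  plus strict rule: even at alpha = 1, plants whose capped p_adj equals 1
  are not admitted; the tests assert exactly this contract.
* Every annotated plant is tested by default, including those with fewer
  than 5 compounds. Such plants rarely reach significance — that is a power
  limitation, not a filter, so the default keeps them; `min_m` exists for
  users who want the pre-filtered analysis (it also shrinks the Bonferroni
  family).
* Plants with m = 0 get p = 1 and are flagged in the log rather than
  raised: an annotation referencing no parseable compound is a data
  problem, not a reason to stop a 2000-plant screen.

## Drug-similarity profile, properties, fragments

Predicted actives are compared to three stage-labelled drug panels
(preclinical, clinical, approved). A compound counts as drug-similar for a
stage when its best Tc against that panel is ≥ 0.70; stages are reported
independently, so a drug listed in two stages counts in both. Reported
percentages are integers rounded half away from zero — base R's
round-half-even does not reproduce conventional report percentages
(74.88% must print as 75%).

Property profiles report ALogP, molecular weight, H-bond donors and
acceptors, rotatable bonds, rings and aromatic rings:

* ALogP is Open Babel's atom-contribution logP (Ghose–Crippen family).
  Different toolkits disagree on ALogP by a few tenths; only the < 5
  rule-of-five cutoff and distribution shapes are interpreted.
* HBA is the N + O count (Open Babel's HBA2), the convention under which
  the rule of five was formulated; the stricter acceptor typing (HBA1)
  would give furan-type oxygens no acceptor count.
* Ring count is the cyclomatic number (bonds − atoms + fragments) computed
  from a V2000 conversion; it equals the SSSR ring count. Aromatic rings
  are counted as unique aromatic 5-, 6- and 7-membered cycles found by
  SMARTS; for fused systems of simple rings this coincides with the SSSR
  aromatic count. Exotic bridged aromatics could be under-counted; none
  occur in the supported chemistry.
* Rotatable bonds use the strict definition: acyclic single bonds between
  two non-terminal heavy atoms, amide C–N excluded.
* All four Lipinski criteria are strict inequalities (HBD < 5, HBA < 10,
  MW < 500 Da, ALogP < 5); a molecule exactly on a boundary fails.

Fragment profiling is dictionary-based: 16 named ring/functional-group
SMARTS (benzene, pyridine, pyrimidine, imidazole, pyrazole, pyrrole,
pyrrolidine, piperazine, morpholine, trifluoroethane, cyclohexane,
cyclohexene, cyclopentane, tetrahydropyran, tetrahydrofuran, methyl
acetate), user-extensible via TSV. A fragment's frequency is the fraction
of molecules containing ≥ 1 embedding — molecules, not occurrences, so
biphenyl counts once for benzene. De novo frequent-subgraph mining is out
of scope; the dictionary makes the frequencies exactly reproducible.

## Plant–drug network

Significant plants connect to drugs: edge (plant, drug) exists when some
compound of the plant has Tc ≥ 0.70 to the drug. By default *all* annotated
compounds of a significant plant may contribute evidence, because the
plant, not the compound, is the node of interest once it is deemed
enriched; `actives_only = TRUE` supports the narrower reading where only
predicted actives form edges. A drug appearing in several stages is
labelled with its most advanced stage. Components are standard undirected
connected components, ordered by size then smallest member; the graph
carries node type, stage, family and degree attributes and exports to SIF
and GraphML for Cytoscape.

## The synthetic benchmark

The generator emulates the *shape* of a real screen so that every stage is
testable offline: 2000 pool compounds at a 25% true-active fraction, 100
plants, drug panels of 127/425/219 (preclinical/clinical/approved), an
approved-panel coverage target of 75% of true actives, and 10 designated
enriched plants (30 compounds each, active fraction 0.9) among ordinary
plants of 8–30 compounds. These sizes are the package's standard benchmark
scale: large enough for stable rates, small enough that the full pipeline
runs in well under a minute of fingerprinting.

Molecules come from a scaffold-decoration grammar — a core SMILES with two
substitution slots filled from a 16-substituent list — which guarantees
validity and makes similarity controllable. MACCS keys at 166 bits cannot
hold eight mutually dissimilar saturated polycyclic cores apart (measured
cross-core Tc reached 0.97), so similarity structure is organised in
scaffold *families*, verified empirically at design time:

* a **covered** family (six terpenoid-like saturated cores, 70% of
  actives) that the drug panels also decorate — these actives are
  drug-similar by construction;
* an **uncovered** family (thioether-terpenoid and glycoside cores, 25% of
  actives) with no corresponding drugs and verified cross-family Tc < 0.7 —
  this sets the 75% coverage target;
* an **isolate** family (an N-methyl alkaloid core, 5% of actives) used
  only by three designated plants and two approved drugs, with maximum
  cross-family Tc 0.63 — the planned isolated network component. The
  isolate plants' inactive filler is drawn from scaffolds verified
  dissimilar to the drug cores, since a single filler compound at Tc ≥ 0.7
  to a mainstream drug would bridge the components;
* an **inactive** family of eight flat aromatic cores for decoys and
  background compounds.

Plants sample compounds from the fixed pool: ordinary plants uniformly (so
a plant's active count is exactly hypergeometric under the null — the
Bonferroni/FWER tests rely on this), enriched plants per-slot from the
active pool at their configured fraction. Because the active fraction is a
pool property, the realised library fraction equals the configured
background exactly. Setting the enriched fraction equal to the background
is the null configuration: no plant is marked enriched and all sample
uniformly.

What the generator does **not** emulate: natural-product chemical space
breadth, property-matched (DUD-E-style) decoys, noisy annotations, and
inter-plant phylogenetic correlation of chemistry. Passing tests therefore
demonstrate the pipeline's statistical and structural correctness under
known truth, not predictive performance on real libraries.

One measured consequence of the scaffold-family design is worth recording.
The label-permutation null for the activity model (refit after shuffling
active/decoy labels) destroys the learned separation completely — a
label-free max-Tc scorer gives the same AUC as the permuted models — but
the permuted AUC settles near 0.36 rather than 0.5. With 60 actives and
400 decoys, a permuted "active" set is ~87% decoy chemistry, and a
nearest-neighbour score then tracks pool composition, which anti-correlates
with the true labels because actives and inactives live on disjoint
scaffold families. A chance-level 0.5 would require chemically
exchangeable classes or balanced reference sets; the corresponding
acceptance check documents this as a known deviation rather than adjusting
the benchmark to mask it.

## Determinism and degenerate inputs

Every stochastic step runs under an explicit seed (`withr::with_seed`), and
all outputs are sorted before writing: edge lists lexicographically,
enrichment by (p_adj, plant name), fragment tables by drug-set frequency.
Identical configurations reproduce every output byte for byte. Unparseable
SMILES never abort a run: batches are validated by recursive bisection
(Open Babel fails whole batches) and drops are counted in logs. Empty
networks export an empty SIF plus valid GraphML with a warning. Result
tables serialise doubles at 15 significant digits so read-back agrees to at
least 12.

## Known limitations

* Open Babel's MACCS implementation sets somewhat fewer keys than other
  toolkits; absolute Tc values are toolkit-specific, and the 0.70 threshold
  should not be compared across fingerprint backends.
* ALogP is an approximation of other vendors' ALogP within roughly ±0.5.
* The activity scorer is a documented surrogate with the published
  interface (score, empirical P, P < 0.05 rule); it is not a reimplementation
  of any proprietary screen, and its published benchmark figures are not
  claimed.
* Real screens of licensed databases (tens of thousands of compounds,
  thousands of plants) are not reproduced at this desk scale; the package
  reproduces the method, the arithmetic identities of its reports, and the
  statistical guarantees.
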