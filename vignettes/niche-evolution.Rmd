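---
title: "Models and methods behind oakniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oakniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakniche)
```

oakniche implements a connected set of analyses for studying how climatic
and biotic niches evolve along a dated phylogeny, in the style of studies
of the Eurasian cork oaks: climate-niche profiling from occurrences,
five-category niche coding, ancestral-state reconstruction with and
without fossil tips, four-taxon introgression tests, and a split-network
morphospace. This vignette documents the models, the parameters that
matter, the synthetic-data design, and the numerical choices, so that a
user can judge what the package's validation does and does not show.

## Dated trees

All analyses run on rooted trees with branch lengths in millions of years
(Ma), stored as ape `phylo` objects. Ages are measured backwards from the
present: the root age is the maximum root-to-tip path length, extant tips
of an ultrametric tree sit at age 0, and fossil tips at positive ages.
`validate_dated_tree()` enforces the invariants everything downstream
relies on — one root, non-negative branch lengths, unique tip labels, and
(optionally) contemporaneous extant tips with a 10⁻⁶ Ma tolerance.
Polytomies are accepted throughout; only fossil grafting requires its
anchor clade to be monophyletic, because the anchor identifies a single
branch to break.

## Köppen profiles and the five-category coding

A species' **Köppen profile** is the proportion of its occupied grid
cells falling in each Köppen–Geiger class, on a regular lon/lat grid at a
stated resolution (5 arc-minutes in the emulated study design). Two
choices deserve emphasis:

* *Grid weighting means unique cells.* Each occupied cell counts once no
  matter how many records fall in it, so the profile is invariant to
  duplicated or permuted records. This is the only weighting the source
  data's "unique grid cells" notion makes explicit.
* *Half-open cells.* Cells are `[west, east) × [south, north)`; a record
  exactly on the global east/north edge joins the last cell. Snapping is
  therefore deterministic, with no boundary ambiguity.

Profiles plus biome memberships are binned into five ordinal categories
(0 Moist-Subtropical … 4 Full-Mediterranean) by an explicit rule cascade
(`classify_niche()`), evaluated in order with Full-Mediterranean as the
residual. The category definitions in the source material are verbal; the
cascade operationalizes them with two tunable thresholds in
`niche_config()`:

* `summer_dry` (default 0.10): minimum summed fraction of summer-dry
  classes (`Cs*`, `Ds*`) that marks a drought-affected niche;
* `cold_dry` (default 0.10): minimum summed fraction of winter-cold
  summer-dry classes (`Ds*`, `BSk`) that marks continental
  summer-drought (rule 3's second route).

Both default to 0.10 to match the inclusive "≥ 10 %" representativeness
cut-off used for reporting representative climate types. Rule 3 is read
as `(summer-dry ∧ temperate-biome-present ∧ dominant ≠ Csa) ∨
(cold-dry ≥ threshold)`.

Two consequences of this operationalization are worth knowing. First, the
bundled emulation gives *Q. crenata* a Cfb-dominant profile with a
summer-dry fraction just below 0.10: its published tabular summary bolds
Csa, but the accompanying text describes a mesic species with rare
droughts, and only the mesic reading makes it Nemoral under the cascade.
Second, the three East Asian species all land in category 0 given their
shared biome pair (moist-subtropical + temperate broadleaf); the verbal
definitions would spread them over categories 0–2, but they do not state
a quantitative criterion that separates them, so the cascade keeps the
simple rule and the package only asserts the four species whose
categories the source states explicitly (chenii 0, crenata 2,
castaneifolia 3, suber 4).

## Fossil grafting

A fossil is specified by an anchor clade, an age range `[oldest,
youngest]`, and a scored state. Grafting inserts a new internal node (the
*shadow MRCA*, labelled `shadow_<fossil>`) on the anchor branch at age
`oldest` and attaches the fossil tip with edge length `oldest −
youngest`, so the tip sits at age `youngest`. Pre-existing node ages,
edge lengths and tips are untouched, and pruning the fossil tips and
suppressing the degree-2 shadow nodes recovers the input tree exactly —
a property the tests assert on hundreds of random cases.

Numerical/design choices:

* An oldest age outside the open age interval of the anchor branch is a
  hard error, never clamped or re-anchored: the branch choice and the
  fossil age must be consistent, and silent repair would hide bad input.
* Several fossils on one branch nest oldest-first as successive sisters
  (a pectinate backbone). The source procedure does not state a policy;
  pectinate nesting is the only one supported, and it makes `graft_all()`
  independent of the input list order. Ties on (anchor, oldest age) break
  by label order.
* Fossils flagged non-assignable (the "unconnected stars" of the study's
  figures) are carried through reports but never grafted.

## The Mk1 model and ancestral states

The k-state equal-rates Markov (Mk1) model has one rate `q` (expected
changes per Ma per off-diagonal entry) and the closed-form transition
matrix `P_ii = 1/k + ((k−1)/k)·e^(−kqt)`, `P_ij = (1 − e^(−kqt))/k`. The
likelihood is computed by Felsenstein pruning with per-node rescaling
(each node's partials are divided by their column maximum and the log
factors accumulated), which keeps 70+-tip trees with small rates well
away from underflow. Missing states contribute all-ones partials;
polytomies are handled exactly because a node's partial is the product
over an arbitrary number of children.

* **Root prior**: uniform `1/k`, the Mk stationary distribution and the
  common Mk1 default; configurable.
* **Rate estimation**: Brent search (`optimize`) over `log q` in
  `[1e−8, 100]` to relative tolerance 1e−8; a boundary hit is flagged,
  and a data set of entirely invariant characters pins `q` at the lower
  bound with a warning. One shared `q` across the characters of a matrix
  by default; `per_character = TRUE` fits one rate each.
* **Marginal reconstruction**: the up–down (outside) pass under the root
  prior gives each internal node's posterior state probabilities; the
  implementation tracks the scaling factors on both passes so the
  likelihood can be re-derived from any node's up×down decomposition —
  an internal consistency check the tests exercise against brute-force
  enumeration over all interior state assignments. The term
  "proportional likelihoods" is read as these marginal posteriors;
  `method = "conditional"` provides the alternative reading
  (renormalized subtree likelihoods) since the two coincide only at the
  root.

`asr_two_trees()` runs the estimator independently on the extant-only and
the fossil-grafted tree, then keys the node sets to each other: the
counterpart of an extant-tree MRCA is the MRCA of the same extant tip set
in the grafted tree, and shadow MRCAs appear only on the grafted side.
`suber_scenario()` packages a small configuration in which this pairing
exhibits the qualitative fossil effect — most extant tips
drought-adapted, summer-wet fossils on one stem, and the crown/stem
argmax flipping once the fossils are included.

## Patterson's D

Sites are polarized by the outgroup allele; ABBA is (P1 ancestral, P2
derived, P3 derived, O ancestral) and BABA its mirror, with all other
patterns ignored and sites missing any taxon dropped (and counted). `D =
(nABBA − nBABA)/(nABBA + nBABA)`. Significance uses a **locus**
bootstrap: loci resampled with replacement, D recomputed per replicate,
and `Z = |D|/sd(D_boot)`, with the conventional threshold `|Z| ≥ 3`
(configurable). A degenerate bootstrap (all replicates identical) is
reported as infinite Z with a flag rather than silently passing. The
bootstrap unit and the cutoff are choices — the cited implementation's
common practice — and both are exposed.

One battery-design lesson is encoded in the demo: the polarizing outgroup
must not itself be an admixture candidate in the same battery. The demo
tests therefore all use the distant `Q_robur` as O, so the taxon tested
for admixture with `Q_suber` (namely `Q_ilex`) never doubles as the
outgroup of another test.

## Hamming morphospace and neighbour-net

Hamming distances on the categorical trait matrix are normalized by the
number of characters scored in *both* taxa of a pair (a ternary mismatch
counts 1, like a binary one); a pair sharing no scored character is an
error rather than a guessed distance. Normalizing by shared-scored
characters (not by all characters) is the choice taken where the source
is silent; with complete matrices the two coincide.

`neighbor_net()` follows the canonical two-level agglomeration: cluster
pairs are selected by the neighbour-joining criterion on mean
between-cluster distances; the joining endpoints within the selected
clusters are chosen by the same criterion with those clusters' endpoints
treated as singletons; chains longer than two nodes are reduced with the
standard 2/3–1/3 distance updates. The resulting circular ordering
supports all `n(n−1)/2` circular splits, whose weights are fitted by
non-negative least squares (active-set, via `pracma::lsqnonneg`); splits
with weight ≤ 1e−8 (configurable) are dropped. Taxa are processed in
lexicographic label order so ties resolve reproducibly and the ordering
is invariant (up to rotation/reflection) under relabelling. Output is the
split system itself — a NEXUS Splits block any split-network viewer can
draw; planar layout is out of scope.

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its seed, and generated objects
always satisfy their consuming module's validators (both properties are
tested). The defaults encode the study-shaped conditions: 5 arc-minute
grids, a 15-species ingroup plus outgroups, a five-state niche character,
an 11-binary + 1-ternary trait matrix, ~dozens of fossils with uniform
age draws, and RAD-scale locus batteries of 200 loci × 250 sites.

* `sim_dated_tree()` runs a forward birth–death process from two root
  lineages, stopping at the first event drawn after the lineage count
  reaches `n_tips`; for pure birth the expected root age is
  `Σ_{i=2..n} 1/(iλ)`, which the tests verify against independent
  waiting-time draws. Extinct subtrees are pruned.
* `sim_koppen_world()` builds one vertical strip per climate class and
  gives each species a rectangular footprint per class whose area is
  proportional to its target weight; records fall uniformly in the
  footprints. With many records the unique-cell profile converges to the
  target weights by construction, making the generator its own oracle.
  It does not emulate spatial autocorrelation of real climate grids,
  coastline-shaped ranges, or GBIF-style georeferencing error.
* `sim_quartet_sites()` draws per-locus multinomial counts over
  {ABBA, BABA, uninformative}; the admixture mode sets
  `p_ABBA = p0 + γδ` with `p0 = 0.02` and `δ = 2/15`, so γ = 0.3 gives a
  threefold ABBA excess and E[D] = 0.5. It does not model linked sites
  within loci or coalescent gene-tree heterogeneity, so the locus
  bootstrap's calibration statement is about multinomially independent
  sites.
* `sim_rad_loci()` (multi-taxon) plants joint derived alleles in an
  admixed pair while lowering that pair's baseline so each taxon's
  marginal derived rate is unchanged; only quartets using the pair
  jointly as (P2, P3) then deviate from the null, which is what makes
  "exactly the planted test fires" a meaningful check.
* The demo chronogram (`cerris_demo_tree()`) is fixed, with the published
  point ages where available and plausible interpolations elsewhere; the
  demo fossil states lean towards the summer-wet temperate categories,
  as in the pre-Pliocene record the preset emulates.

Because all of this is synthetic, green tests demonstrate internal
correctness (likelihoods, inversions, calibrations, determinism), not
that the biological conclusions of any particular study re-emerge from
raw data; assembling real RAD loci, cleaning real occurrence data and
Bayesian dating are explicitly out of scope (the dated tree is an input).

## Validation design and problem sizes

The test suite checks each operation against an oracle that is
independent of the implementation path: brute-force enumeration over
interior states for the Mk likelihood and marginals (trees ≤ 6 tips,
k ≤ 5, 200 random cases), the numerical matrix exponential for the
closed-form transition matrix, per-site classification for pattern
counts, path distances on the generating tree and generator-as-oracle
circular metrics for neighbour-net (100 cases each), and exact graft ⇄
degraft inversion with order-invariance on 500 random tree/fossil-set
cases. Statistical behaviour is checked at moderate scale: 20 × 1000
characters for rate recovery (median within 10 % of q = 0.1), 1000 null
datasets for the D-test's type-I error at |Z| > 1.96 (0.05 ± 0.02), and
200 replicates for power at the planted γ (≥ 0.95 at |Z| > 3). These
sizes were chosen so the whole suite completes in a few minutes on one
CPU while keeping the Monte-Carlo bands meaningful.

## Known limitations

* The Mk machinery is symmetric equal-rates only: no ordered or
  asymmetric models, no rate variation beyond per-character `q`, no
  stochastic mapping or Bayesian reconstruction.
* The niche cascade is a deterministic operationalization of verbal
  category definitions; near-threshold profiles (summer-dry fraction
  ≈ 0.10) can legitimately be argued into the neighbouring category, and
  the East Asian ecotone species are not separated (see above).
* D-statistics use one sampled allele per taxon by default; the
  frequency mode exists but no VCF ingestion of real variant data.
* `neighbor_net()` solves the full NNLS system, which is comfortable for
  the tens of taxa typical of trait matrices but not engineered for
  hundreds of taxa.
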