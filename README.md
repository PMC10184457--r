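# oakniche

Tools for studying climatic and biotic niche evolution on time-calibrated
phylogenies, built around the analyses used for Eurasian cork oaks
(*Quercus* section *Cerris*) and their holly-oak sister clade. The package
is for phylogeneticists and biogeographers who want to (a) summarize
species' climatic niches from occurrence records as grid-weighted
Köppen–Geiger profiles, (b) reconstruct ancestral niches on a dated tree
with and without information from grafted fossil tips, (c) test
introgression hypotheses with Patterson's D, and (d) visualize categorical
trait variation as a planar split network — all on real inputs or on
synthetic data the package generates itself.

## What it computes

**Köppen profiles and five-category niche coding.** Occurrence records are
snapped to a Köppen–Geiger grid (half-open cells at a stated arc-minute
resolution); a species' profile is the fraction of its *unique occupied
cells* per climate class, so duplicated records never change the result.
Profiles plus terrestrial-biome memberships are binned by an explicit rule
cascade into five ordinal categories: 0 Moist-Subtropical, 1
Meridio-Nemoral, 2 Nemoral, 3 Meridional, 4 Full-Mediterranean. The 10 %
representativeness threshold and the summer-dry/winter-cold cut-offs are
exposed in `niche_config()`.

**Mk1 ancestral-state reconstruction.** For a k-state character on a dated
tree, the equal-rates Mk model has transition probabilities

    P_ii(t) = 1/k + (k-1)/k · exp(-k q t),   P_ij(t) = (1 - exp(-k q t))/k,

with a single rate q (changes · Ma⁻¹ per off-diagonal entry). `fit_mk()`
computes the pruning-algorithm likelihood (with per-node rescaling; exact
for polytomies and missing data), maximizes it over log q by Brent search,
and returns marginal posterior state probabilities ("proportional
likelihoods") for every internal node under a uniform root prior.

**Fossil grafting.** `graft_fossil()` implements the sister-lineage rule:
a fossil's oldest possible age dates a new "shadow MRCA" inserted on the
branch subtending its anchor clade, and the youngest possible age sets the
fossil tip's own age, so the pendant edge has length oldest − youngest.
`asr_two_trees()` then pairs the extant-only and fossil-informed
reconstructions node by node, and `compare_asr_report()` tabulates where
the most likely ancestral state flips.

**Introgression.** `dstat_test()` computes D = (nABBA − nBABA)/(nABBA +
nBABA) from polarized biallelic loci and a locus-bootstrap standard score
Z = |D|/sd(D_boot), with the conventional |Z| ≥ 3 significance threshold;
`dstat_battery()` runs a configured set of four-taxon hypotheses.

**Morphospace.** `hamming_distance()` gives shared-scored Hamming
distances for categorical trait matrices (e.g. 11 binary + 1 ternary leaf
traits) and `neighbor_net()` builds the circular split system: an
agglomerative ordering pass followed by non-negative least squares over
all circular splits, written out as a SplitsTree-compatible NEXUS Splits
block.

**Synthetic data.** Every input has a seeded generator: birth–death dated
trees, Mk-evolved characters, mosaic climate grids with clustered
occurrence clouds, multinomial ABBA/BABA site patterns with a plantable
admixture signal γ, and fossils drawn uniformly within valid branch age
intervals. `cerris_species()`, `cerris_demo_tree()` and `run_pipeline()`
bundle these into a cork-oak-shaped end-to-end demonstration.

## Worked example

```r
library(oakniche)

## climate profiles and niche categories for the 15-species preset
w        <- sim_koppen_world(cerris_species(), seed = 1)
profiles <- koppen_profile(snap_to_cells(w$occurrences, w$grid))
profiles$Q_suber
#> Köppen profile: Q_suber (99 cells)
#>   Csa    59.6%
#>   Csb    30.3%
#>   Cfb     7.1%
#>   BSk     3.0%
classify_niches(profiles, w$biomes)[1:4, ]
#>           species category              label dominant summer_dry
#> 1    Q_acutissima        0  Moist-Subtropical      Cfa  0.0000000
#> 2        Q_afares        4 Full-Mediterranean      Csa  1.0000000
#> 3       Q_brantii        3         Meridional      Csa  0.8571429
#> 4 Q_castaneifolia        3         Meridional      Csa  0.8775510
```

Q. suber's profile is Csa-dominated with no temperate biome membership, so
it lands in category 4 (Full-Mediterranean); the summer-dry column is the
summed fraction of Cs*/Ds* classes that drives rules 3 and 4.

```r
## fossil effect on ancestral states: a Suber-like constructed scenario
sc   <- suber_scenario()
pair <- asr_two_trees(sc$tree, sc$grafted, sc$states, sc$fossil_states, k = 5)
pair
#> Paired ASR: 6 extant tips + 2 fossil tip(s)
#>   extant-only  q = 0.00238691, logL = -6.3937
#>   fossil-aware q = 0.0076558, logL = -10.0675
compare_asr_report(pair)$shared[3, c("fingerprint", "map_extant",
                                     "map_grafted", "flip", "tv")]
#>   fingerprint map_extant map_grafted flip        tv
#> 3       S1|S2          4           2 TRUE 0.8954978
```

Without fossils the clade's crown reconstructs as state 4
(Full-Mediterranean, the state of most extant tips); grafting two
summer-wet temperate fossils (state 2) on its stem flips the crown's most
likely state to 2, with a total-variation shift of 0.90 between the two
probability vectors.

```r
## a planted admixture signal giving E[D] = 0.5
qd <- sim_quartet_sites(n_loci = 200, sites_per_locus = 250,
                        gamma = 0.3, seed = 2)
dstat_test(qd, n_boot = 500, seed = 3)
#> Patterson's D  (((P1,P2),P3),O)
#>   nABBA = 3021, nBABA = 1008 over 200 loci
#>   D = 0.4996, Z = 42.55 (500 locus bootstraps)
#>   SIGNIFICANT at |Z| >= 3
```

The full eight-stage pipeline (`run_pipeline(dir, cerris_config(seed = 1))`)
materializes all inputs, runs profile → classify → graft → asr → dstat →
nnet → report, and writes a JSON manifest with the MD5 of every output;
reruns with the same configuration are byte-identical.

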