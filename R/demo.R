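#' Cork-oak style demonstration preset
#'
#' `cerris_species()` returns emulated niche specifications for the 15
#' cork-oak species (Quercus section Cerris): for each species a set of
#' target Köppen class weights (chosen once to mirror the published
#' representative climate types, with the dominant class carrying the
#' largest weight and marginal classes small shares) and its terrestrial
#' biome memberships.  These drive [sim_koppen_world()] so that
#' grid-weighted profiles and the downstream five-category niche coding
#' reproduce the documented assignments for the anchor species
#' (Q. chenii Moist-Subtropical, Q. crenata Nemoral, Q. castaneifolia
#' Meridional, Q. suber Full-Mediterranean).
#'
#' @return a list of per-species specifications (see
#'   [sim_koppen_world()]).
#' @export
cerris_species <- function() {
  spec <- function(species, weights, biomes)
    list(species = species, weights = weights, biomes = biomes,
         n_records = 400)
  list(
    spec("Q_acutissima",
         c(Cfa = 0.50, Cwa = 0.30, Dwa = 0.10, Dfa = 0.06, Aw = 0.02,
           BSk = 0.02), c("TBMF", "TSMBF")),
    spec("Q_chenii", c(Cfa = 1.0), c("TBMF", "TSMBF")),
    spec("Q_variabilis",
         c(Cfa = 0.40, Cwa = 0.25, Cwb = 0.15, Dwa = 0.10, Dfa = 0.05,
           BSk = 0.05), c("TBMF", "TSMBF")),
    spec("Q_crenata",
         c(Cfb = 0.60, Cfa = 0.31, Csa = 0.05, Csb = 0.04), "TBMF"),
    spec("Q_suber",
         c(Csa = 0.60, Csb = 0.30, Cfb = 0.07, BSk = 0.03), "MFWS"),
    spec("Q_brantii",
         c(Csa = 0.55, Dsa = 0.25, BSk = 0.15, Csb = 0.05),
         c("MFWS", "TGSS", "TBMF")),
    spec("Q_ithaburensis",
         c(Csa = 0.70, Csb = 0.20, BSk = 0.07, BWk = 0.03), "MFWS"),
    spec("Q_macrolepis",
         c(Csa = 0.65, Csb = 0.25, Cfb = 0.10), c("MFWS", "TBMF", "TGSS")),
    spec("Q_afares", c(Csa = 0.70, Csb = 0.30), c("MFWS", "TCF")),
    spec("Q_libani",
         c(Csa = 0.45, Csb = 0.20, Dsa = 0.20, Dsb = 0.10, BSk = 0.05),
         c("MFWS", "TBMF", "TGSS")),
    spec("Q_trojana",
         c(Csa = 0.60, Csb = 0.25, Cfb = 0.08, Dsa = 0.07),
         c("TBMF", "MFWS")),
    spec("Q_euboica", c(Csa = 1.0), "MFWS"),
    spec("Q_castaneifolia",
         c(Csa = 0.50, Csb = 0.20, Dsa = 0.18, Cfa = 0.12), "TBMF"),
    spec("Q_look", c(Csa = 0.80, Csb = 0.20), "MFWS"),
    spec("Q_cerris",
         c(Cfb = 0.35, Csa = 0.30, Csb = 0.15, Cfa = 0.10, Dfb = 0.05,
           Dsa = 0.05), c("TBMF", "MFWS")))
}

#' @rdname cerris_species
#' @details `cerris_demo_tree()` returns a fixed 16-tip chronogram (the
#'   15 section-Cerris species plus Q. ilex as outgroup) whose node ages
#'   follow the published point estimates where available (East/West
#'   split 36.7 Ma, western crown 24.3 Ma, Aegilops stem 19.9 Ma,
#'   Campylolepides crown 13.1 Ma, and the young Pleistocene splits) and
#'   plausible interpolations elsewhere.
#' @export
cerris_demo_tree <- function() {
  nwk <- paste0(
    "((((Q_acutissima:6.8,Q_variabilis:6.8):6.3,Q_chenii:13.1):23.6,",
    "((Q_suber:9,Q_crenata:9):15.3,",
    "((Q_ithaburensis:7,(Q_macrolepis:2.4,Q_brantii:2.4):4.6):12.9,",
    "((Q_afares:8,(Q_trojana:1.8,Q_libani:1.8):6.2):5,",
    "(Q_euboica:11,(Q_castaneifolia:8,(Q_cerris:5,Q_look:5):3):3):2):6.9",
    "):4.4):12.4):12.3,Q_ilex:49);")
  read_dated_tree(text = nwk)
}

#' Constructed fossil-effect scenario on the Suber stem
#'
#' A small, fully specified configuration exhibiting the qualitative
#' signature of fossil-informed ancestral-state reconstruction: most
#' extant tips are summer-drought specialists (state 4, one mesic
#' exception), so the extant-only reconstruction makes the crown and
#' stem nodes Mediterranean-like; grafting fossils scored as summer-wet
#' temperate (state 2) along the Suber-like stem flips the stem and
#' crown argmax to the summer-wet state.
#'
#' @return list with `tree` (extant), `grafted`, `states` (extant tip
#'   states), `fossil_states`, `fossils` (the specs), `k`.
#' @export
suber_scenario <- function() {
  nwk <- "(((S1:10,S2:10):15,(M1:12,(M2:5,M3:5):7):13):10,OUT:35);"
  tree <- read_dated_tree(text = nwk)
  states <- c(S1 = 4, S2 = 2, M1 = 4, M2 = 4, M3 = 4, OUT = 4)
  fossils <- list(
    fossil_spec("F_suber1", c("S1", "S2"), oldest = 22, youngest = 16,
                state = 2),
    fossil_spec("F_suber2", c("S1", "S2"), oldest = 15, youngest = 10,
                state = 2))
  grafted <- graft_all(tree, fossils)
  fossil_states <- c(F_suber1 = 2, F_suber2 = 2)
  list(tree = tree, grafted = grafted, states = states,
       fossil_states = fossil_states, fossils = fossils, k = 5)
}

#' Demonstration D-statistic battery
#'
#' The hypothesis battery run by the demo pipeline: putative hybrid
#' origins of Q. afares and Q. crenata, admixture between Q. cerris and
#' Q. afares, among western subsections, and between Q. ilex and
#' Q. suber — each expressed as a (P1, P2, P3, O) quartet over the demo
#' taxa.  The distant Q. robur (subgenus Quercus) serves as outgroup in
#' every test so that ingroup taxa never double as the polarizing
#' outgroup.
#'
#' @return named list of 4-taxon label vectors.
#' @export
cerris_dstat_tests <- function() {
  list(
    afares_hybrid = c("Q_trojana", "Q_afares", "Q_suber", "Q_robur"),
    crenata_hybrid = c("Q_suber", "Q_crenata", "Q_cerris", "Q_robur"),
    cerris_afares = c("Q_trojana", "Q_afares", "Q_cerris", "Q_robur"),
    subsections = c("Q_macrolepis", "Q_suber", "Q_cerris", "Q_robur"),
    ilex_suber = c("Q_crenata", "Q_suber", "Q_ilex", "Q_robur"))
}
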