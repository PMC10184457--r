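#' Configuration for the demonstration pipeline
#'
#' One structured object with per-stage blocks; every run of
#' [run_pipeline()] is a pure function of this configuration, so reruns
#' with the same configuration are byte-identical.
#'
#' @param seed master seed; per-stage substreams are derived from it so
#'   changing one stage's settings never perturbs another stage's draws.
#' @param n_fossils total fossils (two are always the constructed
#'   summer-wet fossils on the Suber stem; the rest are random).
#' @param n_loci,sites_per_locus locus simulation size.
#' @param admixed_pair optional pair of taxa with a planted admixture
#'   signal (see [sim_rad_loci()]); `NULL` for the null battery.
#' @param p_joint planted joint-derived probability per site.
#' @param n_boot,z_crit D-test bootstrap settings.
#' @param trait_q Mk rate used to simulate the 12 leaf traits (per Ma).
#' @param niche tunables from [niche_config()].
#' @return a named list of class `"cerris_config"`.
#' @export
cerris_config <- function(seed = 1, n_fossils = 20, n_loci = 200,
                          sites_per_locus = 250, admixed_pair = NULL,
                          p_joint = 0.05, n_boot = 500, z_crit = 3,
                          trait_q = 0.02, niche = niche_config()) {
  structure(list(seed = as.integer(seed), n_fossils = n_fossils,
                 n_loci = n_loci, sites_per_locus = sites_per_locus,
                 admixed_pair = admixed_pair, p_joint = p_joint,
                 n_boot = n_boot, z_crit = z_crit, trait_q = trait_q,
                 niche = niche),
            class = "cerris_config")
}

.pipeline_path <- function(dir, name) file.path(dir, name)

.need <- function(dir, name, stage) {
  p <- .pipeline_path(dir, name)
  if (!file.exists(p))
    stop("missing '", name, "': run stage '", stage, "' first")
  p
}

#' Run the niche-evolution demonstration pipeline
#'
#' Executes the full analysis end-to-end in a workspace directory:
#' `simulate` (materialize all synthetic inputs), `profile` (Köppen
#' profiles from occurrences), `classify` (five-category niche coding),
#' `graft` (fossil tips onto the chronogram), `asr` (Mk1 rate estimation
#' and marginal ancestral states on the extant and fossil-informed
#' trees), `dstat` (the hypothesis battery), `nnet` (Hamming distances
#' and the neighbour-net split system for the leaf-trait matrix) and
#' `report` (extant vs fossil-informed comparison).  Stages read their
#' inputs from the workspace, so any subset can be rerun against
#' prebuilt files; a missing upstream artifact names the stage to run
#' first.  A JSON manifest records the configuration, seed and MD5
#' digest of every output.
#'
#' @param dir workspace directory (created if needed).
#' @param config a [cerris_config()].
#' @param stages character vector of stages to run, in order.
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(dir, config = cerris_config(),
                         stages = c("simulate", "profile", "classify",
                                    "graft", "asr", "dstat", "nnet",
                                    "report")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  t0 <- proc.time()[3]
  log_stage <- function(stage, detail)
    message(sprintf("[%s] %.1fs %s", stage, proc.time()[3] - t0, detail))

  if ("simulate" %in% stages) {
    tree <- cerris_demo_tree()
    write_dated_tree(tree, .pipeline_path(dir, "tree.nwk"),
                     ages_file = .pipeline_path(dir, "tree_ages.tsv"))
    world <- sim_koppen_world(cerris_species(), seed = seed + 101L)
    write_koppen_grid(world$grid, .pipeline_path(dir, "grid.tsv"))
    write_occurrences(world$occurrences,
                      .pipeline_path(dir, "occurrences.tsv"))
    write_biomes(world$biomes, .pipeline_path(dir, "biomes.tsv"))
    stem_fossils <- list(
      fossil_spec("F_suber1", c("Q_suber", "Q_crenata"), 20, 14, state = 2),
      fossil_spec("F_suber2", c("Q_suber", "Q_crenata"), 15, 10, state = 2))
    ## fossil states lean towards the summer-wet temperate categories,
    ## as in the pre-Pliocene fossil record the preset emulates
    extra <- sim_fossils(tree, max(0, config$n_fossils - 2), states = 0:3,
                         state_probs = c(0.25, 0.2, 0.4, 0.15),
                         seed = seed + 102L)
    write_fossil_specs(c(stem_fossils, extra),
                       .pipeline_path(dir, "fossils.tsv"))
    ingroup <- ape::drop.tip(tree, "Q_ilex")
    traits <- cbind(
      sim_mk_characters(ingroup, k = 2, q = config$trait_q, n_chars = 11,
                        seed = seed + 103L),
      sim_mk_characters(ingroup, k = 3, q = config$trait_q, n_chars = 1,
                        seed = seed + 104L))
    colnames(traits) <- paste0("char", 1:12)
    write_trait_matrix(traits, .pipeline_path(dir, "traits.tsv"))
    taxa <- unique(c(unlist(cerris_dstat_tests())))
    loci <- sim_rad_loci(taxa, config$n_loci, config$sites_per_locus,
                         admixed_pair = config$admixed_pair,
                         p_joint = config$p_joint, seed = seed + 105L)
    write_loci(loci, .pipeline_path(dir, "loci.tsv"))
    log_stage("simulate", sprintf("%d occurrences, %d fossils, %d loci",
                                  nrow(world$occurrences),
                                  config$n_fossils, config$n_loci))
  }

  if ("profile" %in% stages) {
    grid <- read_koppen_grid(.need(dir, "grid.tsv", "simulate"))
    occ <- read_occurrences(.need(dir, "occurrences.tsv", "simulate"))
    cells <- snap_to_cells(occ, grid)
    profiles <- koppen_profile(cells)
    write_profiles(profiles, .pipeline_path(dir, "profiles.tsv"))
    log_stage("profile", sprintf("%d species, %d occupied cells",
                                 length(profiles), nrow(cells)))
  }

  if ("classify" %in% stages) {
    profiles <- read_profiles(.need(dir, "profiles.tsv", "profile"))
    biomes <- read_biomes(.need(dir, "biomes.tsv", "simulate"))
    cats <- classify_niches(profiles, biomes, config$niche)
    utils::write.table(cats, .pipeline_path(dir, "categories.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("classify", paste(table(cats$category), collapse = "/"))
  }

  if ("graft" %in% stages) {
    tree <- read_dated_tree(.need(dir, "tree.nwk", "simulate"))
    specs <- read_fossil_specs(.need(dir, "fossils.tsv", "simulate"))
    grafted <- graft_all(tree, specs)
    write_dated_tree(grafted, .pipeline_path(dir, "grafted.nwk"),
                     ages_file = .pipeline_path(dir, "grafted_ages.tsv"))
    log_stage("graft", sprintf("%d fossil tips grafted",
                               length(grafted$tip.label) -
                                 length(tree$tip.label)))
  }

  if ("asr" %in% stages) {
    pair <- .compute_asr_pair(dir)
    .write_asr <- function(fit, file) {
      a <- fit$anc[[1]]
      ages <- node_ages(fit$tree)
      tab <- data.frame(node = as.integer(rownames(a)),
                        age = ages[as.integer(rownames(a))],
                        round(a, 10))
      utils::write.table(tab, .pipeline_path(dir, file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    .write_asr(pair$extant, "asr_extant.tsv")
    .write_asr(pair$grafted, "asr_grafted.tsv")
    utils::write.table(
      data.frame(tree = c("extant", "grafted"),
                 q = c(pair$extant$q, pair$grafted$q),
                 logLik = c(pair$extant$logLik, pair$grafted$logLik)),
      .pipeline_path(dir, "asr_summary.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log_stage("asr", sprintf("q_extant=%.4g q_grafted=%.4g",
                             pair$extant$q, pair$grafted$q))
  }

  if ("dstat" %in% stages) {
    loci <- read_loci(.need(dir, "loci.tsv", "simulate"))
    rep <- dstat_battery(loci, cerris_dstat_tests(),
                         n_boot = config$n_boot, seed = seed + 106L,
                         z_crit = config$z_crit)
    utils::write.table(rep, .pipeline_path(dir, "dstat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("dstat", sprintf("%d tests, %d significant", nrow(rep),
                               sum(rep$significant)))
  }

  if ("nnet" %in% stages) {
    traits <- read_trait_matrix(.need(dir, "traits.tsv", "simulate"))
    d <- hamming_distance(traits)
    utils::write.table(data.frame(taxon = rownames(d), round(d, 10)),
                       .pipeline_path(dir, "hamming.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ss <- neighbor_net(d)
    write_nexus_splits(ss, .pipeline_path(dir, "splits.nex"))
    log_stage("nnet", sprintf("%d positive splits", length(ss$splits)))
  }

  if ("report" %in% stages) {
    pair <- .compute_asr_pair(dir)
    cmp <- compare_asr_report(pair)
    round_num <- function(df) {
      df[] <- lapply(df, function(x) if (is.double(x)) round(x, 10) else x)
      df
    }
    utils::write.table(round_num(cmp$shared),
                       .pipeline_path(dir, "asr_compare.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(round_num(cmp$shadow),
                       .pipeline_path(dir, "asr_shadow.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    log_stage("report", sprintf("%d shared nodes, %d argmax flips",
                                nrow(cmp$shared), sum(cmp$shared$flip)))
  }

  outputs <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(
    tool = paste0("oakniche ",
                  as.character(utils::packageVersion("oakniche"))),
    seed = seed,
    config = unclass(config),
    stages = stages,
    outputs = lapply(outputs, function(f)
      list(file = f,
           md5 = unname(tools::md5sum(.pipeline_path(dir, f))))))
  jsonlite::write_json(manifest, .pipeline_path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## shared by the asr and report stages: rebuild the paired fit from the
## workspace files so stages stay independently rerunnable
.compute_asr_pair <- function(dir) {
  tree <- read_dated_tree(.need(dir, "tree.nwk", "simulate"))
  grafted <- read_dated_tree(.need(dir, "grafted.nwk", "graft"))
  cats <- utils::read.table(.need(dir, "categories.tsv", "classify"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  specs <- read_fossil_specs(.need(dir, "fossils.tsv", "simulate"))
  states <- stats::setNames(rep(NA_integer_, length(tree$tip.label)),
                            tree$tip.label)
  states[cats$species] <- cats$category
  fossil_states <- stats::setNames(
    vapply(specs, function(s) as.integer(s$state), 0L),
    vapply(specs, `[[`, "", "label"))
  asr_two_trees(tree, grafted, states, fossil_states, k = 5)
}
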