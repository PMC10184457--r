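#' Simulate an ultrametric birth-death dated tree
#'
#' Forward constant-rate birth-death simulation started from two lineages
#' at the root and conditioned on reaching `n_tips` living lineages: the
#' clock stops at the first event drawn after the count reaches
#' `n_tips`, so for a pure-birth process the expected root age is
#' `sum(1/(i * lambda))` for `i = 2..n_tips`.  Extinct subtrees are
#' pruned, so the returned tree is ultrametric with extant tips at age 0
#' (the root age is the age of the surviving lineages' MRCA).
#' Reproducible for a fixed `seed`.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param lambda,mu per-lineage birth and death rates (per Ma).
#' @param seed integer seed, or `NULL`.
#' @param max_tries retry budget when lineages die out before reaching
#'   `n_tips`.
#' @return a `"phylo"` ultrametric dated tree with tips `t1..tn`.
#' @export
sim_dated_tree <- function(n_tips, lambda = 1, mu = 0, seed = NULL,
                           max_tries = 100) {
  if (n_tips < 2) stop("need n_tips >= 2")
  if (lambda <= 0) stop("need lambda > 0")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    par <- c(0L, 0L); born <- c(0, 0); died <- c(NA_real_, NA_real_)
    alive <- c(1L, 2L)
    t <- 0
    t_end <- NA_real_
    repeat {
      n_alive <- length(alive)
      if (n_alive == 0L) break
      t_next <- t + stats::rexp(1, n_alive * (lambda + mu))
      if (n_alive == n_tips) { t_end <- t_next; break }
      t <- t_next
      who <- alive[sample.int(n_alive, 1)]
      if (stats::runif(1) < lambda / (lambda + mu)) {
        id <- length(par)
        par <- c(par, who, who); born <- c(born, t, t)
        died <- c(died, NA_real_, NA_real_)
        died[who] <- t
        alive <- c(alive[alive != who], id + 1L, id + 2L)
      } else {
        died[who] <- t
        alive <- alive[alive != who]
      }
    }
    if (is.na(t_end)) next
    kids <- split(seq_along(par), par)
    tip_id <- 0L
    build <- function(id) {
      ch <- kids[[as.character(id)]]
      if (is.null(ch)) {
        end <- if (is.na(died[id])) t_end else died[id]
        lab <- if (is.na(died[id])) {
          tip_id <<- tip_id + 1L
          paste0("t", tip_id)
        } else paste0("x", id)          # extinct, pruned below
        sprintf("%s:%.12g", lab, end - born[id])
      } else {
        end <- died[id]
        sprintf("(%s,%s):%.12g", build(ch[1]), build(ch[2]), end - born[id])
      }
    }
    nwk <- sprintf("(%s,%s);", build(1L), build(2L))
    phy <- ape::read.tree(text = nwk)
    extinct <- grep("^x", phy$tip.label, value = TRUE)
    if (length(extinct))
      phy <- ape::drop.tip(phy, extinct, collapse.singles = TRUE)
    if (!is.null(phy) && length(phy$tip.label) == n_tips) {
      validate_dated_tree(phy, ultrametric = TRUE)
      return(phy)
    }
  }
  stop("no surviving tree with ", n_tips,
       " tips within the retry budget (mu too close to or above lambda?)")
}

#' Simulate Mk characters on a dated tree
#'
#' Forward simulation of the equal-rates Mk model: the root state is
#' drawn from the uniform prior and states evolve down every edge with
#' the closed-form transition probabilities of [mk_transition()].
#'
#' @param phy a `"phylo"` dated tree.
#' @param k number of states.
#' @param q substitution rate.
#' @param n_chars number of independent characters.
#' @param seed integer seed, or `NULL`.
#' @return integer matrix (tips x characters) of 0-based states, row
#'   names the tip labels; internal-node states attached as attribute
#'   `"node_states"`.
#' @export
sim_mk_characters <- function(phy, k, q, n_chars = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  phy2 <- stats::reorder(phy, "postorder")
  edge <- phy2$edge[rev(seq_len(nrow(phy2$edge))), , drop = FALSE]
  el <- phy2$edge.length[rev(seq_len(nrow(phy2$edge)))]
  states <- matrix(0L, m, n_chars)
  states[n + 1L, ] <- sample.int(k, n_chars, replace = TRUE)
  for (e in seq_len(nrow(edge))) {
    p_keep <- 1 / k + (k - 1) / k * exp(-k * q * el[e])
    src <- states[edge[e, 1], ]
    keep <- stats::runif(n_chars) < p_keep
    shift <- sample.int(k - 1, n_chars, replace = TRUE)
    states[edge[e, 2], ] <- ifelse(keep, src,
                                   (src - 1L + shift) %% k + 1L)
  }
  out <- states[seq_len(n), , drop = FALSE] - 1L
  rownames(out) <- phy$tip.label
  attr(out, "node_states") <- states[(n + 1L):m, , drop = FALSE] - 1L
  out
}

#' Simulate a mosaic climate world with species occurrences
#'
#' Builds a Köppen grid of vertical single-class strips (one strip per
#' climate class used by any species) and, for every species, scatters
#' occurrence records over class-specific rectangular footprints whose
#' areas are proportional to the species' target class weights.  With
#' many records the grid-weighted profile therefore approaches the
#' target weights by construction, which makes the generator its own
#' oracle.
#'
#' @param species list of species specifications; each a list with
#'   `species` (id), `weights` (named numeric over Köppen classes,
#'   summing to 1), `biomes` (character vector) and optionally
#'   `n_records` (default 300).
#' @param res_arcmin grid resolution (default 5).
#' @param strip_cells width of each class strip in cells (default 20).
#' @param n_lat number of grid rows (default 40).
#' @param footprint_cells nominal footprint size per species in cells
#'   (default 100); each class gets `round(weight * footprint_cells)`
#'   cells (at least 1).
#' @param lon_min,lat_min grid origin in degrees.
#' @param seed integer seed, or `NULL`.
#' @return list with `grid` (a [koppen_grid()]), `occurrences` (data
#'   frame `species`, `lon`, `lat`) and `biomes` (named list).
#' @export
sim_koppen_world <- function(species, res_arcmin = 5, strip_cells = 20,
                             n_lat = 40, footprint_cells = 100,
                             lon_min = 0, lat_min = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- unique(unlist(lapply(species, function(s) names(s$weights))))
  bad <- setdiff(classes, koppen_classes())
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  n_lon <- strip_cells * length(classes)
  res <- res_arcmin / 60
  cls <- matrix(rep(classes, each = strip_cells), n_lon, n_lat)
  grid <- koppen_grid(lon_min, lat_min, n_lon, n_lat, res_arcmin, cls)
  occ <- list()
  biomes <- list()
  for (s in species) {
    w <- s$weights / sum(s$weights)
    n_rec <- s$n_records %||% 300
    cells_per_class <- pmax(1L, round(w * footprint_cells))
    draws <- sample.int(length(w), n_rec, replace = TRUE, prob = w)
    lon <- lat <- numeric(n_rec)
    for (ci in seq_along(w)) {
      idx <- which(draws == ci)
      if (!length(idx)) next
      strip0 <- (match(names(w)[ci], classes) - 1L) * strip_cells
      ncell <- cells_per_class[ci]
      width <- max(1L, min(strip_cells, ceiling(sqrt(ncell))))
      cell <- sample.int(ncell, length(idx), replace = TRUE) - 1L
      cx <- strip0 + cell %% width
      cy <- cell %/% width
      lon[idx] <- lon_min + (cx + stats::runif(length(idx))) * res
      lat[idx] <- lat_min + (cy + stats::runif(length(idx))) * res
    }
    occ[[s$species]] <- data.frame(species = s$species, lon = lon, lat = lat,
                                   stringsAsFactors = FALSE)
    biomes[[s$species]] <- s$biomes
  }
  list(grid = grid,
       occurrences = do.call(rbind, c(occ, list(make.row.names = FALSE))),
       biomes = biomes)
}

#' Simulate four-taxon site-pattern data
#'
#' Draws, for every locus, a multinomial split of sites over \{ABBA,
#' BABA, uninformative\} and materializes the corresponding 0/1 site
#' columns (uninformative sites are non-ABBA/BABA patterns with the
#' outgroup ancestral).  An admixture signal is planted as
#' `p_ABBA = p0 + gamma * delta`, `p_BABA = p0`.
#'
#' @param n_loci number of loci.
#' @param sites_per_locus sites per locus.
#' @param p_abba,p_baba pattern probabilities (used when `gamma` is
#'   `NULL`); must sum to at most 1.
#' @param gamma admixture strength; if given, overrides `p_abba` with
#'   `p0 + gamma * delta`.
#' @param p0 baseline (incomplete lineage sorting) pattern probability.
#' @param delta admixture scaling (default `2/15`, so `gamma = 0.3`
#'   yields a threefold ABBA excess and expected D of 0.5).
#' @param taxa quartet labels (P1, P2, P3, O).
#' @param seed integer seed, or `NULL`.
#' @return a [quartet_data()] in count mode.
#' @export
sim_quartet_sites <- function(n_loci = 200, sites_per_locus = 250,
                              p_abba = 0.02, p_baba = 0.02,
                              gamma = NULL, p0 = 0.02, delta = 2 / 15,
                              taxa = c("P1", "P2", "P3", "O"),
                              seed = NULL) {
  if (!is.null(gamma)) {
    p_abba <- p0 + gamma * delta
    p_baba <- p0
  }
  if (p_abba < 0 || p_baba < 0 || p_abba + p_baba > 1)
    stop("invalid pattern probabilities")
  if (!is.null(seed)) set.seed(seed)
  ## uninformative fillers: outgroup-ancestral patterns that are neither
  ## ABBA nor BABA
  fillers <- cbind(c(0, 0, 0, 0), c(1, 1, 1, 0), c(0, 0, 1, 0),
                   c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0))
  loci <- lapply(seq_len(n_loci), function(i) {
    ct <- stats::rmultinom(1, sites_per_locus,
                           c(p_abba, p_baba, 1 - p_abba - p_baba))[, 1]
    cols <- cbind(
      matrix(rep(c(0, 1, 1, 0), ct[1]), nrow = 4),
      matrix(rep(c(1, 0, 1, 0), ct[2]), nrow = 4),
      fillers[, sample.int(ncol(fillers), ct[3], replace = TRUE),
              drop = FALSE])
    cols <- cols[, sample.int(ncol(cols)), drop = FALSE]
    rownames(cols) <- taxa
    cols
  })
  quartet_data(loci, taxa = taxa, mode = "count")
}

#' Simulate multi-taxon biallelic loci with an optional admixed pair
#'
#' Null model: every non-outgroup taxon carries the derived allele
#' independently with probability `p_derived` at each site, which makes
#' Patterson's D zero in expectation for every quartet.  If
#' `admixed_pair` is given, joint derived alleles are planted in exactly
#' that pair of taxa with probability `p_joint` per site while the
#' pair's baseline rate is lowered so each taxon's marginal derived rate
#' stays `p_derived`; the excess ABBA signal therefore appears only in
#' quartets using the pair jointly as (P2, P3), and every test involving
#' just one of the two taxa remains null.
#'
#' @param taxa taxon labels; the last is the outgroup (always ancestral).
#' @param n_loci,sites_per_locus dataset dimensions.
#' @param p_derived per-taxon derived probability under the null.
#' @param admixed_pair character vector of two taxa, or `NULL`.
#' @param p_joint per-site joint derived probability for the pair.
#' @param seed integer seed, or `NULL`.
#' @return list of per-locus 0/1 matrices (taxa x sites) with row names.
#' @export
sim_rad_loci <- function(taxa, n_loci = 200, sites_per_locus = 250,
                         p_derived = 0.1, admixed_pair = NULL,
                         p_joint = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- length(taxa)
  p_base <- p_derived
  if (!is.null(admixed_pair)) {
    miss <- setdiff(admixed_pair, taxa)
    if (length(miss)) stop("admixed taxa not in taxa: ",
                           paste(miss, collapse = ", "))
    if (p_joint > p_derived)
      stop("p_joint must not exceed p_derived")
    # baseline for the pair chosen so the marginal rate stays p_derived
    p_base <- (p_derived - p_joint) / (1 - p_joint)
  }
  lapply(seq_len(n_loci), function(i) {
    m <- matrix(stats::rbinom((nt - 1) * sites_per_locus, 1, p_derived),
                nt - 1, sites_per_locus)
    m <- rbind(m, 0)
    rownames(m) <- taxa
    if (!is.null(admixed_pair)) {
      for (tx in admixed_pair)
        m[tx, ] <- stats::rbinom(sites_per_locus, 1, p_base)
      joint <- stats::rbinom(sites_per_locus, 1, p_joint) == 1
      m[admixed_pair[1], joint] <- 1
      m[admixed_pair[2], joint] <- 1
    }
    m
  })
}

#' Simulate graftable fossil specifications
#'
#' Anchors each fossil to a random non-root branch of the tree, draws the
#' oldest age uniformly inside that branch's age interval and the
#' youngest age uniformly in `[0, oldest]`, and assigns a state from the
#' configured distribution.  Every generated specification satisfies the
#' grafting preconditions by construction.
#'
#' @param phy a `"phylo"` dated tree.
#' @param n_fossils number of fossils.
#' @param states possible scored states.
#' @param state_probs sampling probabilities (default uniform).
#' @param prefix label prefix; fossils are labelled `<prefix>1`, ...
#' @param seed integer seed, or `NULL`.
#' @return list of [fossil_spec()] objects.
#' @export
sim_fossils <- function(phy, n_fossils, states = 0:4, state_probs = NULL,
                        prefix = "fossil_", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_fossils == 0) return(list())
  ages <- node_ages(phy)
  lapply(seq_len(n_fossils), function(i) {
    e <- sample(seq_len(nrow(phy$edge)), 1)
    child <- phy$edge[e, 2]
    lo <- ages[child]; hi <- ages[phy$edge[e, 1]]
    oldest <- stats::runif(1, lo, hi)
    youngest <- stats::runif(1, 0, oldest)
    fossil_spec(paste0(prefix, i), clade_tips(phy, child), oldest, youngest,
                state = sample(states, 1, prob = state_probs),
                assignable = TRUE)
  })
}
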