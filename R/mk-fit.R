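#' Fit the equal-rates Mk model and reconstruct ancestral states
#'
#' The package's central model fit: estimates (or accepts) the single
#' symmetric rate of the Mk model for one or more categorical characters
#' on a dated tree, and computes marginal ancestral-state probabilities
#' ("proportional likelihoods") for every internal node.
#'
#' @param phy a `"phylo"` dated tree with branch lengths in Ma.
#' @param x tip states: named vector or tips-by-characters matrix of
#'   0-based state indices; `NA` = missing (all-ones partial).
#' @param k number of states; default one more than the largest observed
#'   index.
#' @param q fixed rate, or `NULL` (default) to estimate by maximum
#'   likelihood.
#' @param per_character if `TRUE` and `q` is estimated, fit one rate per
#'   character instead of a single shared rate.
#' @param prior root prior (default uniform `1/k`, the Mk stationary
#'   distribution).
#' @param q_min,q_max,tol optimizer bounds and relative tolerance, passed
#'   to [ml_rate()].
#' @param method ancestral-state flavour, see [marginal_asr()].
#' @return an object of class `"mk_fit"` with components `tree`, `data`,
#'   `k`, `q` (length 1 or one per character), `logLik`, `anc` (list of
#'   node-by-state probability matrices, one per character), `prior`,
#'   `boundary`.
#' @seealso [marginal_asr()], [ml_rate()], [asr_two_trees()]
#' @export
fit_mk <- function(phy, x, k = NULL, q = NULL, per_character = FALSE,
                   prior = NULL, q_min = 1e-8, q_max = 100, tol = 1e-8,
                   method = c("marginal", "conditional")) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x)))
  if (is.null(k)) k <- max(x, na.rm = TRUE) + 1L
  if (is.null(prior)) prior <- rep(1 / k, k)
  nc <- ncol(x)
  estimated <- is.null(q)
  boundary <- FALSE
  if (estimated) {
    if (per_character) {
      qs <- numeric(nc); bnd <- logical(nc)
      for (j in seq_len(nc)) {
        qj <- ml_rate(phy, x[, j, drop = FALSE], k, q_min, q_max, tol, prior)
        qs[j] <- as.numeric(qj); bnd[j] <- attr(qj, "boundary")
      }
      q <- qs; boundary <- any(bnd)
    } else {
      qh <- ml_rate(phy, x, k, q_min, q_max, tol, prior)
      q <- as.numeric(qh); boundary <- attr(qh, "boundary")
    }
  }
  qvec <- if (length(q) == 1L) rep(q, nc) else q
  if (length(qvec) != nc) stop("length of q must be 1 or ncol(x)")
  anc <- vector("list", nc)
  ll <- numeric(nc)
  for (j in seq_len(nc)) {
    a <- marginal_asr(phy, x[, j, drop = FALSE], k, qvec[j], prior, method)
    ll[j] <- attr(a, "logLik")
    attr(a, "logLik") <- NULL
    anc[[j]] <- a
  }
  names(anc) <- colnames(x)
  structure(list(tree = phy, data = x, k = k, q = q,
                 estimated = estimated, per_character = per_character,
                 prior = prior, logLik = sum(ll), logLik_by_char = ll,
                 anc = anc, method = method, boundary = boundary),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Mk1 fit: %d tips, %d character(s), k = %d states\n",
              length(x$tree$tip.label), ncol(x$data), x$k))
  cat(sprintf("  rate q%s: %s%s\n",
              if (x$estimated) " (ML)" else " (fixed)",
              paste(signif(x$q, digits), collapse = ", "),
              if (x$boundary) "  [at search bound]" else ""))
  cat(sprintf("  log-likelihood: %.*f\n", digits, x$logLik))
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  map <- vapply(object$anc, function(a)
    max.col(a, ties.method = "first")[1] - 1L, 0L)
  cat(sprintf("Mk1 model, k = %d, uniform root prior\n", object$k))
  print(object)
  cat("  root MAP state per character:",
      paste(map, collapse = " "), "\n")
  invisible(object)
}

#' @export
coef.mk_fit <- function(object, ...) c(q = object$q)

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = if (object$estimated)
    length(unique(object$q)) else 0, class = "logLik")
}

#' @export
predict.mk_fit <- function(object, type = c("prob", "state"),
                           character = 1, ...) {
  type <- match.arg(type)
  a <- object$anc[[character]]
  if (type == "prob") return(a)
  max.col(a, ties.method = "first") - 1L
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sim_mk_characters(object$tree, object$k, object$q[1], nsim, seed = seed)
}

#' @export
plot.mk_fit <- function(x, character = 1, cex = 0.5, ...) {
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(pie = x$anc[[character]], cex = cex)
  invisible(x)
}

## clade fingerprint: sorted extant-tip set below a node, as one string
.fingerprint <- function(phy, node, extant) {
  tips <- intersect(clade_tips(phy, node), extant)
  if (!length(tips)) return(NA_character_)
  paste(sort(tips), collapse = "|")
}

#' Paired ancestral-state reconstruction with and without fossils
#'
#' Runs rate estimation and marginal ancestral-state reconstruction on
#' (1) the extant-only dated tree and (2) the same tree with fossil tips
#' grafted, and keys the two sets of internal nodes to each other: the
#' counterpart of an extant-tree MRCA is the MRCA of the same extant tip
#' set in the grafted tree.  Shadow MRCAs (created by grafting) appear
#' only in the grafted result.
#'
#' @param extant_tree dated tree of extant tips only.
#' @param grafted_tree the same tree after [graft_all()].
#' @param states named vector of 0-based states for the extant tips.
#' @param fossil_states named vector of states for every fossil tip in
#'   `grafted_tree`; a fossil without an entry is an error.
#' @param k number of states.
#' @param ... passed to [fit_mk()] (e.g. `q`, `q_max`).
#' @return an object of class `"asr_pair"`: the two `"mk_fit"`s, the
#'   node correspondence table, and the fossil tip labels.
#' @export
asr_two_trees <- function(extant_tree, grafted_tree, states, fossil_states,
                          k, ...) {
  extant <- extant_tree$tip.label
  fossils <- setdiff(grafted_tree$tip.label, extant)
  if (length(setdiff(extant, grafted_tree$tip.label)))
    stop("grafted tree is missing extant tips")
  no_state <- setdiff(fossils, names(fossil_states))
  if (length(no_state))
    stop("missing fossil state for: ", paste(no_state, collapse = ", "))
  fit_e <- fit_mk(extant_tree, states[extant], k = k, ...)
  all_states <- c(states[extant], fossil_states[fossils])
  fit_g <- fit_mk(grafted_tree, all_states, k = k, ...)
  n_e <- length(extant)
  nodes_e <- (n_e + 1L):(n_e + extant_tree$Nnode)
  map <- data.frame(
    extant_node = nodes_e,
    grafted_node = NA_integer_,
    fingerprint = vapply(nodes_e, function(v)
      .fingerprint(extant_tree, v, extant), ""),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(map))) {
    tips <- strsplit(map$fingerprint[i], "|", fixed = TRUE)[[1]]
    map$grafted_node[i] <- mrca_node(grafted_tree, tips)
  }
  n_g <- length(grafted_tree$tip.label)
  nodes_g <- (n_g + 1L):(n_g + grafted_tree$Nnode)
  shadow <- setdiff(nodes_g, map$grafted_node)
  structure(list(extant = fit_e, grafted = fit_g, map = map,
                 fossils = fossils, shadow_nodes = shadow),
            class = "asr_pair")
}

#' @export
print.asr_pair <- function(x, ...) {
  cat(sprintf("Paired ASR: %d extant tips + %d fossil tip(s)\n",
              length(x$extant$tree$tip.label), length(x$fossils)))
  cat(sprintf("  extant-only  q = %g, logL = %.4f\n",
              x$extant$q[1], x$extant$logLik))
  cat(sprintf("  fossil-aware q = %g, logL = %.4f\n",
              x$grafted$q[1], x$grafted$logLik))
  invisible(x)
}

#' Side-by-side report of extant-only vs fossil-informed reconstructions
#'
#' For every internal node shared between the two trees: the state
#' probabilities from both reconstructions, whether the most likely
#' state differs (`flip`), and the total variation distance between the
#' two probability vectors.  Shadow MRCAs present only in the grafted
#' tree are reported in the `shadow` component.
#'
#' @param pair an [asr_two_trees()] result.
#' @param character which character to report, default 1.
#' @return a list with data frames `shared` and `shadow`.
#' @export
compare_asr_report <- function(pair, character = 1) {
  a_e <- pair$extant$anc[[character]]
  a_g <- pair$grafted$anc[[character]]
  k <- ncol(a_e)
  pe <- a_e[as.character(pair$map$extant_node), , drop = FALSE]
  pg <- a_g[as.character(pair$map$grafted_node), , drop = FALSE]
  shared <- data.frame(
    pair$map,
    map_extant = max.col(pe, ties.method = "first") - 1L,
    map_grafted = max.col(pg, ties.method = "first") - 1L,
    tv = rowSums(abs(pe - pg)) / 2,
    stringsAsFactors = FALSE)
  shared$flip <- shared$map_extant != shared$map_grafted
  colnames(pe) <- paste0("extant_p", 0:(k - 1))
  colnames(pg) <- paste0("grafted_p", 0:(k - 1))
  shared <- cbind(shared, pe, pg)
  rownames(shared) <- NULL
  ps <- a_g[as.character(pair$shadow_nodes), , drop = FALSE]
  n_g <- length(pair$grafted$tree$tip.label)
  lab <- if (!is.null(pair$grafted$tree$node.label))
    pair$grafted$tree$node.label[pair$shadow_nodes - n_g]
  else character(length(pair$shadow_nodes))
  shadow <- data.frame(
    grafted_node = pair$shadow_nodes, label = lab,
    map_grafted = if (nrow(ps)) max.col(ps, ties.method = "first") - 1L
                  else integer(0),
    stringsAsFactors = FALSE)
  shadow <- cbind(shadow, ps)
  rownames(shadow) <- NULL
  list(shared = shared, shadow = shadow)
}
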