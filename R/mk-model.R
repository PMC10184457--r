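#' Transition probabilities of the equal-rates Mk model
#'
#' Closed-form transition matrix of the k-state Markov model with one
#' symmetric rate `q` (expected changes per Ma per off-diagonal entry)
#' over a branch of length `t` Ma:
#' `P_ii = 1/k + ((k-1)/k) exp(-k q t)`, `P_ij = (1 - exp(-k q t))/k`.
#' Rows sum to 1; `t = 0` gives the identity and `q t -> Inf` the
#' stationary uniform matrix.
#'
#' @param q rate, `>= 0`.
#' @param t branch length in Ma, `>= 0`.
#' @param k number of states, `>= 2`.
#' @return a `k x k` stochastic matrix.
#' @export
mk_transition <- function(q, t, k) {
  if (t < 0) stop("negative branch length t = ", t)
  if (q < 0) stop("negative rate q = ", q)
  if (k < 2) stop("need k >= 2 states")
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) / k * e
  P
}

## state matrix coercion: accepts a named vector (one character) or a
## tips x characters matrix of 0-based state indices with NA = missing;
## returns 1-based integer matrix aligned to phy$tip.label
.mk_states <- function(phy, x, k) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x)))
  if (is.null(rownames(x)))
    stop("states must be named by tip label")
  miss <- setdiff(rownames(x)[rowSums(!is.na(x)) > 0], phy$tip.label)
  if (length(miss))
    stop("state(s) for unknown tip(s): ", paste(miss, collapse = ", "))
  X <- matrix(NA_integer_, length(phy$tip.label), ncol(x),
              dimnames = list(phy$tip.label, colnames(x)))
  common <- intersect(phy$tip.label, rownames(x))
  X[common, ] <- as.integer(x[common, , drop = FALSE])
  if (any(X < 0 | X >= k, na.rm = TRUE))
    stop("state index outside 0..", k - 1)
  if (all(is.na(X))) stop("no non-missing tip states")
  X + 1L
}

## Felsenstein pruning with per-node rescaling, vectorized over
## characters; optionally the down (outside) pass for marginal ASR.
## X: 1-based integer matrix tips x chars (NA = missing partial of ones).
.mk_engine <- function(phy, X, k, q, prior = rep(1 / k, k),
                       need_down = FALSE) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  nc <- ncol(X)
  phy <- stats::reorder(phy, "postorder")
  edge <- phy$edge
  el <- phy$edge.length
  ne <- nrow(edge)
  up <- vector("list", m)
  below <- matrix(0, m, nc)          # log scale factors accumulated below
  for (i in seq_len(n)) {
    u <- matrix(0, k, nc)
    obs <- !is.na(X[i, ])
    u[cbind(X[i, obs], which(obs))] <- 1
    u[, !obs] <- 1
    up[[i]] <- u
  }
  Plist <- if (need_down) vector("list", ne) else NULL
  msg <- if (need_down) vector("list", ne) else NULL
  msgfac <- if (need_down) matrix(0, ne, nc) else NULL
  for (e in seq_len(ne)) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- mk_transition(q, el[e], k)
    M <- P %*% up[[ch]]
    s <- apply(M, 2, max)
    pos <- s > 0
    M <- M / rep(ifelse(pos, s, 1), each = k)
    logs <- ifelse(pos, log(pmax(s, .Machine$double.xmin)), -Inf)
    if (need_down) {
      Plist[[e]] <- P
      msg[[e]] <- M
      msgfac[e, ] <- logs + below[ch, ]
    }
    if (is.null(up[[par]])) {
      up[[par]] <- M
      below[par, ] <- below[ch, ] + logs
    } else {
      up[[par]] <- up[[par]] * M
      below[par, ] <- below[par, ] + below[ch, ] + logs
    }
  }
  root <- n + 1L
  Lroot <- as.numeric(crossprod(prior, up[[root]]))
  loglik <- ifelse(Lroot > 0, log(Lroot), -Inf) + below[root, ]
  out <- list(loglik = loglik, up = up, below = below, root = root,
              n_tip = n, n_node = m)
  if (need_down) {
    B <- vector("list", m)
    Bfac <- matrix(0, m, nc)
    B[[root]] <- matrix(prior, k, nc)
    kids <- split(seq_len(ne), edge[, 1])
    for (e in rev(seq_len(ne))) {       # reverse postorder = preorder
      par <- edge[e, 1]; ch <- edge[e, 2]
      sibs <- setdiff(kids[[as.character(par)]], e)
      prodsib <- B[[par]]
      fac <- Bfac[par, ]
      for (s_e in sibs) {
        prodsib <- prodsib * msg[[s_e]]
        fac <- fac + msgfac[s_e, ]
      }
      Bv <- crossprod(Plist[[e]], prodsib)
      sc <- apply(Bv, 2, max)
      pos <- sc > 0
      Bv <- Bv / rep(ifelse(pos, sc, 1), each = k)
      B[[ch]] <- Bv
      Bfac[ch, ] <- fac + ifelse(pos, log(pmax(sc, .Machine$double.xmin)), -Inf)
    }
    out$B <- B
    out$Bfac <- Bfac
  }
  out
}

#' Mk log-likelihood by the pruning algorithm
#'
#' Felsenstein pruning with per-node rescaling; exact for polytomies.
#' Missing tip states contribute all-ones partials.
#'
#' @param phy a `"phylo"` dated tree with branch lengths.
#' @param x tip states: a named vector, or a tips-by-characters matrix,
#'   of 0-based state indices (`NA` = missing).
#' @param k number of states.
#' @param q substitution rate (per Ma, per off-diagonal entry).
#' @param prior root prior; default the Mk stationary uniform `1/k`.
#' @return the summed log-likelihood over characters, with per-character
#'   values as attribute `"by_character"`.
#' @export
prune_loglik <- function(phy, x, k, q, prior = rep(1 / k, k)) {
  if (abs(sum(prior) - 1) > 1e-9) stop("root prior must sum to 1")
  X <- .mk_states(phy, x, k)
  eng <- .mk_engine(phy, X, k, q, prior)
  structure(sum(eng$loglik), by_character = eng$loglik)
}

#' Maximum-likelihood estimate of the Mk rate
#'
#' One-dimensional bounded maximization of the summed log-likelihood over
#' `log(q)` (Brent's golden-section/parabolic search) to relative
#' tolerance `tol`.  A maximum at either search bound is flagged.
#'
#' @inheritParams prune_loglik
#' @param q_min,q_max search bounds for the rate.
#' @param tol relative convergence tolerance on `q`.
#' @return the estimate `q_hat` with attributes `"logLik"` and
#'   `"boundary"` (`TRUE` if the optimum hit a search bound).
#' @export
ml_rate <- function(phy, x, k, q_min = 1e-8, q_max = 100, tol = 1e-8,
                    prior = rep(1 / k, k)) {
  X <- .mk_states(phy, x, k)
  invariant <- all(apply(X, 2, function(col) {
    obs <- unique(col[!is.na(col)])
    length(obs) <= 1
  }))
  f <- function(u) sum(.mk_engine(phy, X, k, exp(u), prior)$loglik)
  opt <- stats::optimize(f, c(log(q_min), log(q_max)), maximum = TRUE,
                         tol = tol / 2)
  q_hat <- exp(opt$maximum)
  boundary <- (opt$maximum - log(q_min)) < 2 * tol ||
              (log(q_max) - opt$maximum) < 2 * tol
  if (invariant) {
    q_hat <- q_min
    boundary <- TRUE
    warning("all characters invariant; rate pinned at lower bound")
  }
  structure(q_hat,
            logLik = if (invariant) f(log(q_min)) else opt$objective,
            boundary = boundary)
}

#' Marginal ancestral-state reconstruction under the Mk model
#'
#' For every internal node, the marginal posterior probability of each
#' state given the tip data, tree and rate ("proportional likelihoods"),
#' computed by the up-down pass under the root prior.  `method =
#' "conditional"` instead returns the renormalized conditional (upward)
#' likelihoods of each node's subtree.
#'
#' @inheritParams prune_loglik
#' @param method `"marginal"` (default) or `"conditional"`.
#' @return a matrix `Nnode x k` of state probabilities (rows sum to 1),
#'   row names the internal node numbers; attributes `"logLik"` (total)
#'   and `"node_logLik"` (per-node likelihood recovered from the
#'   up/down decomposition, a numerical self-check).
#' @export
marginal_asr <- function(phy, x, k, q, prior = rep(1 / k, k),
                         method = c("marginal", "conditional")) {
  method <- match.arg(method)
  X <- .mk_states(phy, x, k)
  if (ncol(X) != 1) stop("marginal_asr reconstructs one character at a time")
  eng <- .mk_engine(phy, X, k, q, prior, need_down = (method == "marginal"))
  n <- eng$n_tip
  nodes <- (n + 1L):eng$n_node
  probs <- matrix(NA_real_, length(nodes), k,
                  dimnames = list(nodes, paste0("state", 0:(k - 1))))
  node_ll <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    w <- if (method == "marginal") eng$up[[v]][, 1] * eng$B[[v]][, 1]
         else eng$up[[v]][, 1]
    probs[i, ] <- w / sum(w)
    if (method == "marginal")
      node_ll[i] <- log(sum(w)) + eng$below[v, 1] + eng$Bfac[v, 1]
  }
  structure(probs, logLik = eng$loglik[1], node_logLik = node_ll)
}
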