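#' Hamming distances on a categorical trait matrix
#'
#' Simple pairwise Hamming distances for categorical characters of any
#' small arity: `d(i, j)` is the number of characters scored in both
#' taxa that differ, divided by the number scored in both (a ternary
#' mismatch counts 1 like a binary one).  A taxon pair sharing no scored
#' character is an error.
#'
#' @param m matrix (taxa x characters) of categorical states; `NA` =
#'   missing.  Row names are the taxon labels.
#' @return symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
hamming_distance <- function(m) {
  if (is.null(rownames(m))) stop("trait matrix needs taxon row names")
  if (nrow(m) < 3) stop("need >= 3 taxa")
  if (any(colSums(!is.na(m)) == 0)) stop("character with no observations")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(shared))
        stop(sprintf("taxa '%s' and '%s' share no scored character",
                     rownames(m)[i], rownames(m)[j]))
      d[i, j] <- d[j, i] <- sum(m[i, shared] != m[j, shared]) / sum(shared)
    }
  }
  d
}

## --- neighbour-net agglomeration ------------------------------------------
## Canonical two-level agglomeration: clusters are chains represented by
## their (<= 2) endpoint nodes; cluster pairs are chosen by the
## neighbour-joining criterion on mean between-cluster distances, the
## joining endpoints by the same criterion with the two clusters'
## endpoints treated as singletons; interior nodes of chains longer than
## two are eliminated by the 2/3-1/3 distance reduction.

.nn_reduce <- function(d, x, y, z) {
  u <- 2 / 3 * d[x, ] + d[y, ] / 3
  v <- 2 / 3 * d[z, ] + d[y, ] / 3
  uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
  d[x, ] <- u; d[, x] <- u
  d[z, ] <- v; d[, z] <- v
  d[y, ] <- 0; d[, y] <- 0
  d[x, z] <- d[z, x] <- uv
  d[x, x] <- d[z, z] <- 0
  d
}

## adjusted-row-sum for endpoint nodes `xs` against other clusters
.nn_rsum <- function(d, xs, clusters) {
  vapply(seq_along(xs), function(i) {
    r <- sum(d[xs[i], xs[-i]])
    for (cl in clusters) r <- r + mean(d[xs[i], cl])
    r
  }, 0)
}

.nn_ordering <- function(d) {
  n <- nrow(d)
  if (n <= 3) return(seq_len(n))
  CL <- ord <- as.list(seq_len(n))   # endpoints / full orderings
  DM <- d
  while (length(CL) > 1) {
    l <- nrow(DM)
    if (l > 2) {
      r <- rowSums(DM) / (l - 2)
      Q <- DM - outer(r, r, "+")
      diag(Q) <- Inf
      sel <- arrayInd(which.min(Q), dim(Q))
      e1 <- min(sel); e2 <- max(sel)
    } else {
      e1 <- 1L; e2 <- 2L
    }
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])
    if (n1 == 1 && n2 == 1) {
      CL[[e1]] <- c(CL[[e1]], CL[[e2]])
      ord[[e1]] <- c(ord[[e1]], ord[[e2]])
    } else {
      xs <- c(CL[[e1]], CL[[e2]])
      others <- CL[-c(e1, e2)]
      m_hat <- length(xs) + length(others)
      r <- .nn_rsum(d, xs, others)
      if (m_hat > 2) r <- r / (m_hat - 2)
      Qhat <- d[xs, xs] - outer(r, r, "+")
      cand <- Qhat[seq_len(n1), n1 + seq_len(n2), drop = FALSE]
      blub <- which.min(cand)
      if (n1 == 2 && n2 == 1) {
        if (blub == 2) {         # join at CL1[2]
          newCL <- c(CL[[e1]][1], CL[[e2]])
          newOrd <- c(ord[[e1]], ord[[e2]])
          d <- .nn_reduce(d, CL[[e1]][1], CL[[e1]][2], CL[[e2]])
        } else {                 # join at CL1[1]
          newCL <- c(CL[[e2]], CL[[e1]][2])
          newOrd <- c(ord[[e2]], ord[[e1]])
          d <- .nn_reduce(d, CL[[e2]], CL[[e1]][1], CL[[e1]][2])
        }
      } else if (n1 == 1 && n2 == 2) {
        if (blub == 1) {
          newCL <- c(CL[[e1]], CL[[e2]][2])
          newOrd <- c(ord[[e1]], ord[[e2]])
          d <- .nn_reduce(d, CL[[e1]], CL[[e2]][1], CL[[e2]][2])
        } else {
          newCL <- c(CL[[e2]][1], CL[[e1]])
          newOrd <- c(ord[[e2]], ord[[e1]])
          d <- .nn_reduce(d, CL[[e2]][1], CL[[e2]][2], CL[[e1]])
        }
      } else {                   # 2 and 2
        i1 <- (blub - 1) %% 2 + 1      # endpoint of CL1
        i2 <- (blub - 1) %/% 2 + 1     # endpoint of CL2
        a <- CL[[e1]][3 - i1]; b <- CL[[e1]][i1]
        c_ <- CL[[e2]][i2];    e_ <- CL[[e2]][3 - i2]
        newCL <- c(a, e_)
        o1 <- if (i1 == 2) ord[[e1]] else rev(ord[[e1]])
        o2 <- if (i2 == 1) ord[[e2]] else rev(ord[[e2]])
        newOrd <- c(o1, o2)
        d <- .nn_reduce(d, a, b, c_)
        d <- .nn_reduce(d, a, c_, e_)
      }
      CL[[e1]] <- newCL
      ord[[e1]] <- newOrd
    }
    for (i in seq_along(CL)) {
      if (i != e1)
        DM[i, e1] <- DM[e1, i] <- mean(d[CL[[i]], CL[[e1]]])
    }
    DM[e1, e1] <- 0
    DM <- DM[-e2, -e2, drop = FALSE]
    CL <- CL[-e2]
    ord <- ord[-e2]
  }
  ord[[1]]
}

#' Neighbour-net circular split network
#'
#' Computes a neighbour-net split system from a distance matrix: an
#' agglomerative pass produces a circular ordering of the taxa, then the
#' weights of all `n(n-1)/2` splits compatible with that ordering are
#' estimated by least squares constrained to non-negativity (active-set
#' NNLS); splits with weight at most `eps` are dropped.  Ties in the
#' agglomeration are broken towards lexicographically earlier taxon
#' labels, so the ordering is reproducible under relabelling.
#'
#' @param d symmetric non-negative distance matrix with labelled rows
#'   (or a `"dist"` object); at least 3 taxa.
#' @param eps weight threshold below which a split is discarded.
#' @return an object of class `"split_system"`: `taxa` (labels),
#'   `cycle` (circular ordering, indices into `taxa`), `splits` (list of
#'   integer vectors, one side of each bipartition), `weights`, `rss`
#'   (residual sum of squares of the distance fit).
#' @export
neighbor_net <- function(d, eps = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  taxa <- rownames(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(d)))
  lex <- order(taxa)
  cyc_lex <- .nn_ordering(d[lex, lex, drop = FALSE])
  cycle <- lex[cyc_lex]
  fit <- .fit_circular_splits(d, cycle, eps)
  structure(list(taxa = taxa, cycle = cycle, splits = fit$splits,
                 weights = fit$weights, rss = fit$rss),
            class = "split_system")
}

## enumerate all circular splits of `cycle` (arcs not containing the
## first cycle element), fit non-negative weights to the distances
.fit_circular_splits <- function(d, cycle, eps) {
  n <- length(cycle)
  sides <- list()
  for (i in 2:n) for (j in i:n) sides[[length(sides) + 1]] <- cycle[i:j]
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  y <- d[upper.tri(d)]
  X <- matrix(0, nrow(pairs), length(sides))
  for (s in seq_along(sides)) {
    inside <- seq_len(nrow(d)) %in% sides[[s]]
    X[, s] <- inside[pairs[, 1]] != inside[pairs[, 2]]
  }
  w <- pracma::lsqnonneg(X, y)$x
  rss <- sum((y - X %*% w)^2)
  keep <- w > eps
  list(splits = sides[keep], weights = w[keep], rss = rss)
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("circular split system: %d taxa, %d positive splits (rss %.3g)\n",
              length(x$taxa), length(x$splits), x$rss))
  cat("  cycle:", paste(x$taxa[x$cycle], collapse = " "), "\n")
  invisible(x)
}

#' Metric induced by a split system
#'
#' `d(i, j)` is the sum of the weights of the splits separating `i` and
#' `j`; for a split system fitted to a circular-decomposable metric this
#' reproduces the input distances.
#'
#' @param ss a `"split_system"`.
#' @return symmetric distance matrix over `ss$taxa`.
#' @export
split_distances <- function(ss) {
  n <- length(ss$taxa)
  d <- matrix(0, n, n, dimnames = list(ss$taxa, ss$taxa))
  for (s in seq_along(ss$splits)) {
    inside <- seq_len(n) %in% ss$splits[[s]]
    sep <- outer(inside, inside, "!=")
    d <- d + ss$weights[s] * sep
  }
  d
}

#' Write a split system as a NEXUS SPLITS block
#'
#' SplitsTree-compatible output: a Taxa block, then a Splits block with
#' the circular ordering as CYCLE and one weighted split per row (the
#' side listed is the one not containing the first cycle element).
#'
#' @param ss a `"split_system"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_nexus_splits <- function(ss, file) {
  n <- length(ss$taxa)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS", "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", n),
    "TAXLABELS",
    sprintf("  [%d] '%s'", seq_len(n), ss$taxa),
    ";", "END;", "",
    "BEGIN Splits;",
    sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(ss$splits)),
    "FORMAT labels=no weights=yes confidences=no intervals=no;",
    sprintf("CYCLE %s;", paste(ss$cycle, collapse = " "))), con)
  writeLines("MATRIX", con)
  for (s in seq_along(ss$splits))
    writeLines(sprintf("  [%d] %g %s,", s, ss$weights[s],
                       paste(sort(ss$splits[[s]]), collapse = " ")), con)
  writeLines(c(";", "END;"), con)
  invisible(file)
}
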