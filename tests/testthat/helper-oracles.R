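# Independent oracles used across the suite.  These deliberately avoid
# the package's own algorithms: likelihoods by exhaustive enumeration
# over interior states, pattern counts by per-site classification,
# distances by path sums on the generating tree.

# Exhaustive Mk likelihood and marginals: sum the joint probability over
# every assignment of states to interior nodes.
enum_mk <- function(phy, x, k, q, prior = rep(1 / k, k)) {
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  tip_state <- x[phy$tip.label] + 1L
  ints <- (n + 1L):m
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(ints))))
  Plist <- lapply(seq_len(nrow(phy$edge)), function(e)
    mk_transition(q, phy$edge.length[e], k))
  node_post <- matrix(0, length(ints), k)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    s <- integer(m)
    s[seq_len(n)] <- tip_state
    s[ints] <- grid[r, ]
    p <- prior[s[n + 1L]]
    for (e in seq_len(nrow(phy$edge))) {
      a <- s[phy$edge[e, 1]]; b <- s[phy$edge[e, 2]]
      if (is.na(b)) next                    # missing tip: marginalized
      p <- p * Plist[[e]][a, b]
    }
    # missing tips: sum over their states
    nas <- which(is.na(s[seq_len(n)]))
    if (length(nas)) {
      for (i in nas) {
        e <- which(phy$edge[, 2] == i)
        p <- p * sum(Plist[[e]][s[phy$edge[e, 1]], ])
      }
    }
    total <- total + p
    node_post[cbind(seq_along(ints), grid[r, ])] <-
      node_post[cbind(seq_along(ints), grid[r, ])] + p
  }
  list(loglik = log(total),
       marginals = node_post / total,
       nodes = ints)
}

# random dated tree via the package-independent route: random topology
# through ape's rtree is avoided; build by random sequential coalescence
rand_dated_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lineages <- as.list(paste0("s", seq_len(n)))
  ages <- rep(0, n)
  t <- 0
  while (length(lineages) > 1) {
    t <- t + runif(1, 0.1, 1)
    pick <- sample.int(length(lineages), 2)
    l1 <- lineages[[pick[1]]]; l2 <- lineages[[pick[2]]]
    a1 <- ages[pick[1]]; a2 <- ages[pick[2]]
    merged <- sprintf("(%s:%.10g,%s:%.10g)", l1, t - a1, l2, t - a2)
    lineages[[pick[1]]] <- merged
    ages[pick[1]] <- t
    lineages <- lineages[-pick[2]]
    ages <- ages[-pick[2]]
  }
  read_dated_tree(text = paste0(lineages[[1]], ";"))
}

# all internal/tip nodes below a node, by direct edge-walking
.descendant_nodes <- function(phy, node) {
  todo <- node; out <- integer(0)
  while (length(todo)) {
    kids <- phy$edge[phy$edge[, 1] == todo[1], 2]
    out <- c(out, kids)
    todo <- c(todo[-1], kids[kids > length(phy$tip.label)])
  }
  out
}

# classify each site of a quartet matrix by direct comparison
site_pattern_oracle <- function(mat) {
  n_abba <- 0L; n_baba <- 0L
  for (j in seq_len(ncol(mat))) {
    s <- mat[, j]
    if (anyNA(s)) next
    anc <- s[4]
    if (s[1] == anc && s[2] != anc && s[3] != anc) n_abba <- n_abba + 1L
    else if (s[1] != anc && s[2] == anc && s[3] != anc) n_baba <- n_baba + 1L
  }
  c(n_abba, n_baba)
}

# path-length distances between tips of a phylo tree
tree_path_distances <- function(phy) {
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

# metric induced by explicit circular split weights, independent of the
# split_system representation: weights indexed by arc (i, j) of the cycle
random_circular_metric <- function(n, seed = NULL, sparsity = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  cycle <- sample.int(n)
  labels <- paste0("c", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  splits <- list()
  weights <- numeric(0)
  for (i in 2:n) {
    for (j in i:n) {
      if (runif(1) > sparsity) next
      w <- runif(1, 0.1, 2)
      side <- cycle[i:j]
      inside <- seq_len(n) %in% side
      sep <- outer(inside, inside, "!=")
      d <- d + w * sep
      splits[[length(splits) + 1]] <- sort(side)
      weights <- c(weights, w)
    }
  }
  list(d = d, cycle = cycle, splits = splits, weights = weights,
       labels = labels)
}

# canonical form of a split (as sorted label string of the smaller side,
# ties broken by lexicographic order) for set comparisons
split_key <- function(side_idx, labels) {
  n <- length(labels)
  a <- sort(labels[side_idx])
  b <- sort(labels[setdiff(seq_len(n), side_idx)])
  if (length(a) < length(b) || (length(a) == length(b) && a[1] < b[1]))
    paste(a, collapse = "|")
  else paste(b, collapse = "|")
}

splits_of_system <- function(ss) {
  vapply(ss$splits, split_key, "", labels = ss$taxa)
}

# all non-trivial bipartitions of a rooted tree's tips (for comparing
# against neighbour-net output)
tree_splits <- function(phy) {
  n <- length(phy$tip.label)
  keys <- character(0)
  for (node in (n + 1):(n + phy$Nnode)) {
    tips <- clade_tips(phy, node)
    if (length(tips) < n)
      keys <- c(keys, split_key(match(tips, phy$tip.label),
                                phy$tip.label))
  }
  for (i in seq_len(n))
    keys <- c(keys, split_key(i, phy$tip.label))
  unique(keys)
}
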