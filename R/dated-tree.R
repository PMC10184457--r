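#' Read and validate a dated rooted tree
#'
#' Reads a rooted tree with branch lengths in millions of years (Ma) from
#' Newick or NEXUS text and validates it as a dated tree: exactly one root,
#' non-negative edge lengths, unique tip labels.  Node ages are measured
#' backwards from the present; the root age equals the maximum root-to-tip
#' path length, so extant tips of an ultrametric tree sit at age 0 and
#' fossil tips at positive ages.
#'
#' @param file path to a Newick or NEXUS file.  Exactly one of `file` and
#'   `text` must be given.
#' @param text a Newick string (or NEXUS TREES block) given directly.
#' @param format `"newick"` or `"nexus"`.
#' @return an object of class `"phylo"` (ape) that has passed
#'   [validate_dated_tree()].
#' @seealso [node_ages()], [write_dated_tree()]
#' @export
read_dated_tree <- function(file = NULL, text = NULL,
                            format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (is.null(file) == is.null(text))
    stop("give exactly one of 'file' or 'text'")
  if (!is.null(text) && format == "newick") .check_newick_syntax(text)
  phy <- if (format == "newick") {
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  } else {
    if (is.null(text)) {
      ape::read.nexus(file)
    } else {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf))
      writeLines(text, tf)
      ape::read.nexus(tf)
    }
  }
  if (inherits(phy, "multiPhylo")) phy <- phy[[1]]
  if (is.null(phy)) stop("no tree could be parsed from input")
  validate_dated_tree(phy)
  phy
}

## cheap syntactic scan so malformed newick reports a character offset,
## which ape's parser does not
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string (length %d)",
                 depth, length(chars)))
  if (!grepl(";", text, fixed = TRUE))
    stop(sprintf("malformed Newick: missing terminal ';' (string length %d)",
                 length(chars)))
  invisible(TRUE)
}

#' Validate a dated tree
#'
#' Checks the invariants every downstream analysis relies on: a single
#' root, branch lengths present and non-negative, unique tip labels, and
#' (optionally) contemporaneous extant tips.
#'
#' @param phy a `"phylo"` object.
#' @param ultrametric if `TRUE`, additionally require all tips at age 0
#'   within `tol` (no fossil tips).
#' @param tol age tolerance in Ma for the ultrametric check.
#' @return `phy`, invisibly; errors describe the first violated invariant.
#' @export
validate_dated_tree <- function(phy, ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("not a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("tree has missing branch lengths")
  if (any(phy$edge.length < 0))
    stop(sprintf("negative branch length (%g) on edge %d",
                 min(phy$edge.length), which.min(phy$edge.length)))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (ultrametric) {
    ages <- node_ages(phy)[seq_along(phy$tip.label)]
    if (any(abs(ages) > tol))
      stop(sprintf("tree is not ultrametric: tip '%s' at age %g",
                   phy$tip.label[which.max(abs(ages))], max(abs(ages))))
  }
  invisible(phy)
}

#' Node ages of a dated tree
#'
#' Ages in Ma before present for every node (tips first, then internal
#' nodes, in ape's numbering).  The root age is the maximum root-to-tip
#' path length, so extant tips of an ultrametric tree have age 0.
#'
#' @param phy a `"phylo"` object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

#' Most recent common ancestor of a set of tips
#'
#' @param phy a `"phylo"` object.
#' @param tips character vector of tip labels (or a single label, in which
#'   case the tip node itself is returned).
#' @return the node number of the MRCA.
#' @export
mrca_node <- function(phy, tips) {
  tips <- unique(as.character(tips))
  miss <- setdiff(tips, phy$tip.label)
  if (length(miss))
    stop("unknown tip label(s): ", paste(miss, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, phy$tip.label))
  ape::getMRCA(phy, tips)
}

#' Tips descending from a node
#' @param phy a `"phylo"` object.
#' @param node an internal node number or tip number.
#' @return character vector of tip labels under `node`.
#' @export
clade_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  phy$tip.label[.descendant_tips(phy, node)]
}

.descendant_tips <- function(phy, node) {
  n <- length(phy$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[[1]]
    todo <- todo[-1]
    kids <- phy$edge[phy$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= n])
    todo <- c(todo, kids[kids > n])
  }
  sort(tips)
}

#' Age interval of the branch subtending a clade
#'
#' Returns the ages of the two nodes incident to the branch below the
#' clade's MRCA: `(age of the MRCA, age of its parent)`.  For the clade of
#' all tips (the root) the upper end is `Inf`.  The clade must be
#' monophyletic; intruding tips are named in the error otherwise.
#'
#' @param phy a `"phylo"` object.
#' @param tips tip labels defining the clade.
#' @param ignore_tips tip labels not counted as intruders in the
#'   monophyly check (e.g. fossil tips already grafted inside the clade).
#' @return numeric vector `c(age_low, age_high)`.
#' @export
branch_age_interval <- function(phy, tips, ignore_tips = character()) {
  node <- mrca_node(phy, tips)
  desc <- clade_tips(phy, node)
  extra <- setdiff(desc, c(tips, ignore_tips))
  if (length(extra))
    stop("clade {", paste(sort(tips), collapse = ","),
         "} is not monophyletic; intruding tips: ",
         paste(extra, collapse = ", "))
  ages <- node_ages(phy)
  root <- length(phy$tip.label) + 1L
  if (node == root) return(c(ages[node], Inf))
  parent <- phy$edge[phy$edge[, 2] == node, 1]
  c(ages[node], ages[parent])
}

#' Write a dated tree
#'
#' Writes Newick or a NEXUS TREES block; optionally a plain-text sidecar
#' table of node ages (`node`, `label`, `age_ma`).
#'
#' @param phy a `"phylo"` object.
#' @param file output path.
#' @param format `"newick"` or `"nexus"`.
#' @param ages_file optional path for the node-age sidecar table.
#' @return `file`, invisibly.
#' @export
write_dated_tree <- function(phy, file, format = c("newick", "nexus"),
                             ages_file = NULL) {
  format <- match.arg(format)
  if (format == "newick") ape::write.tree(phy, file = file)
  else ape::write.nexus(phy, file = file)
  if (!is.null(ages_file)) {
    ages <- node_ages(phy)
    n <- length(phy$tip.label)
    lab <- c(phy$tip.label,
             if (!is.null(phy$node.label)) phy$node.label
             else rep("", phy$Nnode))
    utils::write.table(
      data.frame(node = seq_along(ages), label = lab, age_ma = ages),
      ages_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
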