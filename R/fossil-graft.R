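#' Specify a fossil for tip grafting
#'
#' A fossil taxon to be inserted into a dated tree as a sister lineage of
#' an anchor clade.  The fossil's oldest possible age becomes the age of
#' the new ("shadow") most recent common ancestor placed on the anchor
#' branch; the youngest possible age sets the fossil tip's own age, so
#' the pendant edge has length `oldest - youngest`.
#'
#' @param label fossil taxon label (must not clash with any tip).
#' @param anchor character vector of extant tip labels defining the
#'   branch to break (their MRCA's subtending branch).
#' @param oldest,youngest age range in Ma, `oldest >= youngest >= 0`.
#' @param state scored character state (e.g. a niche category code), or
#'   `NA` if unscorable.
#' @param assignable `FALSE` marks fossils that cannot be associated with
#'   a distinct branch; they are carried through reports but never
#'   grafted ("unconnected stars").
#' @return an object of class `"fossil_spec"`.
#' @export
fossil_spec <- function(label, anchor, oldest, youngest, state = NA,
                        assignable = TRUE) {
  if (youngest < 0 || oldest < youngest)
    stop("need oldest >= youngest >= 0 for fossil ", label)
  structure(list(label = as.character(label),
                 anchor = as.character(anchor),
                 oldest = oldest, youngest = youngest,
                 state = state, assignable = isTRUE(assignable)),
            class = "fossil_spec")
}

#' @export
print.fossil_spec <- function(x, ...) {
  cat(sprintf("fossil %s: [%g, %g] Ma, anchor {%s}%s\n", x$label,
              x$oldest, x$youngest, paste(x$anchor, collapse = ","),
              if (x$assignable) "" else " (not assignable)"))
  invisible(x)
}

#' Graft one fossil tip onto a dated tree
#'
#' Inserts a new internal node (the shadow MRCA, labelled
#' `shadow:<fossil label>`) on the branch subtending the anchor clade at
#' age `spec$oldest`, and attaches the fossil tip with edge length
#' `spec$oldest - spec$youngest`.  All pre-existing node ages, edge
#' lengths and tips are unchanged.  The fossil's oldest age must fall
#' strictly inside the anchor branch's age interval; ages outside it are
#' a hard error (no clamping), since they signal an inconsistent anchor
#' choice.
#'
#' @param phy a `"phylo"` dated tree.
#' @param spec a [fossil_spec()] with `assignable = TRUE`.
#' @param ignore_tips tip labels tolerated inside the anchor clade when
#'   checking monophyly (previously grafted fossils).
#' @return the grafted `"phylo"` tree.
#' @export
graft_fossil <- function(phy, spec, ignore_tips = character()) {
  stopifnot(inherits(spec, "fossil_spec"))
  if (!spec$assignable)
    stop("fossil ", spec$label, " is flagged non-assignable; cannot graft")
  if (spec$label %in% phy$tip.label)
    stop("fossil label '", spec$label, "' already a tip in the tree")
  iv <- branch_age_interval(phy, spec$anchor, ignore_tips)
  if (!(spec$oldest > iv[1] && spec$oldest < iv[2]))
    stop(sprintf(
      "fossil %s: oldest age %g outside the open age interval (%g, %g) of its anchor branch",
      spec$label, spec$oldest, iv[1], iv[2]))
  node <- mrca_node(phy, spec$anchor)
  pendant <- structure(list(
    edge = matrix(c(2L, 1L), 1, 2),
    tip.label = spec$label,
    edge.length = spec$oldest - spec$youngest,
    Nnode = 1L), class = "phylo")
  out <- ape::bind.tree(phy, pendant, where = node,
                        position = spec$oldest - iv[1])
  ## label the newly created shadow node: the parent of the fossil tip
  tip_id <- match(spec$label, out$tip.label)
  shadow <- out$edge[out$edge[, 2] == tip_id, 1]
  n <- length(out$tip.label)
  if (is.null(out$node.label)) out$node.label <- rep("", out$Nnode)
  out$node.label[shadow - n] <- paste0("shadow_", spec$label)
  validate_dated_tree(out)
  out
}

#' Graft a set of fossils
#'
#' Grafts every assignable fossil, inserting fossils that share an anchor
#' branch oldest-first so each breaks the branch segment that still spans
#' its age (a pectinate backbone of successive sisters).  The result is
#' independent of the input list order; ties in (anchor, oldest age) are
#' broken by label order and reported via a message.  Non-assignable
#' fossils are skipped with a message.
#'
#' @param phy a `"phylo"` dated tree.
#' @param specs list of [fossil_spec()] objects.
#' @param quiet suppress per-graft messages.
#' @return the grafted tree, with attribute `"skipped"` listing labels of
#'   non-assignable fossils.
#' @export
graft_all <- function(phy, specs, quiet = TRUE) {
  if (!length(specs)) return(phy)
  labs <- vapply(specs, `[[`, "", "label")
  if (anyDuplicated(labs))
    stop("duplicate fossil labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  assignable <- vapply(specs, `[[`, TRUE, "assignable")
  skipped <- labs[!assignable]
  if (length(skipped) && !quiet)
    message("skipping non-assignable fossil(s): ",
            paste(skipped, collapse = ", "))
  specs <- specs[assignable]
  if (length(specs)) {
    anchor_key <- vapply(specs, function(s)
      paste(sort(s$anchor), collapse = ";"), "")
    oldest <- vapply(specs, `[[`, 0, "oldest")
    labs <- vapply(specs, `[[`, "", "label")
    ord <- order(anchor_key, -oldest, labs)
    ties <- duplicated(paste(anchor_key, oldest))
    if (any(ties) && !quiet)
      message("tie on (anchor, oldest age) broken by label order for: ",
              paste(labs[ties], collapse = ", "))
    done <- character(0)
    for (s in specs[ord]) {
      phy <- graft_fossil(phy, s, ignore_tips = done)
      done <- c(done, s$label)
    }
  }
  attr(phy, "skipped") <- skipped
  phy
}

#' Remove grafted fossil tips (inverse of grafting)
#'
#' Prunes the given fossil tips and suppresses the degree-2 shadow nodes
#' left behind, merging edge lengths, which exactly recovers the
#' pre-graft tree.
#'
#' @param phy a grafted `"phylo"` tree.
#' @param labels fossil tip labels to remove; default: every tip whose
#'   parent node is labelled `shadow:<tip>`.
#' @return the de-grafted tree.
#' @export
degraft <- function(phy, labels = NULL) {
  if (is.null(labels)) {
    n <- length(phy$tip.label)
    parent <- phy$edge[match(seq_len(n), phy$edge[, 2]), 1]
    shadow_lab <- if (is.null(phy$node.label)) rep("", phy$Nnode)
                  else phy$node.label
    labels <- phy$tip.label[shadow_lab[parent - n] ==
                              paste0("shadow_", phy$tip.label)]
  }
  if (!length(labels)) return(phy)
  out <- ape::drop.tip(phy, labels, collapse.singles = TRUE)
  if (!is.null(out$node.label))
    out$node.label[out$node.label == ""] <- ""
  out
}

#' Read fossil specifications from tabular text
#'
#' Expects a tab- or whitespace-separated table with header columns
#' `label`, `anchor` (tip labels joined by `;`), `oldest`, `youngest`,
#' `state`, `assignable`.
#'
#' @param file path to the table.
#' @return list of [fossil_spec()] objects.
#' @export
read_fossil_specs <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    fossil_spec(tab$label[i], strsplit(tab$anchor[i], ";", fixed = TRUE)[[1]],
                tab$oldest[i], tab$youngest[i], tab$state[i],
                as.logical(tab$assignable[i])))
}

#' Write fossil specifications to tabular text
#' @param specs list of [fossil_spec()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_fossil_specs <- function(specs, file) {
  tab <- do.call(rbind, lapply(specs, function(s)
    data.frame(label = s$label,
               anchor = paste(s$anchor, collapse = ";"),
               oldest = s$oldest, youngest = s$youngest,
               state = s$state, assignable = s$assignable,
               stringsAsFactors = FALSE)))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
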