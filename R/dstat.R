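#' Four-taxon locus data for ABBA-BABA tests
#'
#' Bundles per-locus biallelic site data for an ordered quartet
#' (P1, P2, P3, outgroup).  In count mode each site carries one allele
#' per taxon coded 0/1 (the outgroup allele defines the ancestral
#' state); in frequency mode each entry is a derived-allele frequency in
#' `[0, 1]` (already polarized).
#'
#' @param loci list of numeric matrices, one per locus, 4 rows (P1, P2,
#'   P3, O in that order; row names optional but checked when present)
#'   by sites columns; `NA` = missing.
#' @param taxa character vector of the four taxon labels, in
#'   (P1, P2, P3, O) order.
#' @param mode `"count"` (single sampled allele per taxon, default) or
#'   `"frequency"`.
#' @return an object of class `"quartet_data"`.
#' @export
quartet_data <- function(loci, taxa = c("P1", "P2", "P3", "O"),
                         mode = c("count", "frequency")) {
  mode <- match.arg(mode)
  if (!length(loci)) stop("need at least one locus")
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    if (!is.matrix(l) || nrow(l) != 4)
      stop("locus ", i, " is not a 4-row matrix")
    if (mode == "count" && any(!l[!is.na(l)] %in% 0:1))
      stop("locus ", i, ": count mode needs 0/1 alleles")
    if (mode == "frequency" && any(l < 0 | l > 1, na.rm = TRUE))
      stop("locus ", i, ": frequencies outside [0, 1]")
  }
  structure(list(loci = loci, taxa = as.character(taxa), mode = mode),
            class = "quartet_data")
}

#' @export
print.quartet_data <- function(x, ...) {
  cat(sprintf("quartet (((%s,%s),%s),%s): %d loci, %d sites, %s mode\n",
              x$taxa[1], x$taxa[2], x$taxa[3], x$taxa[4], length(x$loci),
              sum(vapply(x$loci, ncol, 0L)), x$mode))
  invisible(x)
}

## per-locus (nABBA, nBABA, n_dropped); sites with any missing taxon are
## dropped; in count mode the outgroup allele defines the ancestral state
.quartet_counts <- function(quartet) {
  t(vapply(quartet$loci, function(l) {
    ok <- colSums(is.na(l)) == 0
    l <- l[, ok, drop = FALSE]
    if (quartet$mode == "count") {
      abba <- l[1, ] == l[4, ] & l[2, ] != l[4, ] & l[3, ] != l[4, ]
      baba <- l[1, ] != l[4, ] & l[2, ] == l[4, ] & l[3, ] != l[4, ]
      c(sum(abba), sum(baba), sum(!ok))
    } else {
      c(sum((1 - l[1, ]) * l[2, ] * l[3, ] * (1 - l[4, ])),
        sum(l[1, ] * (1 - l[2, ]) * l[3, ] * (1 - l[4, ])),
        sum(!ok))
    }
  }, numeric(3)))
}

#' Count ABBA and BABA site patterns
#'
#' ABBA: P1 ancestral, P2 derived, P3 derived, outgroup ancestral;
#' BABA: P1 derived, P2 ancestral, P3 derived, outgroup ancestral.
#' All other patterns are ignored.  Sites with a missing taxon are
#' dropped and counted in the `"n_dropped"` attribute.  In frequency
#' mode the counts are frequency-weighted sums.
#'
#' @param quartet a [quartet_data()].
#' @return named numeric `c(nABBA, nBABA)` with attributes `"n_dropped"`
#'   and `"by_locus"` (the per-locus count matrix).
#' @export
count_patterns <- function(quartet) {
  ct <- .quartet_counts(quartet)
  structure(c(nABBA = sum(ct[, 1]), nBABA = sum(ct[, 2])),
            n_dropped = sum(ct[, 3]),
            by_locus = ct[, 1:2, drop = FALSE])
}

#' Patterson's D from pattern counts
#'
#' `D = (nABBA - nBABA) / (nABBA + nBABA)`; `NA` when there are no
#' informative sites.
#'
#' @param nABBA,nBABA non-negative counts (or frequency-weighted sums).
#' @return D in `[-1, 1]`, or `NA`.
#' @export
d_statistic <- function(nABBA, nBABA) {
  tot <- nABBA + nBABA
  if (tot <= 0) return(NA_real_)
  (nABBA - nBABA) / tot
}

#' D-statistic test with locus bootstrap
#'
#' Computes the observed D and a bootstrap standard score: loci are
#' resampled with replacement `n_boot` times, D recomputed on each
#' replicate, and `Z = |D_obs| / sd(D_boot)`.  A degenerate bootstrap
#' (all replicate Ds identical, sd 0) is reported as `Z = Inf` with the
#' `degenerate` flag set.  Deterministic for a fixed `seed`.
#'
#' @param quartet a [quartet_data()] with at least 2 loci.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed for the resampling, or `NULL` to use the
#'   current RNG state.
#' @param z_crit significance threshold on `|Z|` (ABBA-BABA convention 3).
#' @return an object of class `"dstat"`: `D`, `Z`, `nABBA`, `nBABA`,
#'   `n_loci`, `n_boot`, `sd_boot`, `significant`, `degenerate`,
#'   `n_dropped`.
#' @export
dstat_test <- function(quartet, n_boot = 1000, seed = NULL, z_crit = 3) {
  if (length(quartet$loci) < 2) stop("need >= 2 loci for the bootstrap")
  if (n_boot < 100) stop("need n_boot >= 100")
  ct <- .quartet_counts(quartet)
  nA <- sum(ct[, 1]); nB <- sum(ct[, 2])
  D <- d_statistic(nA, nB)
  if (!is.null(seed)) set.seed(seed)
  nl <- nrow(ct)
  idx <- matrix(sample.int(nl, nl * n_boot, replace = TRUE), nrow = n_boot)
  bA <- matrix(ct[, 1][idx], nrow = n_boot)
  bB <- matrix(ct[, 2][idx], nrow = n_boot)
  sA <- rowSums(bA); sB <- rowSums(bB)
  Db <- ifelse(sA + sB > 0, (sA - sB) / (sA + sB), NA_real_)
  sd_boot <- stats::sd(Db, na.rm = TRUE)
  degenerate <- is.na(sd_boot) || sd_boot == 0
  Z <- if (is.na(D)) NA_real_
       else if (degenerate) Inf
       else abs(D) / sd_boot
  structure(list(D = D, Z = Z, nABBA = nA, nBABA = nB,
                 n_loci = nl, n_boot = n_boot, sd_boot = sd_boot,
                 taxa = quartet$taxa, z_crit = z_crit,
                 significant = !is.na(Z) && Z >= z_crit,
                 degenerate = degenerate,
                 n_dropped = sum(ct[, 3])),
            class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D  (((%s,%s),%s),%s)\n",
              x$taxa[1], x$taxa[2], x$taxa[3], x$taxa[4]))
  cat(sprintf("  nABBA = %g, nBABA = %g over %d loci\n",
              x$nABBA, x$nBABA, x$n_loci))
  cat(sprintf("  D = %.4f, Z = %.2f (%d locus bootstraps)%s\n",
              x$D, x$Z, x$n_boot,
              if (x$degenerate) "  [degenerate bootstrap]" else ""))
  cat(sprintf("  %s at |Z| >= %g\n",
              if (x$significant) "SIGNIFICANT" else "not significant",
              x$z_crit))
  invisible(x)
}

#' Run a battery of D-statistic hypothesis tests
#'
#' Applies [dstat_test()] to a list of named four-taxon configurations
#' drawn from a multi-taxon locus dataset, mirroring hypothesis
#' batteries such as testing putative hybrid origins across several
#' taxon arrangements.
#'
#' @param loci list of per-locus matrices (taxa rows x sites), with taxon
#'   labels as row names.
#' @param tests named list; each element a character vector of four taxon
#'   labels `(P1, P2, P3, O)`.
#' @param n_boot,seed,z_crit passed to [dstat_test()]; each test uses an
#'   independent substream derived from `seed`.
#' @param mode passed to [quartet_data()].
#' @return data frame with one row per test: `test`, `P1`..`O`, `nABBA`,
#'   `nBABA`, `D`, `Z`, `n_loci`, `significant`.
#' @export
dstat_battery <- function(loci, tests, n_boot = 1000, seed = NULL,
                          z_crit = 3, mode = "count") {
  if (!length(tests))
    return(data.frame(test = character(0), P1 = character(0),
                      P2 = character(0), P3 = character(0),
                      O = character(0), nABBA = numeric(0),
                      nBABA = numeric(0), D = numeric(0), Z = numeric(0),
                      n_loci = integer(0), significant = logical(0)))
  taxa_all <- rownames(loci[[1]])
  rows <- lapply(seq_along(tests), function(i) {
    tx <- tests[[i]]
    if (length(tx) != 4) stop("test ", i, " does not name 4 taxa")
    miss <- setdiff(tx, taxa_all)
    if (length(miss))
      stop("test ", names(tests)[i] %||% i, ": unknown taxon ",
           paste(miss, collapse = ", "))
    sub <- lapply(loci, function(l) l[tx, , drop = FALSE])
    res <- dstat_test(quartet_data(sub, taxa = tx, mode = mode),
                      n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + i,
                      z_crit = z_crit)
    data.frame(test = names(tests)[i] %||% paste0("test", i),
               P1 = tx[1], P2 = tx[2], P3 = tx[3], O = tx[4],
               nABBA = res$nABBA, nBABA = res$nBABA, D = res$D,
               Z = res$Z, n_loci = res$n_loci,
               significant = res$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || a == "") b else a
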