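#' Tabular text I/O for pipeline inputs and outputs
#'
#' Plain-text readers and writers for the formats the pipeline consumes
#' and emits: occurrence records (`species`, `lon`, `lat`), Köppen grids
#' (`lon_center`, `lat_center`, `class` with a `# res_arcmin=` header),
#' biome memberships (`species`, `biomes` joined by `;`), Köppen
#' profiles, niche categories, categorical trait matrices (TSV or a
#' NEXUS CHARACTERS block with symbols `0123...` and missing `?`), and
#' per-locus biallelic alignments.
#'
#' @param file path to read or write.
#' @param occ,grid,profiles,m,loci objects to write (see individual
#'   functions).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_occurrences <- function(file) {
  occ <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  occ
}

#' @rdname pipeline_io
#' @export
write_occurrences <- function(occ, file) {
  utils::write.table(occ[, c("species", "lon", "lat")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
write_koppen_grid <- function(grid, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# res_arcmin=%g", grid$res_arcmin), con)
  idx <- expand.grid(ix = seq_len(grid$n_lon), iy = seq_len(grid$n_lat))
  tab <- data.frame(
    lon_center = grid$lon_min + (idx$ix - 0.5) * grid$res_deg,
    lat_center = grid$lat_min + (idx$iy - 0.5) * grid$res_deg,
    class = grid$classes[cbind(idx$ix, idx$iy)])
  utils::write.table(format(tab, digits = 12, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_koppen_grid <- function(file) {
  header <- readLines(file, n = 1)
  res_arcmin <- as.numeric(sub(".*res_arcmin=", "", header))
  if (is.na(res_arcmin)) stop("grid file lacks '# res_arcmin=' header")
  tab <- utils::read.table(file, header = TRUE, sep = "\t", skip = 1,
                           stringsAsFactors = FALSE)
  res <- res_arcmin / 60
  lon_min <- min(tab$lon_center) - res / 2
  lat_min <- min(tab$lat_center) - res / 2
  ix <- as.integer(round((tab$lon_center - lon_min) / res + 0.5))
  iy <- as.integer(round((tab$lat_center - lat_min) / res + 0.5))
  classes <- matrix(NA_character_, max(ix), max(iy))
  classes[cbind(ix, iy)] <- tab$class
  if (anyNA(classes)) stop("grid file does not cover a full rectangle")
  koppen_grid(lon_min, lat_min, max(ix), max(iy), res_arcmin, classes)
}

#' @rdname pipeline_io
#' @export
read_biomes <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(strsplit(tab$biomes, ";", fixed = TRUE), tab$species)
}

#' @rdname pipeline_io
#' @param biomes named list of biome-code vectors.
#' @export
write_biomes <- function(biomes, file) {
  tab <- data.frame(species = names(biomes),
                    biomes = vapply(biomes, paste, "", collapse = ";"))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
write_profiles <- function(profiles, file) {
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(species = p$species, class = names(p$fractions),
               fraction = as.numeric(p$fractions), n_cells = p$n_cells,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_profiles <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  sp <- unique(tab$species)
  out <- lapply(sp, function(s) {
    sub <- tab[tab$species == s, ]
    new_koppen_profile(s, stats::setNames(sub$fraction, sub$class),
                       sub$n_cells[1])
  })
  stats::setNames(out, sp)
}

#' @rdname pipeline_io
#' @export
write_trait_matrix <- function(m, file, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(taxon = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    sym <- paste(sort(unique(as.vector(m[!is.na(m)]))), collapse = "")
    rows <- apply(m, 1, function(r)
      paste(ifelse(is.na(r), "?", r), collapse = ""))
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
      sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=?;", sym),
      "MATRIX",
      sprintf("  %s %s", format(rownames(m)), rows),
      ";", "END;"), con)
  }
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_trait_matrix <- function(file, format = c("tsv", "nexus")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.table(file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE,
                             na.strings = c("NA", "?"))
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    storage.mode(m) <- "integer"
    return(m)
  }
  dat <- ape::read.nexus.data(file)
  m <- do.call(rbind, lapply(dat, function(x) {
    x[x == "?"] <- NA
    as.integer(x)
  }))
  rownames(m) <- names(dat)
  m
}

#' @rdname pipeline_io
#' @export
write_loci <- function(loci, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("locus\ttaxon\talleles", con)
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    al <- apply(l, 1, function(r)
      paste(ifelse(is.na(r), "?", r), collapse = ""))
    writeLines(sprintf("%d\t%s\t%s", i, rownames(l), al), con)
  }
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_loci <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("integer", "character",
                                          "character"))
  lapply(split(tab, tab$locus), function(sub) {
    m <- do.call(rbind, lapply(strsplit(sub$alleles, ""), function(x) {
      x[x == "?"] <- NA
      as.numeric(x)
    }))
    rownames(m) <- sub$taxon
    m
  })
}
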