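## Controlled vocabularies --------------------------------------------------

#' Köppen-Geiger climate classes and biome codes
#'
#' `koppen_classes()` returns the controlled vocabulary of Köppen-Geiger
#' class labels accepted by [koppen_grid()]; `biome_codes()` the five
#' terrestrial biome codes used for niche classification (TSMBF =
#' Tropical & Subtropical Moist Broadleaf Forests, TBMF = Temperate
#' Broadleaf & Mixed Forests, TCF = Temperate Conifer Forests, MFWS =
#' Mediterranean Forests, Woodlands & Scrub, TGSS = Temperate Grasslands,
#' Savannas & Shrublands).
#' @return character vector.
#' @export
koppen_classes <- function() {
  c("Af", "Am", "Aw",
    "BWh", "BWk", "BSh", "BSk",
    "Csa", "Csb", "Csc", "Cwa", "Cwb", "Cwc", "Cfa", "Cfb", "Cfc",
    "Dsa", "Dsb", "Dsc", "Dsd", "Dwa", "Dwb", "Dwc", "Dwd",
    "Dfa", "Dfb", "Dfc", "Dfd",
    "ET", "EF")
}

#' @rdname koppen_classes
#' @export
biome_codes <- function() c("TSMBF", "TBMF", "TCF", "MFWS", "TGSS")

#' Niche category labels
#'
#' The five ordinal niche categories used for ancestral-state
#' reconstruction, coded 0-4: Moist-Subtropical (0, exclusively
#' subtropical moist forest), Meridio-Nemoral (1, subtropical/temperate
#' ecotone), Nemoral (2, temperate broadleaf), Meridional (3,
#' summer-drought tolerating generalists) and Full-Mediterranean (4,
#' summer-drought specialists of winter-mild climates).
#' @return named character vector; names are the codes "0".."4".
#' @export
niche_categories <- function() {
  c("0" = "Moist-Subtropical", "1" = "Meridio-Nemoral", "2" = "Nemoral",
    "3" = "Meridional", "4" = "Full-Mediterranean")
}

## Grid ---------------------------------------------------------------------

#' Construct a Köppen-Geiger climate grid
#'
#' A regular lon/lat grid at a stated arc-minute resolution in which every
#' cell carries exactly one Köppen-Geiger class.  Cells are half-open
#' rectangles `[west, east) x [south, north)`; a point exactly on the
#' global east or north edge joins the last cell, so snapping is total on
#' the covered extent.
#'
#' @param lon_min,lat_min south-west corner of the grid (degrees).
#' @param n_lon,n_lat number of cells along each axis.
#' @param res_arcmin cell size in arc-minutes (> 0); the study grid uses 5.
#' @param classes character matrix (`n_lon` x `n_lat`) or vector (filled
#'   column-major) of Köppen class labels, one per cell.
#' @return an object of class `"koppen_grid"`.
#' @export
koppen_grid <- function(lon_min, lat_min, n_lon, n_lat, res_arcmin,
                        classes) {
  if (res_arcmin <= 0) stop("resolution must be > 0 arc-minutes")
  classes <- matrix(as.character(classes), n_lon, n_lat)
  bad <- setdiff(unique(as.vector(classes)), koppen_classes())
  if (length(bad))
    stop("unknown Köppen class label(s): ", paste(bad, collapse = ", "))
  structure(list(lon_min = lon_min, lat_min = lat_min,
                 n_lon = as.integer(n_lon), n_lat = as.integer(n_lat),
                 res_deg = res_arcmin / 60, res_arcmin = res_arcmin,
                 classes = classes),
            class = "koppen_grid")
}

#' @export
print.koppen_grid <- function(x, ...) {
  cat(sprintf("Köppen-Geiger grid: %d x %d cells at %g arc-min\n",
              x$n_lon, x$n_lat, x$res_arcmin))
  cat(sprintf("  extent: lon [%g, %g), lat [%g, %g)\n",
              x$lon_min, x$lon_min + x$n_lon * x$res_deg,
              x$lat_min, x$lat_min + x$n_lat * x$res_deg))
  tab <- sort(table(x$classes), decreasing = TRUE)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab),
                          collapse = ", "), "\n")
  invisible(x)
}

.grid_index <- function(coord, origin, res, n) {
  i <- floor((coord - origin) / res) + 1
  ## half-open cells; the global east/north edge belongs to the last cell
  at_edge <- abs(coord - (origin + n * res)) < 1e-12
  i[at_edge] <- n
  as.integer(i)
}

#' Snap occurrence records to grid cells
#'
#' Maps every occurrence record to the grid cell containing it and
#' collapses duplicates, giving the set of unique occupied cells per
#' species ("grid-weighted": a cell counts once no matter how many
#' records fall in it).  Records outside the grid extent are dropped with
#' a warning; the number dropped is attached as attribute `"n_dropped"`.
#'
#' @param occ data frame with columns `species`, `lon`, `lat` (degrees;
#'   lon in `[-180, 180)`, lat in `[-90, 90]`).
#' @param grid a [koppen_grid()].
#' @return data frame with one row per occupied (species, cell) pair:
#'   columns `species`, `ix`, `iy`, `lon`, `lat` (cell centres), `class`.
#' @export
snap_to_cells <- function(occ, grid) {
  stopifnot(all(c("species", "lon", "lat") %in% names(occ)))
  if (any(occ$lon < -180 | occ$lon >= 180 | occ$lat < -90 | occ$lat > 90))
    stop("coordinates outside valid lon/lat ranges")
  ix <- .grid_index(occ$lon, grid$lon_min, grid$res_deg, grid$n_lon)
  iy <- .grid_index(occ$lat, grid$lat_min, grid$res_deg, grid$n_lat)
  inside <- ix >= 1 & ix <= grid$n_lon & iy >= 1 & iy <= grid$n_lat
  n_dropped <- sum(!inside)
  if (n_dropped > 0)
    warning(sprintf("%d occurrence record(s) outside grid coverage dropped",
                    n_dropped))
  key <- paste(occ$species[inside], ix[inside], iy[inside])
  keep <- which(inside)[!duplicated(key)]
  out <- data.frame(
    species = as.character(occ$species[keep]),
    ix = ix[keep], iy = iy[keep],
    lon = grid$lon_min + (ix[keep] - 0.5) * grid$res_deg,
    lat = grid$lat_min + (iy[keep] - 0.5) * grid$res_deg,
    class = grid$classes[cbind(ix[keep], iy[keep])],
    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$ix, out$iy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

## Profiles -----------------------------------------------------------------

#' Köppen profile of a species
#'
#' The grid-weighted "Köppen signature": for each climate class, the
#' fraction of the species' occupied grid cells in that class.  Fractions
#' sum to 1.
#'
#' @param cells output of [snap_to_cells()] (may contain several species).
#' @param species species to profile; default all present in `cells`.
#' @return a named list of `"koppen_profile"` objects, one per species;
#'   each holds `species`, `fractions` (named, descending) and `n_cells`.
#' @export
koppen_profile <- function(cells, species = NULL) {
  if (is.null(species)) species <- sort(unique(cells$species))
  out <- lapply(species, function(sp) {
    cl <- cells$class[cells$species == sp]
    if (!length(cl)) stop("empty range: no occupied cells for ", sp)
    tab <- table(cl)
    fr <- sort(as.numeric(tab) / sum(tab), decreasing = TRUE)
    names(fr) <- names(tab)[order(as.numeric(tab), decreasing = TRUE)]
    new_koppen_profile(sp, fr, sum(tab))
  })
  names(out) <- species
  out
}

#' Construct a Köppen profile directly from class fractions
#' @param species species id.
#' @param fractions named numeric vector of class fractions (will be
#'   normalized; must be non-negative, at least one positive).
#' @param n_cells number of occupied grid cells behind the profile.
#' @return a `"koppen_profile"`.
#' @export
new_koppen_profile <- function(species, fractions, n_cells = NA_integer_) {
  if (any(fractions < 0) || sum(fractions) <= 0)
    stop("fractions must be non-negative with positive sum")
  bad <- setdiff(names(fractions), koppen_classes())
  if (length(bad))
    stop("unknown Köppen class label(s): ", paste(bad, collapse = ", "))
  fr <- fractions / sum(fractions)
  fr <- fr[order(-fr, names(fr))]
  structure(list(species = species, fractions = fr,
                 n_cells = as.integer(n_cells)),
            class = "koppen_profile")
}

#' @export
print.koppen_profile <- function(x, ...) {
  cat(sprintf("Köppen profile: %s (%s cells)\n", x$species,
              ifelse(is.na(x$n_cells), "?", x$n_cells)))
  cat(paste(sprintf("  %-4s %6.1f%%", names(x$fractions),
                    100 * x$fractions), collapse = "\n"), "\n")
  invisible(x)
}

#' Representative climate types of a profile
#'
#' Classes covering at least `threshold` of the occupied cells, ordered by
#' descending fraction; the first element is the dominant class.  The
#' comparison is inclusive (a class at exactly the threshold is kept).
#'
#' @param profile a `"koppen_profile"`.
#' @param threshold minimum fraction, default 0.10.
#' @return character vector of class labels (never empty: the dominant
#'   class always qualifies).
#' @export
representative_types <- function(profile, threshold = 0.10) {
  fr <- profile$fractions
  keep <- fr >= threshold
  if (!any(keep)) keep[1] <- TRUE
  names(fr)[keep]
}

## Niche classification -----------------------------------------------------

#' Classification thresholds for niche binning
#'
#' Tunable knobs of the rule cascade in [classify_niche()]:
#' `summer_dry` is the minimum summed fraction of summer-dry classes
#' (`Cs*`/`Ds*`) that marks a drought-affected niche, and `cold_dry` the
#' minimum summed fraction of winter-cold summer-dry classes (`Ds*`,
#' `BSk`) that marks continental summer-drought.  Both default to 0.10,
#' matching the 10 % representativeness cut-off used throughout.
#' @param summer_dry,cold_dry fractions in (0, 1).
#' @return a named list.
#' @export
niche_config <- function(summer_dry = 0.10, cold_dry = 0.10) {
  stopifnot(summer_dry > 0, summer_dry < 1, cold_dry > 0, cold_dry < 1)
  list(summer_dry = summer_dry, cold_dry = cold_dry)
}

.summer_dry_fraction <- function(profile) {
  sum(profile$fractions[grepl("^(Cs|Ds)", names(profile$fractions))])
}

.cold_dry_fraction <- function(profile) {
  sum(profile$fractions[grepl("^Ds", names(profile$fractions)) |
                          names(profile$fractions) == "BSk"])
}

#' Bin a species into one of five niche categories
#'
#' Deterministic rule cascade mapping a Köppen profile plus biome
#' membership to an ordinal niche category 0-4 (see
#' [niche_categories()]).  Rules are evaluated in order; the first match
#' wins and rule 4 (Full-Mediterranean) is the residual:
#'
#' 0. biomes within \{TSMBF, TBMF\} with TSMBF present, summer-dry
#'    fraction below threshold, dominant class Cfa or Cwa;
#' 1. TSMBF and TBMF both present, summer-dry below threshold;
#' 2. biomes within \{TBMF, TCF, TSMBF\}, summer-dry below threshold;
#' 3. summer-dry at/above threshold with a temperate biome (TBMF, TGSS or
#'    TCF) present and a non-Csa dominant class, OR winter-cold summer-dry
#'    classes (Ds*, BSk) at/above threshold;
#' 4. otherwise (MFWS-dominated, Csa/Csb-dominant, summer-dry, mild
#'    winters).
#'
#' @param profile a `"koppen_profile"`.
#' @param biomes character vector of biome codes (subset of
#'   [biome_codes()]), non-empty.
#' @param config thresholds from [niche_config()].
#' @return integer category code 0-4 with the label as attribute
#'   `"label"`.
#' @export
classify_niche <- function(profile, biomes, config = niche_config()) {
  if (!length(biomes)) stop("biome set is empty for ", profile$species)
  bad <- setdiff(biomes, biome_codes())
  if (length(bad)) stop("unknown biome code(s): ", paste(bad, collapse = ", "))
  sdry <- .summer_dry_fraction(profile)
  cdry <- .cold_dry_fraction(profile)
  dominant <- names(profile$fractions)[1]
  code <-
    if (all(biomes %in% c("TSMBF", "TBMF")) && "TSMBF" %in% biomes &&
        sdry < config$summer_dry && dominant %in% c("Cfa", "Cwa")) 0L
    else if ("TSMBF" %in% biomes && "TBMF" %in% biomes &&
             sdry < config$summer_dry) 1L
    else if (all(biomes %in% c("TBMF", "TCF", "TSMBF")) &&
             sdry < config$summer_dry) 2L
    else if ((sdry >= config$summer_dry &&
              any(biomes %in% c("TBMF", "TGSS", "TCF")) &&
              dominant != "Csa") ||
             cdry >= config$cold_dry) 3L
    else 4L
  structure(code, label = unname(niche_categories()[as.character(code)]))
}

#' Classify many species at once
#'
#' @param profiles named list of profiles (as from [koppen_profile()]).
#' @param biomes named list mapping species to biome-code vectors.
#' @param config thresholds from [niche_config()].
#' @return data frame with `species`, `category` (integer 0-4), `label`,
#'   `dominant`, `summer_dry` columns.
#' @export
classify_niches <- function(profiles, biomes, config = niche_config()) {
  sp <- names(profiles)
  miss <- setdiff(sp, names(biomes))
  if (length(miss))
    stop("no biome membership for: ", paste(miss, collapse = ", "))
  rows <- lapply(sp, function(s) {
    code <- classify_niche(profiles[[s]], biomes[[s]], config)
    data.frame(species = s, category = as.integer(code),
               label = attr(code, "label"),
               dominant = names(profiles[[s]]$fractions)[1],
               summer_dry = .summer_dry_fraction(profiles[[s]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
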