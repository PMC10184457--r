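toy_grid <- function(n_lon = 10, n_lat = 10, classes = NULL) {
  if (is.null(classes))
    classes <- matrix(rep(c("Csa", "Cfb"), each = n_lon / 2), n_lon, n_lat)
  koppen_grid(0, 0, n_lon, n_lat, 60, classes)  # 1-degree cells
}

test_that("records in one cell collapse to a single occupied cell", {
  g <- toy_grid()
  occ <- data.frame(species = "sp", lon = runif(5, 3.1, 3.9),
                    lat = runif(5, 4.1, 4.9))
  cells <- snap_to_cells(occ, g)
  expect_equal(nrow(cells), 1L)
  expect_equal(cells$ix, 4L)
  expect_equal(cells$iy, 5L)
})

test_that("cell boundaries follow the half-open convention", {
  g <- toy_grid()
  occ <- data.frame(species = c("a", "a", "a"),
                    lon = c(3, 0, 10), lat = c(4, 0, 10))
  cells <- snap_to_cells(occ, g)
  # (3,4) starts cell (4,5); origin starts cell (1,1); the global
  # east/north corner joins the last cell
  expect_equal(cells[, c("ix", "iy")],
               data.frame(ix = c(1L, 4L, 10L), iy = c(1L, 5L, 10L)))
})

test_that("records outside coverage are dropped with a warning", {
  g <- toy_grid()
  occ <- data.frame(species = "a", lon = c(5, 55), lat = c(5, 5))
  expect_warning(cells <- snap_to_cells(occ, g), "1 occurrence")
  expect_equal(nrow(cells), 1L)
  expect_equal(attr(cells, "n_dropped"), 1L)
})

test_that("snapping equals brute-force point-in-rectangle assignment", {
  g <- toy_grid()
  set.seed(10)
  occ <- data.frame(species = "sp", lon = runif(1000, 0, 10),
                    lat = runif(1000, 0, 10))
  cells <- snap_to_cells(occ, g)
  expected <- unique(data.frame(
    ix = vapply(occ$lon, function(p)
      which(p >= 0:9 & p < 1:10), 0L),
    iy = vapply(occ$lat, function(p)
      which(p >= 0:9 & p < 1:10), 0L)))
  got <- cells[, c("ix", "iy")]
  expect_setequal(paste(got$ix, got$iy),
                  paste(expected$ix, expected$iy))
})

test_that("profiles are cell-count fractions that sum to one", {
  g <- toy_grid()
  # 6 cells in Csa strip, 3+1 in Cfb strip
  occ <- data.frame(
    species = "sp",
    lon = c(0.5, 1.5, 2.5, 3.5, 0.5, 1.5, 5.5, 6.5, 7.5, 8.5) ,
    lat = c(rep(0.5, 4), rep(1.5, 2), rep(0.5, 3), 3.5))
  pr <- koppen_profile(snap_to_cells(occ, g))[["sp"]]
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(pr$fractions["Csa"]), 0.6)
  expect_equal(unname(pr$fractions["Cfb"]), 0.4)
  expect_equal(pr$n_cells, 10L)
})

test_that("profiles are invariant to duplication and permutation", {
  g <- toy_grid()
  set.seed(2)
  occ <- data.frame(species = "sp", lon = runif(200, 0, 10),
                    lat = runif(200, 0, 10))
  p0 <- koppen_profile(snap_to_cells(occ, g))[["sp"]]
  occ_dup <- rbind(occ, occ[sample(200, 50), ])
  occ_dup <- occ_dup[sample(nrow(occ_dup)), ]
  p1 <- koppen_profile(snap_to_cells(occ_dup, g))[["sp"]]
  expect_equal(p0$fractions, p1$fractions)
  expect_equal(p0$n_cells, p1$n_cells)
})

test_that("profile equals a counting oracle on simulated worlds", {
  for (s in 1:10) {
    w <- sim_koppen_world(list(list(species = "sp",
                                    weights = c(Csa = 0.6, Cfb = 0.4),
                                    biomes = "MFWS", n_records = 500)),
                          seed = s)
    cells <- snap_to_cells(w$occurrences, w$grid)
    pr <- koppen_profile(cells)[["sp"]]
    tab <- table(cells$class)
    expect_equal(pr$fractions[names(tab)],
                 as.numeric(tab) / sum(tab), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(pr$fractions), 1, tolerance = 1e-12)
  }
})

test_that("representative types keep classes at or above the threshold", {
  p <- new_koppen_profile("x", c(Csa = 0.6, Cfb = 0.3, BSk = 0.1))
  expect_equal(representative_types(p), c("Csa", "Cfb", "BSk"))
  p2 <- new_koppen_profile("y", c(Cfa = 0.95, Dwa = 0.05))
  expect_equal(representative_types(p2), "Cfa")
  p3 <- new_koppen_profile("z", c(Cfa = 1))
  expect_equal(representative_types(p3), "Cfa")
})

test_that("anchor species reproduce their documented niche categories", {
  chenii <- new_koppen_profile("Q_chenii", c(Cfa = 1))
  expect_equal(as.integer(classify_niche(chenii, c("TBMF", "TSMBF"))), 0L)
  crenata <- new_koppen_profile("Q_crenata",
                                c(Cfb = 0.6, Cfa = 0.31, Csa = 0.05,
                                  Csb = 0.04))
  expect_equal(as.integer(classify_niche(crenata, "TBMF")), 2L)
  cast <- new_koppen_profile("Q_castaneifolia",
                             c(Csa = 0.5, Csb = 0.2, Dsa = 0.18,
                               Cfa = 0.12))
  expect_equal(as.integer(classify_niche(cast, "TBMF")), 3L)
  suber <- new_koppen_profile("Q_suber",
                              c(Csa = 0.6, Csb = 0.3, Cfb = 0.07,
                                BSk = 0.03))
  expect_equal(as.integer(classify_niche(suber, "MFWS")), 4L)
})

test_that("classification is total and stable away from thresholds", {
  set.seed(1)
  biome_pool <- biome_codes()
  for (i in 1:100) {
    cls <- sample(koppen_classes(), sample(2:5, 1))
    fr <- runif(length(cls)); fr <- fr / sum(fr)
    p <- new_koppen_profile("x", setNames(fr, cls))
    bio <- sample(biome_pool, sample(1:3, 1))
    code <- classify_niche(p, bio)
    expect_true(as.integer(code) %in% 0:4)
    # tiny perturbation away from any rule threshold must not change it
    fr2 <- fr + runif(length(fr), -1e-12, 1e-12)
    p2 <- new_koppen_profile("x", setNames(fr2 / sum(fr2), cls))
    expect_equal(as.integer(classify_niche(p2, bio)), as.integer(code))
  }
  expect_error(classify_niche(new_koppen_profile("x", c(Cfa = 1)),
                              character(0)), "empty")
})

test_that("empty ranges and unknown labels are rejected", {
  g <- toy_grid()
  cells <- snap_to_cells(data.frame(species = "a", lon = 1, lat = 1), g)
  expect_error(koppen_profile(cells, species = "missing"), "empty range")
  expect_error(new_koppen_profile("x", c(XXX = 1)), "unknown")
  expect_error(koppen_grid(0, 0, 2, 2, 5, matrix("Qqq", 2, 2)), "unknown")
  expect_error(koppen_grid(0, 0, 2, 2, -5, matrix("Csa", 2, 2)),
               "resolution")
})
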