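test_that("generators are pure functions of their seed", {
  t1 <- sim_dated_tree(10, seed = 5)
  t2 <- sim_dated_tree(10, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  x1 <- sim_mk_characters(t1, 3, 0.2, 20, seed = 6)
  x2 <- sim_mk_characters(t1, 3, 0.2, 20, seed = 6)
  expect_identical(x1, x2)
  w1 <- sim_koppen_world(cerris_species(), seed = 7)
  w2 <- sim_koppen_world(cerris_species(), seed = 7)
  expect_identical(w1$occurrences, w2$occurrences)
  q1 <- sim_quartet_sites(n_loci = 10, seed = 8)
  q2 <- sim_quartet_sites(n_loci = 10, seed = 8)
  expect_identical(q1$loci, q2$loci)
  f1 <- sim_fossils(t1, 4, seed = 9)
  f2 <- sim_fossils(t1, 4, seed = 9)
  expect_identical(f1, f2)
})

test_that("birth-death trees honour tip count and ultrametry", {
  tr <- sim_dated_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  expect_gt(max(node_ages(tr)), 0)
  for (s in 1:10) {
    tr <- sim_dated_tree(sample(3:25, 1), mu = 0.3, seed = s)
    expect_silent(validate_dated_tree(tr, ultrametric = TRUE))
  }
  expect_error(sim_dated_tree(1), "n_tips")
})

test_that("pure-birth root ages match the independent waiting-time sum", {
  # the stopping rule makes the root age a sum of Exp(i * lambda)
  # waiting times for i = 2..n; compare against direct draws
  n <- 10; lambda <- 1; reps <- 400
  set.seed(123)
  ages <- vapply(seq_len(reps), function(i)
    max(node_ages(sim_dated_tree(n, lambda))), 0)
  oracle <- vapply(seq_len(reps), function(i)
    sum(rexp(n - 1, lambda * (2:n))), 0)
  expect_equal(mean(ages), mean(oracle),
               tolerance = 4 * sd(oracle) / sqrt(reps) / mean(oracle))
  expect_gt(stats::ks.test(ages, oracle)$p.value, 0.001)
})

test_that("mk character simulation hits its limits and distribution", {
  tr <- sim_dated_tree(12, seed = 3)
  x0 <- sim_mk_characters(tr, 4, 0, 10, seed = 4)
  expect_true(all(apply(x0, 2, function(col) length(unique(col)) == 1)))
  # long-branch star tree: tip states uniform over k
  star <- read_dated_tree(
    text = paste0("(", paste(sprintf("s%d:50", 1:8), collapse = ","), ");"))
  xs <- sim_mk_characters(star, 5, 1, 400, seed = 5)
  tab <- table(factor(as.vector(xs), levels = 0:4))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("simulated characters recover the generating rate", {
  tr <- sim_dated_tree(20, seed = 41)
  tr$edge.length <- tr$edge.length * 10 / max(node_ages(tr))
  x <- sim_mk_characters(tr, 2, 0.15, 500, seed = 42)
  q_hat <- as.numeric(ml_rate(tr, x, 2))
  expect_lt(abs(q_hat - 0.15) / 0.15, 0.25)
})

test_that("the mosaic world reproduces configured class shares", {
  sp <- list(list(species = "one", weights = c(Cfa = 1), biomes = "TBMF",
                  n_records = 200),
             list(species = "mix", weights = c(Csa = 0.6, Cfb = 0.4),
                  biomes = "MFWS", n_records = 10000))
  w <- sim_koppen_world(sp, seed = 17)
  pr <- koppen_profile(snap_to_cells(w$occurrences, w$grid))
  expect_equal(unname(pr$one$fractions["Cfa"]), 1)
  expect_equal(unname(pr$mix$fractions["Csa"]), 0.6, tolerance = 0.05)
  expect_equal(unname(pr$mix$fractions["Cfb"]), 0.4, tolerance = 0.05)
})

test_that("quartet site patterns match multinomial expectations", {
  # mean D over 200 replicates of 5000 sites at (0.06, 0.02):
  # E[D] = (0.06 - 0.02) / 0.08 = 0.5
  ds <- vapply(1:200, function(r) {
    ct <- count_patterns(sim_quartet_sites(n_loci = 20,
                                           sites_per_locus = 250,
                                           p_abba = 0.06, p_baba = 0.02,
                                           seed = 1900 + r))
    as.numeric(d_statistic(ct[1], ct[2]))
  }, 0)
  expect_equal(mean(ds), 0.5, tolerance = 0.02 / 0.5)
  # aggregated counts follow the configured multinomial
  qd <- sim_quartet_sites(n_loci = 100, sites_per_locus = 200,
                          p_abba = 0.06, p_baba = 0.02, seed = 20)
  ct <- count_patterns(qd)
  obs <- c(ct[1], ct[2], 100 * 200 - sum(ct))
  expect_gt(stats::chisq.test(obs, p = c(0.06, 0.02, 0.92))$p.value, 0.01)
  # gamma parameterization reproduces the same probabilities
  qg <- sim_quartet_sites(n_loci = 100, sites_per_locus = 200,
                          gamma = 0.3, seed = 20)
  expect_identical(qg$loci, qd$loci)
  expect_error(sim_quartet_sites(p_abba = 0.9, p_baba = 0.2), "invalid")
})

test_that("generated fossils always satisfy the graft preconditions", {
  for (s in 1:10) {
    tr <- sim_dated_tree(10, seed = s + 100)
    specs <- sim_fossils(tr, 8, seed = s)
    g <- tr
    done <- character(0)
    for (f in specs[order(-vapply(specs, `[[`, 0, "oldest"))]) {
      expect_silent(g2 <- graft_fossil(g, f, ignore_tips = done))
      g <- g2; done <- c(done, f$label)
    }
  }
  expect_equal(sim_fossils(sim_dated_tree(5, seed = 1), 0), list())
})

test_that("fossil oldest ages are uniform within their branch interval", {
  tr <- read_dated_tree(text = "((A:10,B:10):10,C:20);")
  set.seed(31)
  draws <- replicate(4000, {
    f <- sim_fossils(tr, 1)[[1]]
    if (setequal(f$anchor, c("A", "B"))) f$oldest else NA_real_
  })
  draws <- draws[!is.na(draws)]
  # anchor {A,B} has age interval (10, 20)
  expect_gt(stats::ks.test(draws, "punif", 10, 20)$p.value, 0.01)
})
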