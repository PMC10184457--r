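test_that("hamming distances follow the shared-scored definition", {
  m <- rbind(a = c(0, 1, NA, 2),
             b = c(0, 0, 1, 2),
             c = c(0, 1, NA, 2))
  d <- hamming_distance(m)
  expect_equal(d["a", "b"], 1 / 3)   # shared 3, differing 1
  expect_equal(d["a", "c"], 0)       # identical where scored
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  m2 <- rbind(a = rep(0, 12), b = rep(1, 12), c = rep(0, 12))
  expect_equal(hamming_distance(m2)["a", "b"], 1)
  m3 <- rbind(a = c(0, NA), b = c(NA, 1), c = c(0, 1))
  expect_error(hamming_distance(m3), "share no scored character")
})

test_that("three taxa decompose into exact trivial splits", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ss <- neighbor_net(d)
  w <- setNames(ss$weights, splits_of_system(ss))
  expect_equal(w[["A"]], 0.5)
  expect_equal(w[["B"]], 1.5)
  expect_equal(w[["C"]], 2.5)
  expect_equal(split_distances(ss), d, tolerance = 1e-9)
})

test_that("an additive tree metric yields exactly the tree splits", {
  phy <- read_dated_tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  d <- tree_path_distances(phy)
  ss <- neighbor_net(d)
  w <- setNames(ss$weights, splits_of_system(ss))
  expect_equal(sort(names(w)), sort(c("A", "B", "C", "D", "A|B")))
  expect_equal(w[["A"]], 1); expect_equal(w[["B"]], 2)
  expect_equal(w[["C"]], 3); expect_equal(w[["D"]], 4)
  expect_equal(w[["A|B"]], 2)  # internal path A,B vs C,D
  expect_lt(max(abs(split_distances(ss) - d)), 1e-6)
})

test_that("degenerate and invalid inputs are handled", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ss <- neighbor_net(z)
  expect_length(ss$splits, 0)
  expect_equal(split_distances(ss), z)
  bad <- z; bad[1, 2] <- 1
  expect_error(neighbor_net(bad), "symmetric")
  neg <- z; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_net(neg), "negative")
  expect_error(neighbor_net(z[1:2, 1:2]), ">= 3")
})

test_that("tree metrics round-trip through the split system", {
  set.seed(55)
  for (i in 1:30) {
    phy <- rand_dated_tree(sample(4:8, 1))
    # perturb to non-ultrametric additive by stretching edges
    phy$edge.length <- phy$edge.length * runif(length(phy$edge.length),
                                               0.5, 2)
    d <- tree_path_distances(phy)
    ss <- neighbor_net(d)
    expect_lt(max(abs(split_distances(ss) - d[ss$taxa, ss$taxa])), 1e-6)
    expect_true(all(tree_splits(phy) %in% splits_of_system(ss)))
  }
})

test_that("known circular split systems are recovered", {
  set.seed(66)
  for (i in 1:20) {
    gen <- random_circular_metric(sample(5:9, 1))
    ss <- neighbor_net(gen$d)
    expect_lt(max(abs(split_distances(ss) - gen$d)), 1e-6)
    got <- setNames(ss$weights, splits_of_system(ss))
    want_keys <- vapply(gen$splits, split_key, "", labels = gen$labels)
    # aggregate duplicate generator splits
    want <- tapply(gen$weights, want_keys, sum)
    for (kk in names(want))
      expect_equal(unname(got[[kk]]), unname(want[[kk]]),
                   tolerance = 1e-6)
  }
})

test_that("the ordering is invariant under taxon relabelling", {
  set.seed(8)
  gen <- random_circular_metric(7)
  ss1 <- neighbor_net(gen$d)
  perm <- sample(7)
  d2 <- gen$d[perm, perm]
  ss2 <- neighbor_net(d2)
  lab1 <- ss1$taxa[ss1$cycle]
  lab2 <- ss2$taxa[ss2$cycle]
  # same circular order up to rotation/reflection
  rotations <- lapply(seq_along(lab2), function(r)
    c(lab2[r:length(lab2)], lab2[seq_len(r - 1)]))
  rotations <- c(rotations, lapply(rotations, rev))
  expect_true(any(vapply(rotations, identical, TRUE, y = lab1)))
  expect_equal(sort(splits_of_system(ss1)), sort(splits_of_system(ss2)))
})

test_that("a single split induces a two-block metric", {
  ss <- structure(list(taxa = c("A", "B", "C", "D"), cycle = 1:4,
                       splits = list(c(1L, 2L)), weights = 1,
                       rss = 0), class = "split_system")
  d <- split_distances(ss)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 1)
  expect_equal(d["C", "D"], 0)
})

test_that("nexus splits output is SplitsTree-shaped", {
  gen <- random_circular_metric(5, seed = 2)
  ss <- neighbor_net(gen$d)
  f <- tempfile(fileext = ".nex")
  write_nexus_splits(ss, f)
  txt <- readLines(f)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_true(any(grepl(sprintf("nsplits=%d", length(ss$splits)), txt)))
  expect_true(any(grepl("^CYCLE", txt)))
  unlink(f)
})

test_that("the demo leaf-trait matrix produces a valid morphospace", {
  tree <- ape::drop.tip(cerris_demo_tree(), "Q_ilex")
  traits <- cbind(sim_mk_characters(tree, 2, 0.02, 11, seed = 3),
                  sim_mk_characters(tree, 3, 0.02, 1, seed = 4))
  d <- hamming_distance(traits)
  expect_true(all(d >= 0 & d <= 1))
  ss <- neighbor_net(d)
  expect_equal(sort(ss$taxa[ss$cycle]), sort(rownames(traits)))
  expect_true(all(ss$weights > 0))
})
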