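test_that("mk transition matrix has its closed-form limits", {
  expect_equal(mk_transition(0.7, 0, 4), diag(4))
  expect_equal(mk_transition(5, 1e6, 3), matrix(1 / 3, 3, 3))
  P <- mk_transition(1, 0.5, 2)
  expect_equal(P[1, 1], 0.6839397, tolerance = 1e-7)
  expect_equal(P[1, 2], 0.3160603, tolerance = 1e-7)
  expect_equal(rowSums(mk_transition(0.3, 2.7, 5)), rep(1, 5))
  expect_error(mk_transition(1, -1, 2), "negative")
})

test_that("mk transition agrees with the numerical matrix exponential", {
  for (k in c(2, 3, 5)) {
    for (q in c(0.01, 0.3, 2)) {
      for (t in c(0, 0.1, 1, 10)) {
        Q <- matrix(q, k, k); diag(Q) <- -(k - 1) * q
        expect_lt(max(abs(mk_transition(q, t, k) - ape::matexpo(Q * t))),
                  1e-10)
      }
    }
  }
})

test_that("pruning likelihood has the forced small-tree values", {
  phy <- read_dated_tree(text = "(A:0.5,B:0.5);")
  # q -> 0: identity transport, likelihood = prior mass on the shared state
  expect_equal(exp(as.numeric(prune_loglik(phy, c(A = 0, B = 0), 2, 1e-12))),
               0.5, tolerance = 1e-9)
  # impossible under zero rate
  expect_lt(exp(as.numeric(prune_loglik(phy, c(A = 0, B = 1), 2, 1e-12))),
            1e-10)
  # k=2, q=1: 0.5 * (P00^2 + P01^2)
  expect_equal(exp(as.numeric(prune_loglik(phy, c(A = 0, B = 0), 2, 1))),
               0.28383382, tolerance = 1e-7)
  expect_error(prune_loglik(phy, c(A = 0, B = 3), 2, 1), "state index")
})

test_that("pruning equals enumeration over interior states", {
  set.seed(11)
  for (i in 1:40) {
    k <- sample(c(2, 3, 5), 1)
    phy <- rand_dated_tree(sample(3:6, 1))
    x <- setNames(sample(0:(k - 1), length(phy$tip.label), replace = TRUE),
                  phy$tip.label)
    if (runif(1) < 0.3) x[sample(length(x), 1)] <- NA  # missing tip
    if (all(is.na(x))) x[1] <- 0
    q <- runif(1, 0.05, 2)
    oracle <- enum_mk(phy, x, k, q)
    expect_equal(as.numeric(prune_loglik(phy, x, k, q)), oracle$loglik,
                 tolerance = 1e-9)
    m <- marginal_asr(phy, x, k, q)
    expect_lt(max(abs(m - oracle$marginals)), 1e-9)
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-9)
    # likelihood recoverable from every node's up/down decomposition
    expect_lt(max(abs(attr(m, "node_logLik") - oracle$loglik)), 1e-9)
  }
})

test_that("likelihood is invariant under joint state relabelling", {
  set.seed(5)
  phy <- rand_dated_tree(8)
  k <- 4
  x <- setNames(sample(0:(k - 1), 8, replace = TRUE), phy$tip.label)
  q <- 0.4
  ll <- as.numeric(prune_loglik(phy, x, k, q))
  for (i in 1:5) {
    perm <- sample(0:(k - 1))
    expect_equal(as.numeric(prune_loglik(phy, setNames(perm[x + 1],
                                                       names(x)), k, q)),
                 ll, tolerance = 1e-12)
  }
})

test_that("pruning handles polytomies exactly", {
  phy <- read_dated_tree(text = "(A:1,B:1,C:1,D:1);")  # star, one node
  x <- c(A = 0, B = 0, C = 1, D = 1)
  q <- 0.3; k <- 2
  P <- mk_transition(q, 1, k)
  manual <- 0.5 * (P[1, 1]^2 * P[1, 2]^2 + P[2, 1]^2 * P[2, 2]^2)
  expect_equal(exp(as.numeric(prune_loglik(phy, x, k, q))), manual,
               tolerance = 1e-12)
})

test_that("marginals hit their symmetry and limit cases", {
  phy <- read_dated_tree(text = "(A:1,B:1);")
  m <- marginal_asr(phy, c(A = 0, B = 1), 2, 0.5)
  expect_equal(unname(m[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  # q -> 0 with constant data: indicator of the shared state
  phy2 <- rand_dated_tree(5, seed = 2)
  x <- setNames(rep(2, 5), phy2$tip.label)
  m2 <- marginal_asr(phy2, x, 4, 1e-10)
  expect_true(all(m2[, 3] > 1 - 1e-6))
  # q -> Inf: uniform at every node
  m3 <- marginal_asr(phy2, x, 4, 1e4)
  expect_lt(max(abs(m3 - 0.25)), 1e-6)
})

test_that("conditional mode returns renormalized subtree likelihoods", {
  phy <- rand_dated_tree(6, seed = 9)
  x <- setNames(c(0, 1, 0, 1, 0, 1), phy$tip.label)
  mc <- marginal_asr(phy, x, 2, 0.3, method = "conditional")
  expect_equal(unname(rowSums(mc)), rep(1, nrow(mc)))
  mm <- marginal_asr(phy, x, 2, 0.3)
  # the two flavours agree at the root (uniform prior) but generally differ
  expect_equal(unname(mc[1, ]), unname(mm[1, ]), tolerance = 1e-12)
})

test_that("ml rate matches a dense grid-search oracle", {
  phy <- rand_dated_tree(8, seed = 21)
  x <- setNames(c(0, 0, 0, 1, 1, 1, 0, 1), phy$tip.label)
  qs <- exp(seq(log(1e-4), log(20), length.out = 1e4))
  lls <- vapply(qs, function(q) as.numeric(prune_loglik(phy, x, 2, q)), 0)
  q_grid <- qs[which.max(lls)]
  q_hat <- ml_rate(phy, x, 2)
  expect_equal(as.numeric(q_hat), q_grid, tolerance = 1e-3)
  expect_gte(attr(q_hat, "logLik"), max(lls) - 1e-8)
  expect_false(attr(q_hat, "boundary"))
})

test_that("invariant characters pin the rate at the lower bound", {
  phy <- rand_dated_tree(6, seed = 4)
  x <- setNames(rep(1, 6), phy$tip.label)
  expect_warning(q_hat <- ml_rate(phy, x, 3), "invariant")
  expect_equal(as.numeric(q_hat), 1e-8)
  expect_true(attr(q_hat, "boundary"))
})

test_that("simulated rates are recovered by the estimator", {
  phy <- sim_dated_tree(16, seed = 77)
  # scale so total depth is of order 10 Ma
  phy$edge.length <- phy$edge.length * 10 / max(node_ages(phy))
  q_true <- 0.2
  x <- sim_mk_characters(phy, k = 3, q = q_true, n_chars = 300, seed = 8)
  q_hat <- as.numeric(ml_rate(phy, x, 3))
  expect_lt(abs(q_hat - q_true) / q_true, 0.2)
})

test_that("fit_mk exposes the usual fitted-model surface", {
  phy <- sim_dated_tree(10, seed = 15)
  x <- sim_mk_characters(phy, k = 2, q = 0.5, n_chars = 4, seed = 16)
  fit <- fit_mk(phy, x)
  expect_s3_class(fit, "mk_fit")
  expect_length(fit$anc, 4)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_named(coef(fit)[1], "q")
  expect_output(print(fit), "Mk1 fit")
  p <- predict(fit, type = "prob", character = 2)
  expect_equal(unname(rowSums(p)), rep(1, phy$Nnode))
  states <- predict(fit, type = "state")
  expect_true(all(states %in% 0:1))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(10L, 3L))
  # fixed-q fit reproduces prune_loglik
  fit2 <- fit_mk(phy, x[, 1], k = 2, q = 0.5)
  expect_equal(fit2$logLik,
               as.numeric(prune_loglik(phy, x[, 1], 2, 0.5)))
})

test_that("paired reconstruction with zero fossils is an identity", {
  phy <- sim_dated_tree(6, seed = 31)
  x <- setNames(sample(0:2, 6, replace = TRUE), phy$tip.label)
  pair <- asr_two_trees(phy, phy, x, setNames(numeric(0), character(0)),
                        k = 3)
  cmp <- compare_asr_report(pair)
  expect_equal(nrow(cmp$shadow), 0L)
  expect_equal(max(cmp$shared$tv), 0)
  expect_false(any(cmp$shared$flip))
})

test_that("a stem fossil pulls the shadow node towards its state", {
  sc <- suber_scenario()
  pair <- asr_two_trees(sc$tree, sc$grafted, sc$states, sc$fossil_states,
                        k = sc$k)
  cmp <- compare_asr_report(pair)
  # shadow MRCAs reconstruct as the fossil state
  expect_true(all(cmp$shadow$map_grafted == 2))
  # the Suber-like crown node flips from Mediterranean to summer-wet
  crown <- cmp$shared[cmp$shared$fingerprint == "S1|S2", ]
  expect_equal(crown$map_extant, 4L)
  expect_equal(crown$map_grafted, 2L)
  expect_true(crown$flip)
  expect_error(asr_two_trees(sc$tree, sc$grafted, sc$states,
                             c(F_suber1 = 2), k = 5),
               "missing fossil state.*F_suber2")
})
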