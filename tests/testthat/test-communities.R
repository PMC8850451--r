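planted_layers <- function(n_per = 4, L = 3, p_in = 0.95, p_out = 0.05,
                           seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  lapply(seq_len(L), function(l) {
    a <- matrix(runif(n * n) * p_out, n, n)
    a[1:n_per, 1:n_per] <- runif(n_per^2) * 0.3 + p_in - 0.3
    a[(n_per + 1):n, (n_per + 1):n] <- runif(n_per^2) * 0.3 + p_in - 0.3
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a
  })
}

test_that("single-layer modularity matches the textbook formula", {
  set.seed(1)
  a <- matrix(runif(64), 8, 8)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  # all nodes together: Q = 0 at gamma 1
  one <- rep(1L, 8)
  expect_equal(multilayer_modularity(one, list(a), gamma = 1, omega = 0), 0,
               tolerance = 1e-12)
  for (s in 1:10) {
    set.seed(s)
    comm <- sample(1:3, 8, replace = TRUE)
    expect_equal(
      multilayer_modularity(comm, list(a), gamma = 1, omega = 0),
      newman_girvan_modularity(a, comm),
      tolerance = 1e-12
    )
  }
  # Q is invariant to global relabeling
  comm <- c(1, 1, 2, 2, 3, 3, 1, 2)
  relab <- c(7, 7, 5, 5, 9, 9, 7, 5)
  g <- supra_modularity_matrix(list(a), 1, 0)
  expect_equal(multilayer_modularity(comm, g),
               multilayer_modularity(relab, g), tolerance = 1e-15)
  expect_error(supra_modularity_matrix(list(matrix(0, 3, 3)), 1, 0),
               "edge weight")
})

test_that("the optimizer reaches exhaustive-enumeration optima on tiny graphs", {
  parts <- all_set_partitions(8)     # n = 4 nodes, L = 2 layers
  hits <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    layers <- lapply(1:2, function(l) {
      a <- matrix(runif(16), 4, 4)
      a <- (a + t(a)) / 2
      diag(a) <- 0
      a
    })
    g <- supra_modularity_matrix(layers, gamma = 1, omega = 0.5)
    best_q <- max(vapply(parts, multilayer_modularity, numeric(1), graph = g))
    got <- max(vapply(1:5, function(r) {
      louvain_multilayer(g, 1, 0.5, seed = s * 10 + r)$Q
    }, numeric(1)))
    hits[s] <- got >= best_q - 1e-12
  }
  expect_gte(mean(hits), 0.9)
})

test_that("multilayer Louvain recovers planted structure and coupling limits", {
  layers <- planted_layers(n_per = 5, L = 3, seed = 2)
  p <- louvain_multilayer(layers, gamma = 1, omega = 0.5, seed = 1)
  expect_equal(length(unique(as.vector(p$labels))), 2)
  expect_equal(length(unique(p$labels[1:5, 1])), 1)
  expect_false(p$labels[1, 1] == p$labels[6, 1])
  # each community spans the layers
  expect_equal(p$labels[, 1], p$labels[, 2])

  # very large coupling freezes labels across layers
  noisy <- lapply(1:4, function(l) {
    set.seed(l)
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a
  })
  rigid <- louvain_multilayer(noisy, gamma = 1, omega = 50, seed = 1)
  expect_true(all(rigid$labels[, 1] == rigid$labels[, 4]))

  # gamma near zero merges a connected layer into one community
  loose <- louvain_multilayer(noisy, gamma = 0.01, omega = 0.1, seed = 1)
  expect_equal(length(unique(loose$labels[, 1])), 1)
})

test_that("with no coupling the per-layer partitions match single-layer runs", {
  layers <- planted_layers(n_per = 5, L = 2, seed = 4)
  multi <- louvain_multilayer(layers, gamma = 1, omega = 0, seed = 3)
  for (l in 1:2) {
    single <- louvain_multilayer(layers[l], gamma = 1, omega = 0, seed = 3)
    co_m <- outer(multi$labels[, l], multi$labels[, l], `==`)
    co_s <- outer(single$labels[, 1], single$labels[, 1], `==`)
    expect_true(mean(co_m == co_s) >= 0.95)
  }
})

test_that("consensus partitions are robust and label-invariant", {
  layers <- planted_layers(n_per = 4, L = 2, seed = 5)
  base <- louvain_multilayer(layers, 1, 0.5, seed = 1)$labels
  same <- consensus_partition(rep(list(base), 5), seed = 1)
  expect_true(same$converged)
  expect_equal(same$iterations, 0L)
  expect_identical(loomnet:::co_assignment_key(as.vector(same$labels)),
                   loomnet:::co_assignment_key(as.vector(base)))

  # label-permuted copies are recognized as identical partitions
  permuted <- base
  permuted[] <- c(5L, 9L)[base]
  lab_perm <- consensus_partition(list(base, permuted), seed = 1)
  expect_true(lab_perm$converged)
  expect_identical(loomnet:::co_assignment_key(as.vector(lab_perm$labels)),
                   loomnet:::co_assignment_key(as.vector(base)))

  # one aberrant partition among many consistent ones is outvoted
  set.seed(6)
  rand <- matrix(sample(1:4, length(base), replace = TRUE), nrow(base))
  noisy <- c(rep(list(base), 19), list(rand))
  cons <- consensus_partition(noisy, seed = 2)
  expect_identical(loomnet:::co_assignment_key(as.vector(cons$labels)),
                   loomnet:::co_assignment_key(as.vector(base)))
})

test_that("flexibility counts normalized community changes", {
  lab <- rbind(c(1, 1, 2, 2, 3),
               c(1, 1, 1, 1, 1),
               c(1, 2, 1, 2, 1))
  expect_equal(flexibility(lab), c(2 / 4, 0, 1))
  expect_equal(flexibility(lab[, 1, drop = FALSE]), c(0, 0, 0))
})

test_that("cohesion counts mutual same-to-same community moves", {
  # nodes 1 and 2 move together at exactly one of two transitions
  lab <- rbind(c(1, 2, 2),
               c(1, 2, 3),
               c(1, 1, 1))
  coh <- cohesion(lab)
  expect_equal(coh$M[1, 2], 0.5)
  expect_equal(coh$strength[1], 0.5)
  expect_equal(coh$strength[3], 0)
  expect_true(isSymmetric(coh$M))
  # no changes at all
  expect_equal(cohesion(matrix(1, 4, 3))$strength, rep(0, 4))
  # brute-force transition scan on random partitions
  for (s in 1:8) {
    set.seed(s)
    lab_r <- matrix(sample(1:3, 10 * 6, replace = TRUE), 10, 6)
    expect_equal(cohesion(lab_r)$M, cohesion_bruteforce(lab_r),
                 tolerance = 1e-12)
  }
})

test_that("promiscuity is the fraction of communities ever visited", {
  lab <- rbind(c(1, 2, 1, 3),
               c(1, 1, 1, 1),
               c(2, 2, 3, 2))
  psi <- promiscuity(lab)
  expect_equal(psi[1], 1)            # visits all K = 3 communities
  expect_equal(psi[2], 0)
  expect_equal(psi[3], 0.5)
  expect_equal(promiscuity(matrix(1, 3, 4)), rep(0, 3))
  # bounds on random partitions
  set.seed(9)
  lab_r <- matrix(sample(1:5, 40, replace = TRUE), 8, 5)
  expect_true(all(promiscuity(lab_r) >= 0 & promiscuity(lab_r) <= 1))
  expect_true(all(flexibility(lab_r) >= 0 & flexibility(lab_r) <= 1))
  expect_true(all(cohesion(lab_r)$strength <= nrow(lab_r) - 1))
})

test_that("the parameter sweep applies the bounding and scoring rules", {
  layers <- planted_layers(n_per = 6, L = 4, p_in = 0.9, p_out = 0.1, seed = 7)
  sw <- sweep_gamma_omega(layers, gamma_grid = c(0.5, 1), omega_grid = 0.5,
                          reps = 6, seed = 1,
                          check_transitions = list(c(1, 2)))
  expect_equal(nrow(sw$grid), 2)
  expect_true(all(c("mean_q", "var_q", "null_q", "score", "admissible",
                    "selected") %in% names(sw$grid)))
  # admissibility tracks the community-count range rule
  expect_equal(sw$grid$admissible,
               sw$grid$n_communities >= 4 & sw$grid$n_communities <= 60 &
                 sw$grid$min_change >= ceiling(12 / 3))
  # selected cells are admissible and above the mean score
  expect_true(all(sw$grid$score[sw$grid$selected] > mean(sw$grid$score)))
  expect_true(all(sw$grid$admissible[sw$grid$selected]))
  expect_error(sweep_gamma_omega(layers, numeric(0), 0.5), "degenerate")
})

test_that("the sweep recovers a planted six-community structure", {
  set.seed(8)
  n <- 18
  membership <- rep(1:6, each = 3)
  layers <- lapply(1:3, function(l) {
    a <- matrix(runif(n * n) * 0.1, n, n)
    for (c in 1:6) {
      idx <- which(membership == c)
      a[idx, idx] <- 0.85 + runif(9) * 0.1
    }
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a
  })
  hits <- sapply(1:5, function(s) {
    sw <- sweep_gamma_omega(layers, gamma_grid = c(1, 1.3),
                            omega_grid = c(0.25), reps = 6, seed = s,
                            check_transitions = list())
    any(abs(sw$grid$n_communities - 6) <= 1)
  })
  expect_true(all(hits))
})

test_that("Friedman group comparisons use the 13-test Bonferroni cutoff", {
  set.seed(10)
  blocks <- 34
  same <- matrix(rnorm(blocks), blocks, 3)   # identical groups
  shifted <- same
  shifted[, 3] <- shifted[, 3] + 5
  res <- compare_groups(list(identical_groups = same,
                             one_shifted = shifted), m_tests = 13)
  expect_equal(unique(res$cutoff), 0.05 / 13)
  expect_equal(round(unique(res$cutoff), 4), 0.0038)
  expect_false(res$significant[res$cell == "identical_groups"])
  expect_true(res$significant[res$cell == "one_shifted"])
  pw <- attr(res, "pairwise")$one_shifted
  expect_true(any(pw$significant))
})
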