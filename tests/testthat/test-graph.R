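test_that("the node-count rule maps ROI abundance to 0-4 nodes", {
  expect_equal(node_count_rule(c(0, 150, 199)), c(0L, 0L, 0L))
  expect_equal(node_count_rule(c(200, 350, 499)), c(1L, 1L, 1L))
  expect_equal(node_count_rule(c(500, 999)), c(2L, 2L))
  expect_equal(node_count_rule(c(1000, 2999, 3000)), c(3L, 3L, 3L))
  expect_equal(node_count_rule(c(3001, 5000)), c(4L, 4L))
  # scaled rule table
  expect_equal(node_count_rule(30, thresholds = c(20, 50, 100, 300)), 1L)
})

test_that("nodes are placed per region-cluster and sparse-fish nodes flagged", {
  set.seed(8)
  n <- 600
  rois <- data.frame(
    roi_id = 1:n,
    fish_id = rep(paste0("f", 1:5), length.out = n),
    region = rep(c("tectum", "hindbrain", "pallium"), each = n / 3),
    x = runif(n, 0, 100), y = runif(n, 0, 100), z = runif(n, 0, 100)
  )
  labels <- rep(c("moderate", "strong", "weak"), length.out = n)
  nb <- build_nodes(rois, labels, thresholds = c(20, 50, 100, 300), seed = 1)
  # each (region, cluster) cell has ~66 ROIs -> 2 nodes each
  expect_equal(nrow(nb$nodes), 18)
  expect_true(all(nb$nodes$n_fish == 5))
  expect_equal(sum(nb$nodes$n_rois), n)
  # membership is consistent with the node table
  for (k in sample(nrow(nb$nodes), 5)) {
    expect_equal(sum(nb$membership == nb$nodes$node_id[k], na.rm = TRUE),
                 nb$nodes$n_rois[k])
  }
  # a cluster confined to one fish is flagged (n_fish <= 3) and dropped
  rois1 <- rois
  rois1$fish_id[labels == "strong"] <- "f1"
  nb1 <- build_nodes(rois1, labels, thresholds = c(20, 50, 100, 300),
                     seed = 1, drop_flagged = FALSE)
  expect_true(all(nb1$nodes$flagged[nb1$nodes$cluster == "strong"]))
  nb1d <- build_nodes(rois1, labels, thresholds = c(20, 50, 100, 300),
                      seed = 1, drop_flagged = TRUE)
  expect_false(any(nb1d$nodes$cluster == "strong"))
})

test_that("ROIs join the nearest node of their own cluster", {
  nodes <- data.frame(node_id = c(1L, 2L, 3L), region = "tectum",
                      cluster = c("strong", "strong", "weak"),
                      x = c(0, 10, 0), y = c(0, 0, 0), z = c(0, 0, 0))
  rois <- data.frame(x = c(1, 9, 5, 2), y = 0, z = 0)
  labels <- c("strong", "strong", "strong", "weak")
  mem <- assign_to_existing_nodes(rois, labels, nodes)
  expect_equal(mem[1:2], c(1L, 2L))
  expect_equal(mem[3], 1L)          # exact tie breaks to the lower node id
  expect_equal(mem[4], 3L)          # region-agnostic but cluster-matched
  expect_true(is.na(assign_to_existing_nodes(
    data.frame(x = 0, y = 0, z = 0), "inhibited", nodes)))

  # brute-force nearest-centroid scan agrees on random data
  set.seed(9)
  nodes_r <- data.frame(node_id = 1:6, region = "x", cluster = "strong",
                        x = runif(6), y = runif(6), z = runif(6))
  rr <- data.frame(x = runif(40), y = runif(40), z = runif(40))
  mem_r <- assign_to_existing_nodes(rr, rep("strong", 40), nodes_r)
  brute <- sapply(1:40, function(i) {
    d <- sqrt((rr$x[i] - nodes_r$x)^2 + (rr$y[i] - nodes_r$y)^2 +
                (rr$z[i] - nodes_r$z)^2)
    which.min(d)
  })
  expect_equal(mem_r, as.integer(brute))
})

test_that("per-loom matrices are windowed Pearson correlations", {
  set.seed(10)
  nt <- list(fish1 = matrix(rnorm(5 * 60), 5, 60,
                            dimnames = list(1:5, NULL)))
  windows <- list(loom1 = 1:20, loom2 = 21:40)
  tens <- per_loom_matrices(nt, windows)
  direct <- cor(t(nt$fish1[, 1:20]))
  expect_equal(unname(tens[, , 1, 1]), unname(direct), tolerance = 1e-12)
  expect_true(all(abs(tens[, , 1, 1] - t(tens[, , 1, 1])) < 1e-12))
  expect_equal(unname(diag(tens[, , 2, 1])), rep(1, 5))
  # identical and sign-flipped traces
  nt2 <- list(f = rbind(a = nt$fish1[1, ], b = nt$fish1[1, ],
                        c = -nt$fish1[1, ]))
  t2 <- per_loom_matrices(nt2, windows)
  expect_equal(t2[1, 2, 1, 1], 1)
  expect_equal(t2[1, 3, 1, 1], -1)
  # constant trace gives NA off-diagonal
  nt3 <- list(f = rbind(nt$fish1[1, ], rep(2, 60)))
  t3 <- per_loom_matrices(nt3, windows)
  expect_true(is.na(t3[1, 2, 1, 1]))
  expect_equal(t3[2, 2, 1, 1], 1)
})

test_that("fish averaging is an elementwise mean with leave-one-out", {
  set.seed(11)
  tens <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5),
                dimnames = list(1:4, 1:4, paste0("loom", 1:3),
                                paste0("fish", 1:5)))
  avg <- average_matrices(tens)
  loop <- apply(tens, c(1, 2, 3), mean)
  expect_equal(avg, loop, tolerance = 1e-14)
  # leaving one of two fish returns the other exactly
  two <- tens[, , , 1:2, drop = FALSE]
  expect_equal(average_matrices(two, leave_out = "fish2"),
               tens[, , , 1, drop = TRUE], tolerance = 1e-14)
  # identical matrices average to themselves
  same <- array(rep(tens[, , , 1], 5), dim(tens), dimnames = dimnames(tens))
  expect_equal(average_matrices(same), tens[, , , 1], tolerance = 1e-14)
  # NA entries propagate only when missing in all fish
  tens_na <- tens
  tens_na[1, 2, 1, ] <- NA
  tens_na[2, 1, 1, ] <- NA
  tens_na[1, 3, 1, 1:4] <- NA
  avg_na <- average_matrices(tens_na)
  expect_true(is.na(avg_na[1, 2, 1]))
  expect_equal(avg_na[1, 3, 1], tens_na[1, 3, 1, 5])
  expect_error(average_matrices(two, leave_out = 1:2), "no fish")
})

test_that("graph thresholding keeps absolute correlations at the cutoff", {
  m <- rbind(c(1, 0.8, -0.8, 0.3),
             c(0.8, 1, 0.75, -0.2),
             c(-0.8, 0.75, 1, 0.1),
             c(0.3, -0.2, 0.1, 1))
  g <- threshold_graph(m, 0.75)
  expect_equal(g[1, 2], 0.8)
  expect_equal(g[1, 3], -0.8)       # negative edge retained by |r|
  expect_equal(g[2, 3], 0.75)       # boundary kept under >=
  expect_equal(g[1, 4], 0)
  expect_equal(diag(g), rep(0, 4))
  gs <- threshold_graph(m, 0.75, strict = TRUE)
  expect_equal(gs[2, 3], 0)
  expect_equal(threshold_graph(matrix(0.5, 3, 3), 0.75),
               matrix(0, 3, 3))
})

test_that("graph density is present over possible edges", {
  full <- matrix(1, 6, 6); diag(full) <- 0
  expect_equal(graph_density(full), 1)
  expect_equal(graph_density(matrix(0, 6, 6)), 0)
  m5 <- matrix(0, 5, 5)
  m5[1, 2] <- m5[2, 1] <- m5[2, 3] <- m5[3, 2] <- 0.9
  m5[3, 4] <- m5[4, 3] <- m5[4, 5] <- m5[5, 4] <- 0.8
  expect_equal(graph_density(m5), 4 / 10)
})

test_that("participation coefficients follow the squared-strength formula", {
  # all weight inside one community
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  expect_equal(participation_coefficients(w, c("a", "a", "b", "b"))[1], 0)
  # weight split equally over 4 communities
  w4 <- matrix(0, 5, 5)
  w4[1, 2:5] <- w4[2:5, 1] <- 1
  p <- participation_coefficients(w4, c("x", "a", "b", "c", "d"))
  expect_equal(p[1], 1 - 4 * (1 / 4)^2)
  # isolated node
  expect_equal(participation_coefficients(matrix(0, 3, 3), c(1, 2, 3)),
               rep(0, 3))
  # brute-force oracle on random weighted graphs
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:20, 1)
    w <- matrix(runif(n * n, -0.5, 1), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    comm <- sample(1:4, n, replace = TRUE)
    expect_equal(participation_coefficients(w, comm),
                 participation_bruteforce(w, comm), tolerance = 1e-12)
  }
})

test_that("recovery matching finds the planted duplicate trial", {
  set.seed(12)
  tens <- array(rnorm(6 * 6 * 10), c(6, 6, 10))
  for (l in 1:10) {
    tens[, , l] <- (tens[, , l] + t(tens[, , l])) / 2
    diag(tens[, , l]) <- 1
  }
  m11 <- tens[, , 4] + matrix(rnorm(36, 0, 0.01), 6, 6)
  m11 <- (m11 + t(m11)) / 2
  expect_equal(match_recovery_matrix(tens, m11)$best, 4)
  expect_equal(match_recovery_matrix(tens, tens[, , 1])$best, 1)
  # exact two-way tie goes to the smaller index
  tens_tie <- tens
  tens_tie[, , 7] <- tens_tie[, , 2]
  expect_equal(match_recovery_matrix(tens_tie, tens_tie[, , 2])$best, 2)
  # missing entries are excluded pairwise
  tens_na <- tens
  tens_na[1, 2, 4] <- tens_na[2, 1, 4] <- NA
  expect_equal(match_recovery_matrix(tens_na, m11)$best, 4)
})

test_that("relative graphs expose displayed differences only", {
  a <- matrix(c(1, 0.9, 0.7, 0.9, 1, 0.2, 0.7, 0.2, 1), 3, 3)
  b <- matrix(c(1, 0.7, 0.7, 0.7, 1, 0.8, 0.7, 0.8, 1), 3, 3)
  d <- relative_graph(a, b, 0.75)
  expect_equal(d[1, 2], 0.2)          # above cutoff in a
  expect_equal(d[2, 3], -0.6)         # above cutoff in b
  expect_true(is.na(d[1, 3]))         # 0.7 in both: not displayed
  d0 <- relative_graph(a, a)
  expect_true(all(d0[!is.na(d0)] == 0))
})

test_that("strong-edge counts are signed upper-triangle counts", {
  expect_equal(count_strong_edges(diag(10)), 0)
  ones <- matrix(1, 10, 10)
  expect_equal(count_strong_edges(ones), 45)
  set.seed(13)
  m <- random_corr_matrix(12, 13)
  brute <- 0
  for (i in 1:11) for (j in (i + 1):12) if (m[i, j] > 0.75) brute <- brute + 1
  expect_equal(count_strong_edges(m), brute)
  neg <- diag(3)
  neg[1, 2] <- neg[2, 1] <- -0.9      # |r| high but signed count excludes it
  expect_equal(count_strong_edges(neg), 0)
})

test_that("edge recovery deltas subtract post-rest from pre-rest strengths", {
  nodes <- data.frame(node_id = 1:3, region = c("tectum", "tectum", "pallium"),
                      cluster = c("strong", "weak", "weak"))
  m10 <- rbind(c(1, 0.2, 0.5), c(0.2, 1, 0.4), c(0.5, 0.4, 1))
  m11 <- rbind(c(1, 0.9, 0.5), c(0.9, 1, 0.1), c(0.5, 0.1, 1))
  d <- edge_recovery_deltas(m10, m11, nodes)
  expect_equal(nrow(d), 3)
  expect_equal(d$delta[d$i == 1 & d$j == 2], -0.7)
  expect_equal(d$delta[d$i == 1 & d$j == 3], 0)
  expect_equal(sort(unique(d$cluster_pair)),
               c("strong-weak", "weak-weak"))
  # grouping partitions all edges
  expect_equal(sum(table(d$region_pair)), choose(3, 2))
})
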