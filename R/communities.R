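#' Supra-modularity matrix of an ordinal multilayer graph
#'
#' Builds the (n*L) x (n*L) modularity matrix B with intralayer blocks
#' `A_l - gamma * k k' / 2m_l` (Newman-Girvan configuration null per layer)
#' and uniform ordinal interlayer coupling `omega` between copies of the same
#' node in adjacent layers. Layer diagonals are zeroed and missing entries
#' treated as absent edges. The normalization `2mu` accumulates each layer's
#' total weight plus `2 * omega * n * (L - 1)`. A degenerate layer whose
#' weights sum to zero or less contributes its raw weights without a
#' configuration-null term (and its absolute weight to the normalization).
#'
#' @param layers List of symmetric node x node weight matrices (shared node
#'   set; negative entries allowed).
#' @param gamma Structural resolution parameter (scalar or per-layer).
#' @param omega Temporal coupling parameter.
#' @return List: `B`, `twomu`, `n`, `L`.
#' @export
supra_modularity_matrix <- function(layers, gamma = 1, omega = 1) {
  n <- nrow(layers[[1]])
  L <- length(layers)
  gamma <- rep_len(gamma, L)
  B <- matrix(0, n * L, n * L)
  twomu <- 0
  for (l in seq_len(L)) {
    A <- layers[[l]]
    A[is.na(A)] <- 0
    diag(A) <- 0
    k <- rowSums(A)
    twom <- sum(k)
    idx <- (l - 1) * n + seq_len(n)
    if (twom > 0) {
      B[idx, idx] <- A - gamma[l] * outer(k, k) / twom
      twomu <- twomu + twom
    } else {
      # a layer whose weights cancel (or an empty layer) has no meaningful
      # configuration null; its weights enter as-is
      B[idx, idx] <- A
      twomu <- twomu + sum(abs(A))
    }
  }
  if (L > 1 && omega != 0) {
    for (l in seq_len(L - 1)) {
      i1 <- (l - 1) * n + seq_len(n)
      i2 <- l * n + seq_len(n)
      B[cbind(i1, i2)] <- omega
      B[cbind(i2, i1)] <- omega
    }
    twomu <- twomu + 2 * omega * n * (L - 1)
  }
  if (twomu <= 0) stop("total edge weight of the multilayer graph is zero")
  list(B = B, twomu = twomu, n = n, L = L)
}

#' Multilayer modularity of a partition
#'
#' `Q = (1/2mu) * sum_ijlr [ (A_ijl - gamma_l P_ijl) delta_lr +
#' delta_ij omega_jlr ] delta(C_il, C_jr)` with the per-layer configuration
#' null `P_ijl = k_i k_j / 2m_l`.
#'
#' @param labels Community labels: an n x L matrix or a length-`n*L` vector
#'   (layer-major, node fastest).
#' @param graph A [supra_modularity_matrix()] result, or a list of layers
#'   (then `gamma` and `omega` must be supplied).
#' @param gamma,omega Used when `graph` is a list of layers.
#' @return Scalar Q.
#' @export
multilayer_modularity <- function(labels, graph, gamma = 1, omega = 1) {
  if (is.null(graph$B)) graph <- supra_modularity_matrix(graph, gamma, omega)
  v <- as.integer(as.factor(as.vector(labels)))
  stopifnot(length(v) == nrow(graph$B))
  total <- 0
  for (c in unique(v)) {
    idx <- which(v == c)
    total <- total + sum(graph$B[idx, idx])
  }
  total / graph$twomu
}

# Louvain-type optimization directly on a (supra-)modularity matrix:
# greedy node moves in seeded random scan order, then aggregation, repeated
# until no move improves. Handles negative entries (signed modularity).
louvain_matrix <- function(B, seed = 1L, tol = 1e-10) {
  set.seed(as.integer(seed))
  n0 <- nrow(B)
  mapping <- seq_len(n0)
  repeat {
    n <- nrow(B)
    comm <- seq_len(n)
    improved_any <- FALSE
    repeat {
      improved <- FALSE
      for (i in sample.int(n)) {
        w <- B[i, ]
        w[i] <- 0
        gains <- rowsum(w, comm)           # community id x 1
        cur <- gains[as.character(comm[i]), 1]
        best_c <- rownames(gains)[which.max(gains[, 1])]
        if (gains[best_c, 1] > cur + tol && best_c != as.character(comm[i])) {
          comm[i] <- as.integer(best_c)
          improved <- TRUE
          improved_any <- TRUE
        }
      }
      if (!improved) break
    }
    comm <- as.integer(as.factor(comm))
    if (!improved_any || max(comm) == n) {
      return(mapping_labels(mapping, comm))
    }
    mapping <- comm[mapping]
    B <- aggregate_matrix(B, comm)
  }
}

mapping_labels <- function(mapping, comm) as.integer(as.factor(comm[mapping]))

aggregate_matrix <- function(B, comm) {
  Bc <- rowsum(B, comm)
  t(rowsum(t(Bc), comm))
}

#' Generalized Louvain community detection on a multilayer graph
#'
#' Maximizes the multilayer modularity quality function by greedy node moves
#' and aggregation on the supra-modularity matrix. Stochastic over the seeded
#' node scan order; ties break to the first maximal-gain move.
#'
#' @param layers List of node x node weight matrices, or a prebuilt
#'   [supra_modularity_matrix()].
#' @param gamma Structural resolution parameter.
#' @param omega Temporal coupling parameter.
#' @param seed Integer seed.
#' @return Object of class `multilayer_partition`: `labels` (n x L integer
#'   matrix), `Q`, `gamma`, `omega`.
#' @export
louvain_multilayer <- function(layers, gamma = 1, omega = 1, seed = 1L) {
  graph <- if (is.null(layers$B)) {
    supra_modularity_matrix(layers, gamma, omega)
  } else layers
  v <- louvain_matrix(graph$B, seed = seed)
  labels <- matrix(v, graph$n, graph$L)
  structure(list(labels = labels, Q = multilayer_modularity(v, graph),
                 gamma = gamma, omega = omega),
            class = "multilayer_partition")
}

#' Consensus partition over repeated community detection runs
#'
#' Builds the agreement matrix (fraction of runs co-assigning each node-layer
#' pair), zeroes entries at or below the level expected from randomly
#' permuted labels, re-clusters the thresholded agreement matrix with the
#' same Louvain procedure, and iterates until all re-clustering runs agree
#' (or `max_iter` is reached, flagged).
#'
#' @param partitions List of label matrices/vectors on the same node-layer
#'   set (>= 2).
#' @param seed Integer seed.
#' @param n_recluster Louvain runs per consensus iteration.
#' @param max_iter Iteration cap.
#' @return List: `labels` (consensus, same shape as the inputs), `converged`,
#'   `iterations`.
#' @export
consensus_partition <- function(partitions, seed = 1L, n_recluster = 10,
                                max_iter = 50) {
  stopifnot(length(partitions) >= 2)
  shape <- dim(partitions[[1]])
  vecs <- lapply(partitions, as.vector)
  N <- length(vecs[[1]])
  for (it in seq_len(max_iter)) {
    if (all_partitions_equal(vecs)) {
      lab <- as.integer(as.factor(vecs[[1]]))
      if (!is.null(shape)) lab <- matrix(lab, shape[1], shape[2])
      return(list(labels = lab, converged = TRUE, iterations = it - 1L))
    }
    agree <- matrix(0, N, N)
    null_level <- 0
    for (v in vecs) {
      vi <- as.integer(as.factor(v))
      agree <- agree + outer(vi, vi, `==`)
      s <- tabulate(vi)
      null_level <- null_level + sum(s * (s - 1)) / (N * (N - 1))
    }
    agree <- agree / length(vecs)
    null_level <- null_level / length(vecs)
    agree[agree <= null_level] <- 0
    diag(agree) <- 0
    if (sum(agree) == 0) {
      return(list(labels = reshape_labels(vecs[[1]], shape),
                  converged = FALSE, iterations = it))
    }
    k <- rowSums(agree)
    Bc <- agree - outer(k, k) / sum(k)
    vecs <- lapply(seq_len(n_recluster), function(r) {
      louvain_matrix(Bc, seed = mix_seed(seed, it, r))
    })
  }
  list(labels = reshape_labels(vecs[[1]], shape), converged = FALSE,
       iterations = max_iter)
}

all_partitions_equal <- function(vecs) {
  ref <- co_assignment_key(vecs[[1]])
  all(vapply(vecs[-1], function(v) identical(co_assignment_key(v), ref),
             logical(1)))
}

# canonical relabeling so label-permuted copies compare equal
co_assignment_key <- function(v) {
  as.integer(factor(v, levels = unique(v)))
}

reshape_labels <- function(v, shape) {
  lab <- as.integer(as.factor(v))
  if (!is.null(shape)) lab <- matrix(lab, shape[1], shape[2]) else lab
}

#' Node flexibility
#'
#' Number of community changes of each node across consecutive layers,
#' normalized by the `L - 1` possible changes.
#' @param labels n x L community label matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
flexibility <- function(labels) {
  L <- ncol(labels)
  if (L < 2) return(rep(0, nrow(labels)))
  rowSums(labels[, -1, drop = FALSE] != labels[, -L, drop = FALSE]) / (L - 1)
}

#' Node cohesion and the cohesion matrix
#'
#' `M_ij` is the fraction of the `L - 1` layer transitions at which nodes i
#' and j move together: both change community, depart from a shared
#' community, and arrive in a shared community. Cohesion strength is
#' `Omega_i = sum_j M_ij`.
#'
#' @param labels n x L community label matrix.
#' @return List: `strength` (Omega per node), `M` (symmetric matrix).
#' @export
cohesion <- function(labels) {
  n <- nrow(labels)
  L <- ncol(labels)
  M <- matrix(0, n, n)
  if (L >= 2) {
    for (l in seq_len(L - 1)) {
      changed <- which(labels[, l] != labels[, l + 1])
      if (length(changed) < 2) next
      same_before <- outer(labels[changed, l], labels[changed, l], `==`)
      same_after <- outer(labels[changed, l + 1], labels[changed, l + 1], `==`)
      M[changed, changed] <- M[changed, changed] + (same_before & same_after)
    }
    M <- M / (L - 1)
    diag(M) <- 0
  }
  list(strength = rowSums(M), M = M)
}

#' Node promiscuity
#'
#' Fraction of all communities in the partition that each node visits at
#' least once: `(distinct communities of node i - 1) / (K - 1)` with K the
#' total community count (0 when K = 1).
#'
#' @param labels n x L community label matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
promiscuity <- function(labels) {
  K <- length(unique(as.vector(labels)))
  if (K <= 1) return(rep(0, nrow(labels)))
  g_dif <- apply(labels, 1, function(r) length(unique(r)) - 1)
  g_dif / (K - 1)
}

#' Sweep the resolution and coupling parameters
#'
#' For every (gamma, omega) cell: repeated Louvain runs give the mean and
#' variance of Q; matched runs on temporal-null (layer-permuted) graphs give
#' the null mean; the optimized score is
#' `(meanQ - meanQ_null) * (max(var) - var) / max(var)` (down-weighting
#' high-variance cells). The consensus partition of each cell is checked
#' against the bounding rules: between `comm_range[1]` and `comm_range[2]`
#' communities, and at least `ceiling(n * change_frac)` nodes changing
#' community across each transition in `check_transitions` (by default
#' pre-loom to loom 1, and loom 10 to loom 11 when the layers are the
#' pre-loom window followed by looms 1-11). Selected cells are admissible
#' cells scoring above the grid mean.
#'
#' @param layers List of node x node matrices (layer 1 = pre-loom window).
#' @param gamma_grid,omega_grid Parameter values (within 0.1-2.5 / 0.1-2).
#' @param reps Louvain repetitions per cell.
#' @param seed Integer seed.
#' @param comm_range Admissible community-count range.
#' @param change_frac Minimum changing-node fraction per checked transition.
#' @param check_transitions List of layer-index pairs to check.
#' @return List: `grid` (data frame gamma, omega, mean_q, var_q, null_q,
#'   score, n_communities, admissible, selected), `consensus` (list of
#'   consensus label matrices per cell).
#' @export
sweep_gamma_omega <- function(layers, gamma_grid, omega_grid, reps = 100,
                              seed = 1L, comm_range = c(4, 60),
                              change_frac = 1 / 3,
                              check_transitions = list(c(1, 2), c(11, 12))) {
  if (length(gamma_grid) < 1 || length(omega_grid) < 1) stop("degenerate grid")
  n <- nrow(layers[[1]])
  L <- length(layers)
  check_transitions <- Filter(function(tr) max(tr) <= L, check_transitions)
  cells <- expand.grid(gamma = gamma_grid, omega = omega_grid)
  res <- vector("list", nrow(cells))
  consensus <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    g <- cells$gamma[ci]
    o <- cells$omega[ci]
    graph <- supra_modularity_matrix(layers, g, o)
    parts <- lapply(seq_len(reps), function(r) {
      louvain_multilayer(graph, g, o, seed = mix_seed(seed, ci, r))
    })
    qs <- vapply(parts, `[[`, numeric(1), "Q")
    null_qs <- vapply(seq_len(reps), function(r) {
      nl <- temporal_null(layers, seed = mix_seed(seed, 1, ci, r))
      louvain_multilayer(nl, g, o, seed = mix_seed(seed, 2, ci, r))$Q
    }, numeric(1))
    cons <- consensus_partition(lapply(parts, `[[`, "labels"),
                                seed = mix_seed(seed, 3, ci))
    consensus[[ci]] <- cons$labels
    n_comm <- length(unique(as.vector(cons$labels)))
    changes <- vapply(check_transitions, function(tr) {
      sum(cons$labels[, tr[1]] != cons$labels[, tr[2]])
    }, numeric(1))
    res[[ci]] <- data.frame(
      gamma = g, omega = o, mean_q = mean(qs), var_q = stats::var(qs),
      null_q = mean(null_qs), n_communities = n_comm,
      min_change = if (length(changes)) min(changes) else NA_real_,
      admissible = n_comm >= comm_range[1] && n_comm <= comm_range[2] &&
        all(changes >= ceiling(n * change_frac))
    )
  }
  grid <- do.call(rbind, res)
  max_var <- max(grid$var_q)
  rel_var <- if (max_var > 0) (max_var - grid$var_q) / max_var else 1
  grid$score <- (grid$mean_q - grid$null_q) * rel_var
  grid$selected <- grid$admissible & grid$score > mean(grid$score)
  list(grid = grid, consensus = consensus)
}

#' Friedman comparison of dynamic community metrics across groups
#'
#' For each grouping cell (each of the 9 brain regions and 4 functional
#' clusters in the study design), runs a Friedman test across groups with the
#' selected (gamma, omega) pairs as blocks, followed by pairwise mean-rank
#' comparisons; significance uses a Bonferroni cutoff `alpha / m_tests`
#' (13 tests in the study design).
#'
#' @param cell_values Named list; each element a blocks x groups matrix of
#'   the metric for one grouping cell.
#' @param alpha Family-wise error rate.
#' @param m_tests Bonferroni divisor across grouping cells.
#' @return Data frame: cell, statistic, df, p_value, cutoff, significant;
#'   pairwise mean-rank comparisons in attribute `pairwise`.
#' @export
compare_groups <- function(cell_values, alpha = 0.05, m_tests = 13) {
  cutoff <- bonferroni_cutoff(alpha, m_tests)
  rows <- list()
  pairwise <- list()
  for (nm in names(cell_values)) {
    m <- as.matrix(cell_values[[nm]])
    ft <- stats::friedman.test(m)
    rows[[nm]] <- data.frame(
      cell = nm, statistic = unname(ft$statistic),
      df = unname(ft$parameter), p_value = ft$p.value, cutoff = cutoff,
      significant = is.finite(ft$p.value) && ft$p.value < cutoff
    )
    pairwise[[nm]] <- friedman_pairwise(m, alpha / m_tests)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pairwise") <- pairwise
  out
}

# pairwise comparison of average column ranks after a Friedman test
friedman_pairwise <- function(m, alpha = 0.05) {
  nblk <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1, rank))
  mean_rank <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * nblk))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    diff = mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]],
    p_value = pmin(1, 2 * stats::pnorm(-abs(
      (mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]]) / se)) * n_pairs),
    significant = pmin(1, 2 * stats::pnorm(-abs(
      (mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]]) / se)) * n_pairs) < alpha
  )
}
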