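#' Node count from pooled ROI abundance
#'
#' The rule balancing sparse-but-real populations against abundant ones:
#' fewer than 200 ROIs, no node; 200-499, 1 node; 500-999, 2 nodes;
#' 1000-3000, 3 nodes; above 3000, 4 nodes. Thresholds are configurable so
#' desk-scale cohorts can use a scaled table.
#'
#' @param n ROI count pooled over fish for one region x cluster cell.
#' @param thresholds Length-4 increasing vector of rule boundaries.
#' @return Integer node count, 0-4.
#' @export
node_count_rule <- function(n, thresholds = c(200, 500, 1000, 3000)) {
  stopifnot(length(thresholds) == 4, !is.unsorted(thresholds))
  vapply(n, function(ni) {
    if (ni < thresholds[1]) 0L
    else if (ni < thresholds[2]) 1L
    else if (ni < thresholds[3]) 2L
    else if (ni <= thresholds[4]) 3L
    else 4L
  }, integer(1))
}

#' Build spatial-functional nodes
#'
#' Per (region, functional cluster): the pooled ROI count sets the node count
#' via [node_count_rule()]; Euclidean k-means on the 3-D ROI coordinates
#' places that many nodes; every member ROI joins its node. Nodes with three
#' or fewer contributing fish are flagged for removal.
#'
#' @param rois Data frame with `roi_id`, `fish_id`, `x`, `y`, `z`.
#' @param labels Per-ROI functional cluster labels.
#' @param clusters Cluster labels that receive nodes.
#' @param thresholds Node-count rule boundaries.
#' @param min_fish Nodes with `n_fish <= min_fish` are flagged.
#' @param seed Integer seed for the spatial k-means.
#' @param drop_flagged Drop flagged nodes from the returned set.
#' @return List: `nodes` (data frame node_id, region, cluster, x, y, z,
#'   n_rois, n_fish, flagged) and `membership` (node_id per ROI, NA when the
#'   ROI feeds no node).
#' @export
build_nodes <- function(rois, labels,
                        clusters = c("strong", "moderate", "weak", "inhibited"),
                        thresholds = c(200, 500, 1000, 3000), min_fish = 3,
                        seed = 1L, drop_flagged = TRUE) {
  membership <- rep(NA_integer_, nrow(rois))
  nodes <- list()
  node_id <- 0L
  set.seed(as.integer(seed))
  for (cl in clusters) {
    for (rg in unique(rois$region[labels == cl])) {
      idx <- which(labels == cl & rois$region == rg)
      k <- node_count_rule(length(idx), thresholds)
      if (k == 0) next
      xyz <- as.matrix(rois[idx, c("x", "y", "z")])
      assign <- if (k == 1) rep(1L, length(idx)) else {
        stats::kmeans(xyz, centers = k, nstart = 5, iter.max = 50)$cluster
      }
      for (j in seq_len(k)) {
        node_id <- node_id + 1L
        m <- idx[assign == j]
        nodes[[node_id]] <- data.frame(
          node_id = node_id, region = rg, cluster = cl,
          x = mean(rois$x[m]), y = mean(rois$y[m]), z = mean(rois$z[m]),
          n_rois = length(m), n_fish = length(unique(rois$fish_id[m]))
        )
        membership[m] <- node_id
      }
    }
  }
  nodes <- do.call(rbind, nodes)
  if (is.null(nodes)) stop("no region-cluster cell reaches the node-count rule")
  nodes$flagged <- nodes$n_fish <= min_fish
  if (drop_flagged && any(nodes$flagged)) {
    membership[membership %in% nodes$node_id[nodes$flagged]] <- NA_integer_
    nodes <- nodes[!nodes$flagged, ]
  }
  if (nrow(nodes) == 0) {
    stop("all nodes were discarded by the minimum-fish rule (n_fish <= ",
         min_fish, ")")
  }
  list(nodes = nodes, membership = membership)
}

#' Assign ROIs to an existing node set
#'
#' Each ROI joins the nearest (Euclidean) node centroid of its own functional
#' cluster, regardless of region; ties break to the lower node id. Used to
#' carry a reference cohort's nodes onto another cohort.
#'
#' @param rois Data frame with `x`, `y`, `z`.
#' @param labels Per-ROI functional cluster labels.
#' @param nodes Node table from [build_nodes()].
#' @return Integer node_id per ROI (`NA` when no node shares the cluster).
#' @export
assign_to_existing_nodes <- function(rois, labels, nodes) {
  membership <- rep(NA_integer_, nrow(rois))
  for (cl in unique(nodes$cluster)) {
    nd <- nodes[nodes$cluster == cl, ]
    nd <- nd[order(nd$node_id), ]
    rows <- which(labels == cl)
    if (!length(rows)) next
    d <- outer(rows, seq_len(nrow(nd)), function(i, j) {
      sqrt((rois$x[i] - nd$x[j])^2 + (rois$y[i] - nd$y[j])^2 +
             (rois$z[i] - nd$z[j])^2)
    })
    membership[rows] <- nd$node_id[max.col(-d, ties.method = "first")]
  }
  membership
}

#' Per-fish node mean traces
#'
#' @param traces z-scored ROI x timepoint matrix.
#' @param membership Node id per ROI.
#' @param nodes Node table.
#' @param fish_id Per-ROI fish labels.
#' @return Named list (per fish) of node x timepoint matrices; nodes with no
#'   member ROIs in a fish are `NA` rows.
#' @export
node_mean_traces <- function(traces, membership, nodes, fish_id) {
  fish <- unique(fish_id)
  lapply(stats::setNames(fish, fish), function(f) {
    m <- matrix(NA_real_, nrow(nodes), ncol(traces),
                dimnames = list(nodes$node_id, NULL))
    for (j in seq_len(nrow(nodes))) {
      rows <- which(fish_id == f & membership == nodes$node_id[j])
      if (length(rows)) m[j, ] <- colMeans(traces[rows, , drop = FALSE])
    }
    m
  })
}

#' Per-loom node correlation matrices
#'
#' Zero-lag Pearson correlation between node mean traces restricted to each
#' loom window, per fish. Constant or missing traces give `NA` entries.
#'
#' @param node_traces List (per fish) of node x timepoint matrices.
#' @param windows List of frame-index windows ([loom_frame_windows()]).
#' @return node x node x window x fish array with unit diagonal per slice.
#' @export
per_loom_matrices <- function(node_traces, windows) {
  n <- nrow(node_traces[[1]])
  out <- array(NA_real_, c(n, n, length(windows), length(node_traces)),
               dimnames = list(rownames(node_traces[[1]]),
                               rownames(node_traces[[1]]),
                               names(windows), names(node_traces)))
  for (f in seq_along(node_traces)) {
    for (w in seq_along(windows)) {
      x <- t(node_traces[[f]][, windows[[w]], drop = FALSE])
      sds <- apply(x, 2, stats::sd)
      ok <- is.finite(sds) & sds > 0
      cc <- matrix(NA_real_, n, n)
      if (sum(ok) >= 2) cc[ok, ok] <- stats::cor(x[, ok, drop = FALSE])
      diag(cc) <- 1
      out[, , w, f] <- cc
    }
  }
  out
}

#' Average correlation matrices across fish
#'
#' Elementwise mean over the fish axis using pairwise-present entries; with
#' `leave_out`, the named fish is excluded (leave-one-out validation).
#'
#' @param tensor node x node x loom x fish array.
#' @param leave_out Fish name or index to exclude, or NULL.
#' @return node x node x loom array.
#' @export
average_matrices <- function(tensor, leave_out = NULL) {
  keep <- seq_len(dim(tensor)[4])
  if (!is.null(leave_out)) {
    if (is.character(leave_out)) leave_out <- match(leave_out, dimnames(tensor)[[4]])
    keep <- setdiff(keep, leave_out)
  }
  if (length(keep) < 1) stop("no fish left to average")
  apply(tensor[, , , keep, drop = FALSE], c(1, 2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Threshold a correlation matrix into a weighted graph
#'
#' Removes edges whose absolute correlation falls below the cutoff; retained
#' edges keep their signed weights.
#'
#' @param mat Symmetric correlation matrix.
#' @param cutoff Threshold (default 0.75).
#' @param mode `"absolute"` thresholds `|r|`; `"signed"` thresholds `r`.
#' @param strict Use `>` instead of `>=` for retention.
#' @return Matrix with sub-threshold entries set to 0 and zero diagonal.
#' @export
threshold_graph <- function(mat, cutoff = 0.75, mode = c("absolute", "signed"),
                            strict = FALSE) {
  mode <- match.arg(mode)
  v <- if (mode == "absolute") abs(mat) else mat
  keep <- if (strict) v > cutoff else v >= cutoff
  keep[is.na(keep)] <- FALSE
  out <- ifelse(keep, mat, 0)
  diag(out) <- 0
  out
}

#' Graph density
#'
#' Ratio of present edges to the total possible edges.
#' @param graph Thresholded weight matrix (0 = absent edge).
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  n <- nrow(graph)
  if (n < 2) return(0)
  ut <- graph[upper.tri(graph)]
  sum(ut != 0, na.rm = TRUE) / (n * (n - 1) / 2)
}

#' Participation coefficients over a fixed community partition
#'
#' `P_i = 1 - sum_k (S_iCk / S_i)^2`, where `S_iCk` is the total edge weight
#' from node i into community k and `S_i` its total weight. Only positive
#' weights enter the strengths (squared weight proportions are ill-defined
#' under mixed signs); isolated nodes get `P_i = 0`.
#'
#' @param graph Weighted adjacency matrix (zero diagonal).
#' @param communities Community label per node (here typically the four
#'   functional clusters).
#' @return Numeric vector of `P_i`.
#' @export
participation_coefficients <- function(graph, communities) {
  stopifnot(length(communities) == nrow(graph))
  w <- pmax(graph, 0)
  w[is.na(w)] <- 0
  diag(w) <- 0
  comm <- as.factor(communities)
  s_ik <- t(rowsum(t(w), comm))        # node x community strengths
  s_i <- rowSums(s_ik)
  p <- 1 - rowSums((s_ik / ifelse(s_i == 0, 1, s_i))^2)
  p[s_i == 0] <- 0
  p
}

#' Most similar earlier trial to the post-rest trial
#'
#' Correlates the upper-triangle vector of each of the first `n` matrices
#' with that of the post-rest matrix and returns the best-matching trial
#' (ties to the smaller index). Missing entries are excluded pairwise.
#'
#' @param tensor node x node x loom array for the reference trials.
#' @param mat11 Matrix for the post-rest trial.
#' @return List: `best` (trial index), `r` (per-trial correlations).
#' @export
match_recovery_matrix <- function(tensor, mat11) {
  ut <- upper.tri(mat11)
  v11 <- mat11[ut]
  r <- vapply(seq_len(dim(tensor)[3]), function(l) {
    v <- tensor[, , l][ut]
    ok <- is.finite(v) & is.finite(v11)
    if (sum(ok) < 3) return(NA_real_)
    stats::cor(v[ok], v11[ok])
  }, numeric(1))
  list(best = which.max(r), r = r)
}

#' Relative (difference) graph between two conditions
#'
#' Per-edge `A - B`, restricted to edges whose correlation exceeds the
#' display cutoff in either condition; all other entries are `NA`.
#'
#' @param a,b Correlation matrices on the same node set.
#' @param display_cutoff Strict display threshold.
#' @return Matrix of signed differences with `NA` for undisplayed edges.
#' @export
relative_graph <- function(a, b, display_cutoff = 0.75) {
  keep <- (a > display_cutoff) | (b > display_cutoff)
  keep[is.na(keep)] <- FALSE
  out <- ifelse(keep, a - b, NA_real_)
  diag(out) <- NA_real_
  out
}

#' Count edges above a cutoff
#'
#' Upper-triangle entries strictly greater than the (signed) cutoff.
#' @param mat Correlation matrix.
#' @param cutoff Edge threshold.
#' @return Integer count.
#' @export
count_strong_edges <- function(mat, cutoff = 0.75) {
  sum(mat[upper.tri(mat)] > cutoff, na.rm = TRUE)
}

#' Edge-wise recovery deltas between the last pre-rest and post-rest trials
#'
#' Per upper-triangle edge: strength at the pre-rest trial minus strength at
#' the post-rest trial (negative = pronounced recovery), grouped by
#' region-pair and cluster-pair.
#'
#' @param m10,m11 Correlation matrices (pre-rest, post-rest).
#' @param nodes Node table with `region` and `cluster` aligned to the rows.
#' @return Data frame: `i`, `j`, `delta`, `region_pair`, `cluster_pair`.
#' @export
edge_recovery_deltas <- function(m10, m11, nodes) {
  n <- nrow(m10)
  idx <- which(upper.tri(m10), arr.ind = TRUE)
  data.frame(
    i = idx[, 1], j = idx[, 2],
    delta = m10[idx] - m11[idx],
    region_pair = paste(pmin(nodes$region[idx[, 1]], nodes$region[idx[, 2]]),
                        pmax(nodes$region[idx[, 1]], nodes$region[idx[, 2]]),
                        sep = "-"),
    cluster_pair = paste(pmin(nodes$cluster[idx[, 1]], nodes$cluster[idx[, 2]]),
                         pmax(nodes$cluster[idx[, 1]], nodes$cluster[idx[, 2]]),
                         sep = "-")
  )
}
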