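#' Descending-correlation edge filtration
#'
#' Orders the edges of a weighted graph from strongest to weakest correlation
#' (signed by default, so negative correlations enter after all positive
#' ones; optionally by absolute value), with ties broken by the (min node id,
#' max node id) pair. The correlation value is the filtration parameter;
#' internally it maps to an ascending parameter `t = 1 - r` so standard
#' reduction algorithms apply.
#'
#' @param mat Symmetric correlation-like matrix; `NA` entries are treated as
#'   absent pairs.
#' @param mode `"signed"` or `"absolute"` ordering.
#' @return Object of class `filtration`: `edges` (data frame i, j, r, in
#'   filtration order), `n`, `mode`.
#' @export
build_filtration <- function(mat, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (!isSymmetric(unname(mat))) stop("matrix must be symmetric")
  n <- nrow(mat)
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  r <- mat[idx]
  keep <- is.finite(r)
  edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2], r = r[keep])
  key <- if (mode == "absolute") abs(edges$r) else edges$r
  edges <- edges[order(-key, edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, n = n, mode = mode), class = "filtration")
}

#' Persistent homology of the filtered clique complex
#'
#' Tracks connected components (dimension 0), loops of four or more edges
#' (dimension 1) and triangle-bounded shells (dimension 2) as edges are added
#' from strongest to weakest correlation, forming the flag (clique) complex
#' at each step. Coefficients are over GF(2). Each bar runs from the birth
#' correlation (strongest value at which the cavity exists) to its death;
#' cavities alive at the end of the filtration die at the final (weakest)
#' filtration value. All dimension-0 bars are reported (their count at the
#' start equals the node count); zero-lifetime pairs in dimensions 1-2 are
#' discarded, while essential (never-dying) classes are always kept.
#'
#' @param filtration A [build_filtration()] result, or a symmetric matrix.
#' @param max_dim Maximum homology dimension (0, 1 or 2).
#' @return Object of class `barcode`: data frame `dimension`, `birth`,
#'   `death`, `lifetime` (`|death - birth|`).
#' @export
persistent_homology <- function(filtration, max_dim = 2) {
  if (!inherits(filtration, "filtration")) {
    filtration <- build_filtration(filtration)
  }
  if (max_dim > 2) stop("dimensions above 2 are unsupported")
  n <- filtration$n
  ed <- filtration$edges
  m <- nrow(ed)
  r_final <- if (m > 0) ed$r[m] else 1
  bars <- list()

  ## dimension 0: union-find over edges in filtration order (elder rule;
  ## equal vertex births, so the root with the lower index survives a merge)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  creator <- logical(m)
  for (e in seq_len(m)) {
    a <- find(ed$i[e])
    b <- find(ed$j[e])
    if (a == b) {
      creator[e] <- TRUE
    } else {
      young <- max(a, b)
      parent[young] <- min(a, b)
      bars[[length(bars) + 1]] <- c(0, 1, ed$r[e])
    }
  }
  n_components <- length(unique(vapply(seq_len(n), find, integer(1))))
  for (s in seq_len(n_components)) {
    bars[[length(bars) + 1]] <- c(0, 1, r_final)
  }

  if (max_dim >= 1 && m > 0) {
    adj <- matrix(FALSE, n, n)
    eidx <- matrix(0L, n, n)
    for (e in seq_len(m)) {
      adj[ed$i[e], ed$j[e]] <- adj[ed$j[e], ed$i[e]] <- TRUE
      eidx[ed$i[e], ed$j[e]] <- eidx[ed$j[e], ed$i[e]] <- e
    }
    tri <- enumerate_triangles(adj, eidx, ed)
    red2 <- reduce_boundary(tri$cols, m)
    # paired creator edges die at the pairing triangle's filtration value
    for (t in seq_along(red2$pair_low)) {
      low <- red2$pair_low[t]
      if (low > 0) {
        birth <- ed$r[low]
        death <- tri$value[t]
        if (birth != death) bars[[length(bars) + 1]] <- c(1, birth, death)
      }
    }
    essential1 <- setdiff(which(creator), red2$pair_low[red2$pair_low > 0])
    for (e in essential1) {
      bars[[length(bars) + 1]] <- c(1, ed$r[e], r_final)
    }

    if (max_dim >= 2 && nrow(tri$simplices) > 0) {
      tet <- enumerate_tetrahedra(adj, tri)
      creators2 <- which(red2$pair_low == 0)   # triangles creating 2-cycles
      red3 <- reduce_boundary(tet$cols, nrow(tri$simplices))
      paired_tri <- red3$pair_low[red3$pair_low > 0]
      for (s in seq_along(red3$pair_low)) {
        low <- red3$pair_low[s]
        if (low > 0) {
          birth <- tri$value[low]
          death <- tet$value[s]
          if (birth != death) bars[[length(bars) + 1]] <- c(2, birth, death)
        }
      }
      for (t in setdiff(creators2, paired_tri)) {
        bars[[length(bars) + 1]] <- c(2, tri$value[t], r_final)
      }
    }
  }

  out <- as.data.frame(do.call(rbind, bars))
  names(out) <- c("dimension", "birth", "death")
  out$lifetime <- abs(out$death - out$birth)
  out <- out[order(out$dimension, -out$birth, -out$death), ]
  rownames(out) <- NULL
  structure(out, class = c("barcode", "data.frame"))
}

# triangles of the final graph, in filtration order (entry step = position of
# the weakest member edge; ties by vertex triple)
enumerate_triangles <- function(adj, eidx, ed) {
  n <- nrow(adj)
  m <- nrow(ed)
  simp <- list()
  for (e in seq_len(m)) {
    i <- ed$i[e]
    j <- ed$j[e]
    common <- which(adj[i, ] & adj[j, ])
    for (k in common[common > j]) {
      if (i < j && j < k) simp[[length(simp) + 1]] <- sort(c(i, j, k))
    }
  }
  if (!length(simp)) {
    return(list(simplices = matrix(0L, 0, 3), value = numeric(0),
                cols = list(), pos = integer(0)))
  }
  simp <- unique(do.call(rbind, simp))
  cols <- lapply(seq_len(nrow(simp)), function(t) {
    v <- simp[t, ]
    sort(c(eidx[v[1], v[2]], eidx[v[1], v[3]], eidx[v[2], v[3]]))
  })
  pos <- vapply(cols, max, integer(1))     # filtration step of entry
  ord <- order(pos, simp[, 1], simp[, 2], simp[, 3])
  list(simplices = simp[ord, , drop = FALSE],
       value = ed$r[pos[ord]],
       cols = cols[ord])
}

# tetrahedra of the final graph, as GF(2) columns over triangle indices
enumerate_tetrahedra <- function(adj, tri) {
  simp <- tri$simplices
  if (nrow(simp) == 0) return(list(value = numeric(0), cols = list()))
  n <- nrow(adj)
  tri_key <- paste(simp[, 1], simp[, 2], simp[, 3])
  tri_id <- stats::setNames(seq_len(nrow(simp)), tri_key)
  tets <- list()
  for (t in seq_len(nrow(simp))) {
    v <- simp[t, ]
    cand <- which(adj[v[1], ] & adj[v[2], ] & adj[v[3], ])
    for (l in cand[cand > v[3]]) tets[[length(tets) + 1]] <- c(v, l)
  }
  if (!length(tets)) return(list(value = numeric(0), cols = list()))
  tets <- unique(do.call(rbind, tets))
  cols <- lapply(seq_len(nrow(tets)), function(s) {
    v <- tets[s, ]
    faces <- rbind(v[-4], v[-3], v[-2], v[-1])
    sort(unname(tri_id[apply(faces, 1, function(f) paste(sort(f), collapse = " "))]))
  })
  pos <- vapply(cols, max, integer(1))     # entry step in triangle order
  value <- tri$value[pos]
  ord <- order(pos, tets[, 1], tets[, 2], tets[, 3], tets[, 4])
  list(value = value[ord], cols = cols[ord])
}

# standard persistence column reduction over GF(2); columns are sorted
# integer vectors of face indices, processed in filtration order
reduce_boundary <- function(cols, n_faces) {
  n_cols <- length(cols)
  pair_low <- integer(n_cols)
  low_owner <- integer(n_faces)            # face index -> column owning it
  for (c in seq_len(n_cols)) {
    col <- cols[[c]]
    while (length(col)) {
      low <- col[length(col)]
      other <- low_owner[low]
      if (other == 0) break
      col <- xor_sorted(col, cols[[other]])
    }
    cols[[c]] <- col
    if (length(col)) {
      low <- col[length(col)]
      low_owner[low] <- c
      pair_low[c] <- low
    }
  }
  list(pair_low = pair_low, reduced = cols)
}

# symmetric difference of two sorted integer vectors (GF(2) column addition)
xor_sorted <- function(a, b) {
  u <- c(a, b)
  u <- sort(u)
  dup <- u[duplicated(u)]
  u[!u %in% dup]
}

#' Sum of bar lifetimes in one dimension
#' @param barcode A [persistent_homology()] barcode.
#' @param dim Homology dimension.
#' @return Scalar lifetime sum (0 for an empty barcode).
#' @export
lifetime_sum <- function(barcode, dim) {
  sum(barcode$lifetime[barcode$dimension == dim])
}
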