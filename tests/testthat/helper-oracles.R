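# Independent brute-force oracles used to validate the package's
# implementations. These are written from the definitions, not from the
# package code paths they check.

# participation coefficient by naive double loop over nodes and communities
participation_bruteforce <- function(w, communities) {
  w <- pmax(w, 0)
  diag(w) <- 0
  n <- nrow(w)
  comms <- unique(communities)
  p <- numeric(n)
  for (i in seq_len(n)) {
    s_i <- 0
    for (j in seq_len(n)) s_i <- s_i + w[i, j]
    if (s_i == 0) {
      p[i] <- 0
      next
    }
    acc <- 0
    for (ck in comms) {
      s_ik <- 0
      for (j in which(communities == ck)) s_ik <- s_ik + w[i, j]
      acc <- acc + (s_ik / s_i)^2
    }
    p[i] <- 1 - acc
  }
  p
}

# textbook Newman-Girvan modularity: Q = sum_c (e_c/m - (d_c/2m)^2)
newman_girvan_modularity <- function(a, communities) {
  diag(a) <- 0
  m <- sum(a) / 2
  q <- 0
  for (c in unique(communities)) {
    idx <- communities == c
    e_c <- sum(a[idx, idx]) / 2
    d_c <- sum(a[idx, ])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      rec(c(prefix, lab), max(maxlab, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# cohesion matrix by explicit triple scan over transitions and node pairs
cohesion_bruteforce <- function(labels) {
  n <- nrow(labels)
  L <- ncol(labels)
  M <- matrix(0, n, n)
  for (l in seq_len(L - 1)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        moved_i <- labels[i, l] != labels[i, l + 1]
        moved_j <- labels[j, l] != labels[j, l + 1]
        together <- labels[i, l] == labels[j, l] &&
          labels[i, l + 1] == labels[j, l + 1]
        if (moved_i && moved_j && together) M[i, j] <- M[i, j] + 1
      }
    }
  }
  M / (L - 1)
}

# persistent homology by full GF(2) boundary-matrix reduction over all
# simplices (vertices, edges, triangles, tetrahedra) in filtration order
ph_bruteforce <- function(mat, max_dim = 2) {
  n <- nrow(mat)
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  r <- mat[idx]
  keep <- is.finite(r)
  ed <- data.frame(i = idx[keep, 1], j = idx[keep, 2], r = r[keep])
  ed <- ed[order(-ed$r, ed$i, ed$j), ]
  rownames(ed) <- NULL
  m <- nrow(ed)
  r_final <- if (m > 0) ed$r[m] else 1

  # collect simplices as (vertex set, dim, entry value, entry order key)
  simplices <- lapply(seq_len(n), function(v) list(v = v, dim = 0L, val = 1))
  epos <- function(i, j) which(ed$i == min(i, j) & ed$j == max(i, j))
  if (m > 0) {
    for (e in seq_len(m)) {
      simplices[[length(simplices) + 1]] <-
        list(v = c(ed$i[e], ed$j[e]), dim = 1L, val = ed$r[e], pos = e)
    }
    if (max_dim >= 1 && n >= 3) {
      for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
        pe <- c(epos(a, b), epos(a, cc), epos(b, cc))
        if (length(pe) == 3) {
          simplices[[length(simplices) + 1]] <-
            list(v = c(a, b, cc), dim = 2L, val = ed$r[max(pe)], pos = max(pe))
        }
      }
    }
    if (max_dim >= 2 && n >= 4) {
      for (a in 1:(n - 3)) for (b in (a + 1):(n - 2)) {
        for (cc in (b + 1):(n - 1)) for (d in (cc + 1):n) {
          pe <- c(epos(a, b), epos(a, cc), epos(a, d),
                  epos(b, cc), epos(b, d), epos(cc, d))
          if (length(pe) == 6) {
            simplices[[length(simplices) + 1]] <-
              list(v = c(a, b, cc, d), dim = 3L, val = ed$r[max(pe)],
                   pos = max(pe))
          }
        }
      }
    }
  }
  # filtration order: vertices first, then by entry step, dim, vertex tuple
  key <- sapply(simplices, function(s) {
    c(if (s$dim == 0) 0 else s$pos, s$dim,
      sum(s$v * (n + 1)^(seq_along(s$v) - 1)))
  })
  ord <- order(key[1, ], key[2, ], key[3, ])
  simplices <- simplices[ord]
  ns <- length(simplices)
  skey <- vapply(simplices, function(s) paste(sort(s$v), collapse = "-"),
                 character(1))
  sid <- stats::setNames(seq_len(ns), skey)

  # dense GF(2) reduction
  cols <- vector("list", ns)
  for (s in seq_len(ns)) {
    sx <- simplices[[s]]
    if (sx$dim == 0) {
      cols[[s]] <- integer(0)
    } else {
      faces <- utils::combn(sort(sx$v), length(sx$v) - 1)
      cols[[s]] <- sort(unname(sid[apply(faces, 2, paste, collapse = "-")]))
    }
  }
  low_owner <- integer(ns)
  pair_of <- integer(ns)     # creator simplex -> killer column (0 = essential)
  creator <- logical(ns)
  for (s in seq_len(ns)) {
    col <- cols[[s]]
    while (length(col)) {
      low <- col[length(col)]
      o <- low_owner[low]
      if (o == 0) break
      col <- sort(c(setdiff(col, intersect(col, cols[[o]])),
                    setdiff(cols[[o]], intersect(col, cols[[o]]))))
    }
    cols[[s]] <- col
    if (length(col)) {
      low <- col[length(col)]
      low_owner[low] <- s
      pair_of[low] <- s
    } else {
      creator[s] <- TRUE
    }
  }
  bars <- list()
  for (s in seq_len(ns)) {
    if (!creator[s]) next
    d <- simplices[[s]]$dim
    if (d > max_dim) next
    birth <- simplices[[s]]$val
    if (pair_of[s] > 0) {
      death <- simplices[[pair_of[s]]]$val
      if (d == 0 || birth != death) {
        bars[[length(bars) + 1]] <- c(d, birth, death)
      }
    } else {
      bars[[length(bars) + 1]] <- c(d, birth, r_final)
    }
  }
  out <- as.data.frame(do.call(rbind, bars))
  names(out) <- c("dimension", "birth", "death")
  out$lifetime <- abs(out$death - out$birth)
  out[order(out$dimension, -out$birth, -out$death), ]
}

# canonical form of a barcode for set comparison
barcode_key <- function(bc, digits = 10) {
  k <- sprintf("%d|%.*f|%.*f", bc$dimension, digits, bc$birth, digits, bc$death)
  sort(k)
}

# small random symmetric "correlation" matrix with unit diagonal
random_corr_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# small cohort shared across tests (cached per session)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cc <- cohort_config("s20-short", 3,
                          roi_counts = default_roi_counts(0.4))
      cache <<- simulate_cohort(cc, seed = 42)
    }
    cache
  }
})

octahedron_matrix <- function(w = 0.8) {
  # K2,2,2: all pairs adjacent except the three antipodal ones
  m <- matrix(w, 6, 6)
  m[1, 2] <- m[2, 1] <- NA
  m[3, 4] <- m[4, 3] <- NA
  m[5, 6] <- m[6, 5] <- NA
  diag(m) <- 1
  m
}
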