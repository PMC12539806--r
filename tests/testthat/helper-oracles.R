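# Independent oracles. Each is written from the definition, not from the
# implementation path it checks: brute-force loops over pixels/pairs, the
# double-loop modularity formula, and a from-scratch dense assembly of the
# C-PHATE connectivity matrix.

# distance from pixel (r, c) to the nearest pixel of a region, pixel centers
oracle_dist_to_region <- function(mask, r, c) {
  idx <- which(mask, arr.ind = TRUE)
  min(sqrt((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
}

# exhaustive per-pixel expansion: every pixel within distance_px of the region
oracle_expand <- function(mask, distance_px) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      out[r, c] <- oracle_dist_to_region(mask, r, c) <= distance_px
    }
  }
  out
}

# directed count a->b on one slice: pixels of b within distance_px of a
oracle_contact_slice <- function(slice, a, b, distance_px) {
  ma <- slice == a
  mb <- slice == b
  if (!any(ma) || !any(mb)) return(c(0L, 0L))
  idxb <- which(mb, arr.ind = TRUE)
  ab <- sum(apply(idxb, 1, function(p)
    oracle_dist_to_region(ma, p[1], p[2]) <= distance_px))
  idxa <- which(ma, arr.ind = TRUE)
  ba <- sum(apply(idxa, 1, function(p)
    oracle_dist_to_region(mb, p[1], p[2]) <= distance_px))
  c(ab, ba)
}

# full adjacency matrix of a label volume by exhaustive pixel counting
oracle_adjacency <- function(vol, distance_px) {
  zs <- if (is.null(vol$region)) seq_along(vol$slices)
        else seq(vol$region[1], vol$region[2])
  labels <- sort(unique(unlist(lapply(vol$slices[zs], function(s)
    unique(s[s != 0L])))))
  labs <- as.character(labels)
  directed <- matrix(0, length(labels), length(labels),
                     dimnames = list(labs, labs))
  for (z in zs) {
    sl <- vol$slices[[z]]
    for (ai in seq_along(labels)) {
      for (bi in seq_along(labels)) {
        if (ai == bi) next
        cnt <- oracle_contact_slice(sl, labels[ai], labels[bi], distance_px)
        directed[ai, bi] <- directed[ai, bi] + cnt[1]
      }
    }
  }
  (directed + t(directed)) / 2
}

# Box-formula modularity by explicit double loop
oracle_modularity <- function(assignment, A) {
  diag(A) <- 0
  d <- rowSums(A)
  m <- sum(A) / 2
  s <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(A))) {
      if (assignment[i] == assignment[j]) s <- s + A[i, j] - d[i] * d[j] / (2 * m)
    }
  }
  s / (2 * m)
}

# from-scratch dense C-PHATE connectivity over a trace: iterate node pairs
# and fill entries from first principles (kernels from block sums, lag-1/2
# weights from raw membership movements)
oracle_connectivity <- function(trace, A0, w1 = 100, w2 = 30) {
  iters <- trace$iterations
  Tn <- length(iters)
  nodes <- do.call(rbind, lapply(seq_len(Tn), function(t) {
    ids <- sort(unique(iters[[t]]$assignment))
    data.frame(t = t, cluster = ids)
  }))
  N <- nrow(nodes)
  members <- lapply(seq_len(N), function(r) {
    a <- iters[[nodes$t[r]]]$assignment
    names(a)[a == nodes$cluster[r]]
  })
  # per-iteration kernels
  kern_entry <- function(t, ci, cj) {
    a <- iters[[t]]$assignment
    ids <- sort(unique(a))
    At <- matrix(0, length(ids), length(ids))
    for (x in seq_along(ids)) {
      for (y in seq_along(ids)) {
        mx <- names(a)[a == ids[x]]
        my <- names(a)[a == ids[y]]
        At[x, y] <- sum(A0[mx, my])
      }
    }
    dd <- rowSums(At)
    At[match(ci, ids), match(cj, ids)] /
      sqrt(dd[match(ci, ids)] * dd[match(cj, ids)])
  }
  C <- matrix(0, N, N)
  for (r in seq_len(N)) {
    for (s in seq_len(N)) {
      tr_ <- nodes$t[r]; ts_ <- nodes$t[s]
      if (tr_ == ts_) {
        C[r, s] <- kern_entry(tr_, nodes$cluster[r], nodes$cluster[s])
      } else if (abs(tr_ - ts_) == 1) {
        early <- if (tr_ < ts_) r else s
        late <- if (tr_ < ts_) s else r
        frac <- length(intersect(members[[early]], members[[late]])) /
          length(members[[early]])
        C[r, s] <- w1 * frac
      } else if (abs(tr_ - ts_) == 2) {
        early <- if (tr_ < ts_) r else s
        late <- if (tr_ < ts_) s else r
        # composed two-step movement: fraction of early's members ending in late
        frac <- length(intersect(members[[early]], members[[late]])) /
          length(members[[early]])
        C[r, s] <- w2 * frac
      }
    }
  }
  C
}

# total triangle area from vertex/face arrays, written independently
oracle_mesh_area <- function(mesh) {
  tot <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[i, ], ]
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    tot <- tot + sqrt(sum(cr^2)) / 2
  }
  tot
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
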