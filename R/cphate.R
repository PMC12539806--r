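#' Symmetrically normalized kernel matrix
#'
#' `K = D^(-1/2) A D^(-1/2)` with `D_ii = sum_j A_ij`: the within-iteration
#' kernel placed on the diagonal blocks of the C-PHATE connectivity matrix.
#'
#' @param A symmetric nonnegative cluster-level affinity with positive row
#'   sums.
#' @return symmetric kernel matrix.
#' @export
symmetric_kernel <- function(A) {
  d <- rowSums(A)
  bad <- which(d <= 0)
  stop_if(length(bad) > 0,
          sprintf("zero row sum in cluster affinity at row(s) %s",
                  paste(bad, collapse = ",")))
  A / sqrt(outer(d, d))
}

#' Cluster-level affinity by block aggregation
#'
#' Coarse-grains the original adjacency to clusters: entry (I, J) is the sum
#' of `A0[i, j]` over members i of I and j of J. Total edge weight is
#' conserved under this aggregation.
#'
#' @param assignment cluster id per original neuron (named or aligned with
#'   `A0` rows).
#' @param A0 original adjacency matrix.
#' @return k x k matrix with cluster ids as dimnames.
#' @export
cluster_affinity <- function(assignment, A0) {
  if (!is.null(names(assignment)) && !is.null(rownames(A0)))
    assignment <- assignment[rownames(A0)]
  ids <- sort(unique(assignment))
  M <- matrix(0, nrow(A0), length(ids))
  M[cbind(seq_len(nrow(A0)), match(assignment, ids))] <- 1
  At <- t(M) %*% A0 %*% M
  dimnames(At) <- list(ids, ids)
  At
}

#' Transition probabilities between nested partitions
#'
#' `P[i, j]` is the fraction of cluster i's members (at iteration t) that
#' belong to cluster j at iteration t+1. Condensation only merges, so the
#' later partition must coarsen the earlier one (each row has a single 1);
#' non-nested inputs are rejected.
#'
#' @param assign_t,assign_t1 cluster assignments over the same neuron set.
#' @return k_t x k_t1 row-stochastic matrix with cluster ids as dimnames.
#' @export
transition_probabilities <- function(assign_t, assign_t1) {
  stop_if(length(assign_t) != length(assign_t1),
          "assignments must cover the same neuron set")
  if (!is.null(names(assign_t)) && !is.null(names(assign_t1)))
    assign_t1 <- assign_t1[names(assign_t)]
  # numeric level order: must match the row order of cluster_affinity()
  tab <- table(factor(assign_t, levels = sort(unique(assign_t))),
               factor(assign_t1, levels = sort(unique(assign_t1))))
  P <- tab / rowSums(tab)
  if (any(rowSums(tab > 0) > 1))
    stop("assignments are not nested: some cluster splits between iterations",
         call. = FALSE)
  out <- matrix(as.numeric(P), nrow(P), ncol(P),
                dimnames = dimnames(tab))
  out
}

#' Assemble the C-PHATE block connectivity matrix
#'
#' One node per (iteration, cluster) across the whole condensation trace.
#' Diagonal blocks are the symmetric kernels of the block-aggregated
#' affinities; the (t, t+1) blocks carry `lag_weights[1]` times the
#' transition probabilities (mirrored by transposition), and the (t, t+2)
#' blocks `lag_weights[2]` times the composed two-step transitions. All
#' other off-diagonal blocks are zero. Iterations with no merge still
#' contribute nodes (identity transitions), so every condensation iteration
#' is represented; set `collapse_duplicates = TRUE` to drop consecutive
#' duplicate partitions instead.
#'
#' @param trace a [run_condensation()] trace.
#' @param A0 the original adjacency matrix the trace was computed from.
#' @param lag_weights weights for the lag-1 and lag-2 blocks (default
#'   `c(100, 30)`).
#' @param collapse_duplicates drop iterations whose partition equals the
#'   previous one.
#' @return an object of class `cphate_connectivity`: list with `values`
#'   (N x N symmetric matrix), `node_index` (data.frame `iteration`,
#'   `cluster`, `row`), `lag_weights`.
#' @export
build_connectivity <- function(trace, A0, lag_weights = c(100, 30),
                               collapse_duplicates = FALSE) {
  stopifnot(inherits(trace, "condensation_trace"))
  validate_adjacency(A0)
  iters <- trace$iterations
  stop_if(length(iters) < 1, "trace has no iterations")
  if (collapse_duplicates && length(iters) > 1) {
    keep <- c(TRUE, vapply(seq(2, length(iters)), function(i)
      !identical(unname(iters[[i]]$assignment),
                 unname(iters[[i - 1]]$assignment)), logical(1)))
    iters <- iters[keep]
  }
  Tn <- length(iters)
  Ks <- lapply(iters, function(itr) symmetric_kernel(
    cluster_affinity(itr$assignment, A0)))
  ks <- vapply(Ks, nrow, integer(1))
  Ps <- if (Tn > 1) lapply(seq_len(Tn - 1), function(t)
    transition_probabilities(iters[[t]]$assignment,
                             iters[[t + 1]]$assignment)) else list()
  N <- sum(ks)
  off <- c(0L, cumsum(ks))
  C <- matrix(0, N, N)
  node_index <- do.call(rbind, lapply(seq_len(Tn), function(t)
    data.frame(iteration = iters[[t]]$iteration,
               cluster = as.integer(rownames(Ks[[t]])),
               row = off[t] + seq_len(ks[t]))))
  for (t in seq_len(Tn)) {
    ix <- off[t] + seq_len(ks[t])
    C[ix, ix] <- Ks[[t]]
    if (t < Tn) {
      jx <- off[t + 1] + seq_len(ks[t + 1])
      B1 <- lag_weights[1] * Ps[[t]]
      C[ix, jx] <- B1
      C[jx, ix] <- t(B1)
    }
    if (t < Tn - 1) {
      kx <- off[t + 2] + seq_len(ks[t + 2])
      B2 <- lag_weights[2] * (Ps[[t]] %*% Ps[[t + 1]])
      C[ix, kx] <- B2
      C[kx, ix] <- t(B2)
    }
  }
  structure(list(values = C, node_index = node_index,
                 lag_weights = lag_weights, iterations = iters),
            class = "cphate_connectivity")
}

#' Default PHATE-family embedding backend
#'
#' Potential-distance embedding of a symmetric affinity matrix: row-normalize
#' to a Markov operator, diffuse for `diffusion_time` steps (computed by
#' repeated squaring), take the negative-log potential of the diffused
#' transition probabilities, and embed the pairwise potential distances in
#' `k` dimensions by classical multidimensional scaling. Deterministic for a
#' given input; the seed is consumed for interface compatibility with
#' stochastic backends.
#'
#' @param C symmetric nonnegative connectivity/affinity matrix.
#' @param diffusion_time number of diffusion steps (default 50).
#' @param seed integer seed (default 1).
#' @param k embedding dimension (default 3).
#' @return N x k coordinate matrix.
#' @export
phate_potential_backend <- function(C, diffusion_time = 50, seed = 1L, k = 3L) {
  stop_if(diffusion_time < 1, "diffusion_time must be >= 1")
  rs <- rowSums(C)
  stop_if(any(rs <= 0), "connectivity has zero row sums")
  set.seed(seed)
  P <- C / rs
  Pt <- diag(nrow(P))
  e <- as.integer(diffusion_time)
  B <- P
  while (e > 0) {
    if (e %% 2L == 1L) Pt <- Pt %*% B
    B <- B %*% B
    e <- e %/% 2L
  }
  U <- -log(Pt + 1e-12)   # diffusion potential; guard exact zeros
  Y <- stats::cmdscale(stats::dist(U), k = k)
  unname(Y)
}

#' Embed a C-PHATE connectivity matrix in 3-D
#'
#' Applies a PHATE-family embedding backend to the connectivity matrix. The
#' backend is pluggable: any function with the signature
#' `(C, diffusion_time, seed, k)` returning an N x 3 coordinate matrix can
#' be injected; [phate_potential_backend()] is the default.
#'
#' @param connectivity a [build_connectivity()] result.
#' @param diffusion_time PHATE diffusion time parameter (default 50).
#' @param seed integer seed (default 1); identical input and seed give
#'   identical coordinates.
#' @param backend embedding backend function.
#' @return an object of class `cphate_embedding`: list with `coords`
#'   (N x 3), `node_index`, `params`.
#' @export
cphate_embed <- function(connectivity, diffusion_time = 50, seed = 1L,
                         backend = phate_potential_backend) {
  stopifnot(inherits(connectivity, "cphate_connectivity"))
  stop_if(!is.function(backend),
          "no embedding backend available: supply a function (C, diffusion_time, seed, k)")
  coords <- backend(connectivity$values, diffusion_time = diffusion_time,
                    seed = seed, k = 3L)
  stop_if(!is.matrix(coords) || nrow(coords) != nrow(connectivity$values) ||
            ncol(coords) != 3 || any(!is.finite(coords)),
          "backend must return a finite N x 3 coordinate matrix")
  structure(list(coords = coords, node_index = connectivity$node_index,
                 params = list(diffusion_time = diffusion_time, seed = seed)),
            class = "cphate_embedding")
}

#' Node table for a C-PHATE embedding
#'
#' One record per embedded node: iteration, cluster id, comma-separated
#' member neuron names, x/y/z coordinates, and the stratum id of the node's
#' ancestor at the maximum-modularity iteration.
#'
#' @param embedding a [cphate_embed()] result.
#' @param trace the [run_condensation()] trace the connectivity was built
#'   from.
#' @return data.frame with columns `iteration`, `cluster`, `members`, `x`,
#'   `y`, `z`, `stratum`.
#' @export
export_cphate <- function(embedding, trace) {
  stopifnot(inherits(embedding, "cphate_embedding"),
            inherits(trace, "condensation_trace"))
  strata <- select_strata(trace)
  by_iter <- stats::setNames(trace$iterations,
                             vapply(trace$iterations, `[[`, integer(1), "iteration"))
  ni <- embedding$node_index
  members <- character(nrow(ni))
  stratum <- integer(nrow(ni))
  for (r in seq_len(nrow(ni))) {
    assign <- by_iter[[as.character(ni$iteration[r])]]$assignment
    mem <- names(assign)[assign == ni$cluster[r]]
    members[r] <- paste(mem, collapse = ",")
    # stratum of the cluster: before the max-modularity iteration each node
    # nests inside exactly one stratum; after it, clusters may union several
    # strata, in which case the majority stratum is reported (smallest id on
    # ties)
    stratum[r] <- as.integer(names(which.max(table(strata$partition[mem]))))
  }
  data.frame(iteration = ni$iteration, cluster = ni$cluster,
             members = members,
             x = embedding$coords[ni$row, 1],
             y = embedding$coords[ni$row, 2],
             z = embedding$coords[ni$row, 3],
             stratum = stratum)
}
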