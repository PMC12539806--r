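#' Gaussian affinity matrix
#'
#' `A_ij = exp(-d(x_i, x_j)^2 / (2 sigma^2))` with Euclidean `d`; the
#' diagonal is exactly 1 (zero self-distance).
#'
#' @param coords numeric matrix, one point per row.
#' @param sigma positive kernel bandwidth.
#' @return symmetric affinity matrix with unit diagonal.
#' @export
gaussian_affinity <- function(coords, sigma) {
  stop_if(sigma <= 0, "sigma must be > 0")
  D2 <- as.matrix(stats::dist(coords))^2
  A <- exp(-D2 / (2 * sigma^2))
  diag(A) <- 1
  A
}

#' Adaptive kernel bandwidth for the current centers
#'
#' Two bandwidth statistics over the current cluster centers, both
#' translation invariant and homogeneous of degree 1:
#' `"min"` (default), the smallest nonzero pairwise Euclidean distance,
#' used to initialize the condensation schedule so that diffusion acts
#' locally first; and `"median"`, the median nonzero pairwise distance.
#' If all pairwise distances are zero the caller must supply `last_sigma`
#' (the previous positive bandwidth), which is returned unchanged.
#'
#' @param coords numeric matrix of current centers (>= 2 rows).
#' @param rule `"min"` or `"median"`.
#' @param last_sigma fallback when all distances are zero.
#' @return positive bandwidth.
#' @export
adaptive_sigma <- function(coords, rule = c("min", "median"), last_sigma = NULL) {
  rule <- match.arg(rule)
  stop_if(nrow(coords) < 2, "need >= 2 rows (condensation already complete)")
  d <- stats::dist(coords)
  nz <- d[d > 0]
  if (length(nz) == 0) {
    stop_if(is.null(last_sigma), "all pairwise distances are zero and no last_sigma")
    return(last_sigma)
  }
  switch(rule, min = min(nz), median = stats::median(nz))
}

#' Row-stochastic diffusion operator
#'
#' `P = D^-1 A` where `D` is the diagonal degree matrix `D_ii = sum_j A_ij`.
#'
#' @param A symmetric nonnegative affinity matrix with positive row sums.
#' @return row-stochastic matrix.
#' @export
diffusion_operator <- function(A) {
  rs <- rowSums(A)
  bad <- which(rs <= 0)
  stop_if(length(bad) > 0,
          sprintf("zero row sum in affinity at row(s) %s",
                  paste(bad, collapse = ",")))
  A / rs
}

#' Apply one diffusion step
#'
#' `Y = P X`: every row of the output is a convex combination of the input
#' rows, smoothing the data along the affinity graph.
#'
#' @param P row-stochastic operator.
#' @param X data matrix (rows = current centers).
#' @return diffused matrix with `X`'s rownames.
#' @export
diffuse <- function(P, X) {
  stop_if(ncol(P) != nrow(X), "dimension mismatch between P and X")
  Y <- P %*% X
  rownames(Y) <- rownames(X)
  Y
}

#' Merge threshold epsilon
#'
#' `epsilon = max over coordinates of (max - min) / divisor`. The coordinate
#' range equals the maximum pairwise Chebyshev (infinity-norm) distance, so
#' the range-based and the max-pairwise formulations coincide. Computed once
#' after the first diffusion step and then held fixed for the run.
#'
#' @param Y diffused data matrix with >= 2 distinct rows.
#' @param divisor positive divisor (default 10000).
#' @return scalar epsilon.
#' @export
compute_epsilon <- function(Y, divisor = 10000) {
  stop_if(divisor <= 0, "divisor must be > 0")
  rng <- apply(Y, 2, function(col) diff(range(col)))
  stop_if(max(rng) == 0, "all rows identical: degenerate input")
  max(rng) / divisor
}

#' One condensation step
#'
#' Groups the current rows by connected components of the graph with an edge
#' wherever the Euclidean distance is `< epsilon` (transitive merging), and
#' replaces each group by the unweighted mean of its members.
#'
#' @param Y numeric matrix of current centers.
#' @param epsilon positive merge threshold.
#' @return list with `partition` (integer component id per input row) and
#'   `coords` (new center matrix, one row per component).
#' @export
condense_step <- function(Y, epsilon) {
  stop_if(epsilon <= 0, "epsilon must be > 0")
  D <- as.matrix(stats::dist(Y))
  comp <- connected_components(D < epsilon)
  coords <- do.call(rbind, lapply(split(seq_len(nrow(Y)), comp), function(ix)
    colMeans(Y[ix, , drop = FALSE])))
  rownames(coords) <- NULL
  list(partition = comp, coords = coords)
}

#' Weighted graph modularity of a partition
#'
#' `e_M = (1/2m) sum_ij (A_ij - d_i d_j / 2m) delta(pi_i, pi_j)` with
#' `d_i = sum_j A_ij` and `m = sum_ij A_ij / 2`, always evaluated on the
#' fixed original adjacency graph so that scores are comparable across
#' condensation iterations.
#'
#' @param assignment cluster id per node, aligned with (or named by) the
#'   rows of `A0`.
#' @param A0 symmetric nonnegative adjacency matrix (zero diagonal assumed;
#'   any diagonal is ignored).
#' @return modularity score.
#' @export
modularity_score <- function(assignment, A0) {
  A <- A0
  diag(A) <- 0
  if (!is.null(names(assignment)) && !is.null(rownames(A)))
    assignment <- assignment[rownames(A)]
  stop_if(length(assignment) != nrow(A),
          "assignment must cover every node of A0")
  d <- rowSums(A)
  m <- sum(A) / 2
  stop_if(m <= 0, "total edge weight must be > 0")
  same <- outer(assignment, assignment, "==")
  sum((A - outer(d, d) / (2 * m)) * same) / (2 * m)
}

#' Condensation parameters
#'
#' @param epsilon_divisor divisor for the merge threshold (default 10000).
#' @param max_iterations iteration cap (default 1000); hitting it raises a
#'   warning and returns a non-converged trace.
#' @param sigma_growth multiplicative bandwidth inflation applied after any
#'   iteration that produces no merge (default 1.1). The bandwidth starts at
#'   the smallest nonzero pairwise distance (see [adaptive_sigma()]) so the
#'   first diffusion steps act locally, and grows only when condensation
#'   stalls.
#' @param sigma_init `"min"` or `"median"`, the [adaptive_sigma()] rule used
#'   for the starting bandwidth.
#' @return an object of class `condensation_params`.
#' @export
condensation_params <- function(epsilon_divisor = 10000,
                                max_iterations = 1000L,
                                sigma_growth = 1.1,
                                sigma_init = c("min", "median")) {
  stop_if(epsilon_divisor <= 0, "epsilon_divisor must be > 0")
  stop_if(max_iterations < 1, "max_iterations must be >= 1")
  stop_if(sigma_growth < 1, "sigma_growth must be >= 1")
  structure(list(epsilon_divisor = epsilon_divisor,
                 max_iterations = as.integer(max_iterations),
                 sigma_growth = sigma_growth,
                 sigma_init = match.arg(sigma_init)),
            class = "condensation_params")
}

#' Run diffusion condensation on an adjacency matrix
#'
#' Each neuron starts as its own point with coordinates equal to its
#' adjacency profile (its row of `A0`). Iteratively: compute the Gaussian
#' affinity among current centers at the current bandwidth, row-normalize to
#' a diffusion operator, diffuse, and merge centers closer than epsilon
#' (computed once from the first diffused configuration as max coordinate
#' range / divisor). After every iteration the induced partition of the
#' original neurons and its modularity on `A0` are recorded. The loop stops
#' when a single cluster remains or `max_iterations` is reached.
#'
#' @param A0 labeled symmetric nonnegative adjacency matrix (n >= 2).
#' @param params a [condensation_params()].
#' @return an object of class `condensation_trace`: list with `iterations`
#'   (each with `iteration` (0-based; 0 is the initial singleton state),
#'   `assignment` (named integer vector over original neurons),
#'   `n_clusters`, `modularity`, `sigma`), `epsilon`, `labels`, `converged`.
#' @export
run_condensation <- function(A0, params = condensation_params()) {
  validate_adjacency(A0)
  stop_if(nrow(A0) < 2, "need at least 2 neurons")
  stopifnot(inherits(params, "condensation_params"))
  labels <- rownames(A0)
  n <- nrow(A0)
  X <- A0                      # adjacency profiles as initial coordinates
  memb <- seq_len(n)           # original neuron -> current row of X
  sigma <- adaptive_sigma(X, rule = params$sigma_init)
  epsilon <- NULL
  iters <- list(list(iteration = 0L,
                     assignment = stats::setNames(memb, labels),
                     n_clusters = n,
                     modularity = modularity_score(memb, A0),
                     sigma = NA_real_))
  it <- 0L
  while (length(unique(memb)) > 1 && it < params$max_iterations) {
    it <- it + 1L
    A <- gaussian_affinity(X, sigma)
    P <- diffusion_operator(A)
    Y <- diffuse(P, X)
    if (is.null(epsilon))
      epsilon <- compute_epsilon(Y, params$epsilon_divisor)
    step <- condense_step(Y, epsilon)
    merged <- nrow(step$coords) < nrow(Y)
    memb <- step$partition[memb]
    X <- step$coords
    iters[[length(iters) + 1L]] <-
      list(iteration = it,
           assignment = stats::setNames(memb, labels),
           n_clusters = nrow(X),
           modularity = modularity_score(memb, A0),
           sigma = sigma)
    if (!merged) sigma <- sigma * params$sigma_growth
  }
  converged <- length(unique(memb)) == 1
  if (!converged)
    ctm_warn("CTM_NO_CONVERGENCE",
             sprintf("condensation stopped at %d clusters after %d iterations",
                     length(unique(memb)), it))
  structure(list(iterations = iters, epsilon = epsilon,
                 labels = labels, converged = converged),
            class = "condensation_trace")
}

#' @export
print.condensation_trace <- function(x, ...) {
  ks <- vapply(x$iterations, `[[`, integer(1), "n_clusters")
  cat(sprintf(
    "condensation_trace: %d neurons, %d iterations (%s), epsilon %.3g\n",
    length(x$labels), length(x$iterations) - 1,
    if (x$converged) "converged" else "NOT converged", x$epsilon))
  cat("  cluster counts:", paste(ks, collapse = " "), "\n")
  invisible(x)
}

#' Select strata at the highest-modularity iteration
#'
#' Returns the partition recorded at the iteration with the maximum
#' modularity score (the iteration of highest clustering confidence); ties
#' are broken by the earliest such iteration.
#'
#' @param trace a [run_condensation()] trace.
#' @return an object of class `strata_result`: list with `partition` (named
#'   stratum id per neuron), `iteration_index` (0-based), `modularity`,
#'   `n_strata`.
#' @export
select_strata <- function(trace) {
  stopifnot(inherits(trace, "condensation_trace"))
  stop_if(length(trace$iterations) == 0, "empty trace")
  mods <- vapply(trace$iterations, `[[`, numeric(1), "modularity")
  best <- which.max(mods)   # which.max takes the first maximum
  itr <- trace$iterations[[best]]
  structure(list(partition = itr$assignment,
                 iteration_index = itr$iteration,
                 modularity = itr$modularity,
                 n_strata = itr$n_clusters),
            class = "strata_result")
}

#' Cluster flows between consecutive iterations (Sankey export)
#'
#' One row per (source cluster at iteration t, target cluster at t+1) pair
#' with the number of neurons flowing; flows out of each source sum to its
#' size, so each step conserves the neuron count.
#'
#' @param trace a [run_condensation()] trace.
#' @return data.frame with columns `iteration_from`, `iteration_to`,
#'   `source`, `target`, `n_neurons`.
#' @export
sankey_flows <- function(trace) {
  stopifnot(inherits(trace, "condensation_trace"))
  out <- list()
  for (i in seq_len(length(trace$iterations) - 1)) {
    a <- trace$iterations[[i]]
    b <- trace$iterations[[i + 1]]
    tab <- table(a$assignment, b$assignment)
    nz <- which(tab > 0, arr.ind = TRUE)
    out[[i]] <- data.frame(
      iteration_from = a$iteration,
      iteration_to = b$iteration,
      source = as.integer(rownames(tab)[nz[, 1]]),
      target = as.integer(colnames(tab)[nz[, 2]]),
      n_neurons = as.integer(tab[nz]))
  }
  do.call(rbind, out)
}
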