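test_that("Gaussian affinity reproduces its closed forms", {
  x <- rbind(c(0, 0), c(3, 4))  # distance 5
  A <- gaussian_affinity(x, sigma = 5)
  expect_equal(A[1, 2], exp(-1 / 2))
  expect_equal(unname(diag(A)), c(1, 1))
  A2 <- gaussian_affinity(x, sigma = 5 / sqrt(2 * log(2)))
  expect_equal(A2[1, 2], 0.5)
  same <- gaussian_affinity(rbind(c(1, 1), c(1, 1)), 2)
  expect_equal(unname(same), matrix(1, 2, 2))
  expect_error(gaussian_affinity(x, 0), "sigma")
})

test_that("adaptive sigma is translation invariant and homogeneous", {
  x <- rbind(c(0, 0), c(4, 0))
  expect_equal(adaptive_sigma(x, "min"), 4)
  expect_equal(adaptive_sigma(x, "median"), 4)
  y <- matrix(rnorm(20, sd = 3), 10, 2)
  for (rule in c("min", "median")) {
    expect_equal(adaptive_sigma(y + 100, rule), adaptive_sigma(y, rule))
    expect_equal(adaptive_sigma(y * 3, rule), 3 * adaptive_sigma(y, rule))
  }
  expect_error(adaptive_sigma(matrix(1, 1, 2)), "complete")
  expect_equal(adaptive_sigma(matrix(1, 3, 2), last_sigma = 0.7), 0.7)
})

test_that("the diffusion operator is the degree-normalized affinity", {
  expect_equal(diffusion_operator(diag(3)), diag(3))
  expect_equal(diffusion_operator(matrix(1, 2, 2)), matrix(0.5, 2, 2))
  set.seed(1)
  A <- matrix(runif(36), 6, 6)
  A <- A + t(A)
  expect_equal(unname(rowSums(diffusion_operator(A))), rep(1, 6))
  bad <- diag(3)
  bad[2, ] <- 0
  expect_error(diffusion_operator(bad), "row\\(s\\) 2")
})

test_that("diffusion smooths as a convex combination of rows", {
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(diffuse(diag(5), X), X, ignore_attr = TRUE)
  U <- matrix(1 / 5, 5, 5)
  Y <- diffuse(U, X)
  expect_equal(unname(Y), matrix(colMeans(X), 5, 3, byrow = TRUE))
  set.seed(2)
  P <- diffusion_operator(gaussian_affinity(X, 1))
  Y2 <- diffuse(P, X)
  for (j in 1:3) {
    expect_gte(min(Y2[, j]), min(X[, j]))
    expect_lte(max(Y2[, j]), max(X[, j]))
  }
  expect_error(diffuse(diag(4), X), "mismatch")
})

test_that("epsilon is the max coordinate range over the divisor", {
  Y <- rbind(c(0, 0, 0), c(2, 5, 3))
  expect_equal(compute_epsilon(Y), 5e-4)
  expect_equal(compute_epsilon(Y, divisor = 1), 5)
  # the range formulation equals the max pairwise Chebyshev distance
  set.seed(3)
  for (rep in 1:5) {
    Z <- matrix(rnorm(40), 8, 5)
    cheb <- 0
    for (i in 1:7) for (j in (i + 1):8)
      cheb <- max(cheb, max(abs(Z[i, ] - Z[j, ])))
    expect_equal(compute_epsilon(Z), cheb / 10000)
  }
  expect_error(compute_epsilon(matrix(1, 3, 2)), "degenerate")
})

test_that("condensation merges transitively through epsilon chains", {
  Y <- rbind(a = c(0, 0), b = c(0.9, 0), c = c(1.8, 0))
  st <- condense_step(Y, epsilon = 1)
  expect_equal(st$partition, c(1L, 1L, 1L))  # a-b and b-c chain into one
  expect_equal(unname(st$coords), matrix(c(0.9, 0), 1, 2))
  far <- condense_step(Y, epsilon = 0.5)
  expect_equal(far$partition, 1:3)
  expect_equal(unname(far$coords), unname(Y))
  dup <- condense_step(rbind(c(1, 2), c(1, 2)), epsilon = 0.1)
  expect_equal(dup$partition, c(1L, 1L))
  expect_equal(unname(dup$coords), matrix(c(1, 2), 1, 2))
})

test_that("modularity matches the double-loop and igraph oracles", {
  # single all-encompassing cluster scores exactly zero
  set.seed(4)
  A <- matrix(runif(25), 5, 5)
  A <- A + t(A)
  diag(A) <- 0
  expect_equal(modularity_score(rep(1, 5), A), 0)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    A <- matrix(runif(n * n), n, n) * matrix(rbinom(n * n, 1, 0.6), n, n)
    A <- A + t(A)
    diag(A) <- 0
    memb <- sample(1:3, n, replace = TRUE)
    got <- modularity_score(memb, A)
    expect_equal(got, oracle_modularity(memb, A), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(got,
                 igraph::modularity(g, membership = memb,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-9)
  }
  expect_error(modularity_score(rep(1, 3), matrix(0, 3, 3)), "edge weight")
})

test_that("condensation terminates at one cluster with nested coarsenings", {
  pa <- planted_4x10(seed = 7)
  tr <- run_condensation(pa$adjacency)
  expect_true(tr$converged)
  ks <- vapply(tr$iterations, `[[`, integer(1), "n_clusters")
  expect_equal(ks[1], 40L)
  expect_equal(ks[length(ks)], 1L)
  expect_true(all(diff(ks) <= 0))
  for (i in seq_len(length(tr$iterations) - 1)) {
    a <- tr$iterations[[i]]$assignment
    b <- tr$iterations[[i + 1]]$assignment
    # each earlier cluster maps into exactly one later cluster
    expect_true(all(tapply(b, a, function(v) length(unique(v))) == 1))
  }
})

test_that("max-modularity strata recover planted blocks exactly", {
  for (seed in c(7, 21, 99)) {
    pa <- planted_4x10(seed)
    st <- select_strata(run_condensation(pa$adjacency))
    expect_equal(st$n_strata, 4L)
    expect_equal(ari(st$partition, pa$ground_truth), 1)
  }
})

test_that("condensation is equivariant under neuron permutation", {
  pa <- planted_4x10(seed = 13)
  st <- select_strata(run_condensation(pa$adjacency))
  set.seed(5)
  perm <- sample(nrow(pa$adjacency))
  Ap <- pa$adjacency[perm, perm]
  stp <- select_strata(run_condensation(Ap))
  # same partition of the same neuron names
  expect_equal(ari(st$partition[names(stp$partition)], stp$partition), 1)
})

test_that("well-separated blobs condense internally before any cross merge", {
  pc <- make_point_cloud(rbind(c(0, 0), c(50, 50)), n_per_blob = 6,
                         sd = 0.5, seed = 8)
  blob <- attr(pc, "blob")
  # run the condensation loop from the primitives on raw coordinates
  X <- pc
  memb <- seq_len(nrow(X))
  sigma <- adaptive_sigma(X, "min")
  epsilon <- NULL
  for (it in 1:200) {
    if (length(unique(memb)) == 1) break
    P <- diffusion_operator(gaussian_affinity(X, sigma))
    Y <- diffuse(P, X)
    if (is.null(epsilon)) epsilon <- compute_epsilon(Y)
    st <- condense_step(Y, epsilon)
    merged <- nrow(st$coords) < nrow(Y)
    memb <- st$partition[memb]
    X <- st$coords
    if (!merged) sigma <- sigma * 1.1
    # any cluster containing both blobs must already contain every point:
    # cross-blob merging only happens after each blob condensed internally
    per_cluster <- tapply(blob, memb, function(v) length(unique(v)))
    mixed <- names(per_cluster)[per_cluster > 1]
    for (cl in mixed) expect_equal(sum(memb == as.integer(cl)), length(blob))
  }
  expect_equal(length(unique(memb)), 1L)  # terminated at one cluster
})

test_that("strata selection breaks modularity ties at the earliest iteration", {
  mk_iter <- function(i, assign, mod) list(iteration = i,
                                           assignment = assign,
                                           n_clusters = length(unique(assign)),
                                           modularity = mod, sigma = 1)
  a0 <- stats::setNames(1:4, letters[1:4])
  a1 <- stats::setNames(c(1L, 1L, 2L, 3L), letters[1:4])
  a2 <- stats::setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  a3 <- stats::setNames(rep(1L, 4), letters[1:4])
  trace <- structure(list(iterations = list(mk_iter(0L, a0, 0.1),
                                            mk_iter(1L, a1, 0.4),
                                            mk_iter(2L, a2, 0.4),
                                            mk_iter(3L, a3, 0.2)),
                          epsilon = 1, labels = letters[1:4],
                          converged = TRUE),
                     class = "condensation_trace")
  st <- select_strata(trace)
  expect_equal(st$iteration_index, 1L)
  expect_equal(st$modularity, 0.4)
  expect_equal(st$n_strata, 3L)
  single <- structure(list(iterations = list(mk_iter(0L, a0, 0.1)),
                           epsilon = 1, labels = letters[1:4],
                           converged = FALSE),
                      class = "condensation_trace")
  expect_equal(select_strata(single)$iteration_index, 0L)
})

test_that("Sankey flows conserve the neuron count at every step", {
  pa <- planted_4x10(seed = 3)
  tr <- run_condensation(pa$adjacency)
  fl <- sankey_flows(tr)
  for (i in unique(fl$iteration_from)) {
    expect_equal(sum(fl$n_neurons[fl$iteration_from == i]), 40L)
  }
  # a no-merge step has purely diagonal flows (source count = target count)
  ks <- vapply(tr$iterations, `[[`, integer(1), "n_clusters")
  flat <- which(diff(ks) == 0)
  if (length(flat) > 0) {
    i0 <- tr$iterations[[flat[1]]]$iteration
    sub <- fl[fl$iteration_from == i0, ]
    expect_equal(nrow(sub), ks[flat[1]])
  }
  # two pairs merging into one cluster contribute flows (c1 -> m, 2), (c2 -> m, 2)
  a1 <- stats::setNames(c(1L, 1L, 2L, 2L), letters[1:4])
  a2 <- stats::setNames(rep(1L, 4), letters[1:4])
  mk <- function(i, assign) list(iteration = i, assignment = assign,
                                 n_clusters = length(unique(assign)),
                                 modularity = 0, sigma = 1)
  tr2 <- structure(list(iterations = list(mk(0L, a1), mk(1L, a2)),
                        epsilon = 1, labels = letters[1:4], converged = TRUE),
                   class = "condensation_trace")
  fl2 <- sankey_flows(tr2)
  expect_equal(nrow(fl2), 2L)
  expect_equal(fl2$n_neurons, c(2L, 2L))
  expect_equal(fl2$target, c(1L, 1L))
})

test_that("a warning marks hitting the iteration cap", {
  pa <- planted_4x10(seed = 2)
  expect_warning(
    tr <- run_condensation(pa$adjacency,
                           condensation_params(max_iterations = 2)),
    "CTM_NO_CONVERGENCE")
  expect_false(tr$converged)
  expect_error(run_condensation(pa$adjacency[1, 1, drop = FALSE]))
})
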