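#' @keywords internal
"_PACKAGE"

# round-half-up; base round() is round-half-even, which would map 10.5 px -> 10
round_half_up <- function(x) floor(x + 0.5)

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# connected components of a logical symmetric relation matrix (diagonal ignored)
connected_components <- function(rel) {
  n <- nrow(rel)
  diag(rel) <- TRUE
  comp <- seq_len(n)
  repeat {
    newc <- apply(rel, 1L, function(r) min(comp[r]))
    if (all(newc == comp)) break
    comp <- newc
  }
  as.integer(factor(comp, levels = unique(comp)))
}

# dense rank: largest value gets rank 1, ties share a rank, ranks are consecutive
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}

# machine-parsable warning codes on stderr (CTM = contactome)
ctm_warn <- function(code, msg) {
  warning(sprintf("[%s] %s", code, msg), call. = FALSE)
}

is_square_symmetric <- function(A, tol = 0) {
  is.matrix(A) && nrow(A) == ncol(A) &&
    (if (tol == 0) identical(A, t(A)) else max(abs(A - t(A))) <= tol)
}

# validate a labeled symmetric nonnegative adjacency matrix with zero diagonal
validate_adjacency <- function(A) {
  stop_if(!is.matrix(A) || !is.numeric(A), "adjacency must be a numeric matrix")
  stop_if(nrow(A) != ncol(A), "adjacency must be square")
  stop_if(is.null(rownames(A)) || is.null(colnames(A)),
          "adjacency must carry row and column labels")
  stop_if(!identical(rownames(A), colnames(A)),
          "adjacency row and column labels must match")
  stop_if(anyDuplicated(rownames(A)) > 0, "duplicate adjacency labels")
  stop_if(any(A < 0), "adjacency entries must be nonnegative")
  stop_if(max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))),
          "adjacency must be symmetric")
  invisible(A)
}
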