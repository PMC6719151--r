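#' Construct an h-uniform fuzzy partition with raised-cosine basic functions
#'
#' Builds the scaffold for the discrete fuzzy transform: `n` equidistant
#' nodes `x_k = a + h (k - 1)` spanning `[a, b]` with spacing
#' `h = (b - a) / (n - 1)`, each carrying a raised-cosine basic function
#' `A_k(x) = 0.5 (1 + cos(pi (x - x_k) / h))` supported on
#' `[x_{k-1}, x_{k+1}]` (half support at the two boundary nodes). The family
#' satisfies normality at the nodes, local support, strict monotonicity on
#' each half-support, the partition of unity, and shift symmetry.
#'
#' @param a Domain lower bound.
#' @param b Domain upper bound; must exceed `a`.
#' @param n Number of nodes; at least 3.
#' @return An object of class `fuzzy_partition` with elements `a`, `b`,
#'   `n`, `h` and `nodes`.
#' @examples
#' p <- fuzzy_partition(0, 4, 5)
#' p$nodes         # 0 1 2 3 4
#' basis_value(p, 2, 1)   # 1: normality at the node
#' @export
fuzzy_partition <- function(a, b, n) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      !is.finite(a) || !is.finite(b) || b <= a)
    stop("'a' and 'b' must be finite numbers with b > a")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 3L)
    stop("'n' must be an integer >= 3")
  h <- (b - a) / (n - 1)
  structure(
    list(a = a, b = b, n = n, h = h, nodes = a + h * (seq_len(n) - 1)),
    class = "fuzzy_partition"
  )
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf(
    "h-uniform fuzzy partition of [%g, %g]: %d raised-cosine nodes, h = %g\n",
    x$a, x$b, x$n, x$h))
  invisible(x)
}

#' Evaluate one basic function of a fuzzy partition
#'
#' Returns the membership `A_k(x)` of the raised-cosine basic function
#' attached to node `k`. Outside its support (and outside `[a, b]`) the
#' value is 0; the function is total in `x` so callers that must reject
#' out-of-domain points do so themselves. Values are clipped to `[0, 1]`
#' to absorb floating-point rounding at the support edges.
#'
#' @param partition A [fuzzy_partition()].
#' @param k Node index in `1..n`.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of memberships in `[0, 1]`.
#' @export
basis_value <- function(partition, k, x) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > partition$n)
    stop(sprintf("node index k = %s out of range 1..%d", k, partition$n))
  d <- (x - partition$nodes[k]) / partition$h
  v <- ifelse(abs(d) <= 1, 0.5 * (1 + cospi(d)), 0)
  v[x < partition$a | x > partition$b] <- 0
  pmin(pmax(v, 0), 1)
}

#' Membership matrix of a fuzzy partition
#'
#' Evaluates all `n` basic functions at each point, returning the
#' `length(x) x n` matrix `A[i, k] = A_k(x_i)`. Rows for points inside
#' `[a, b]` sum to 1 (partition of unity); rows for outside points are 0.
#'
#' @inheritParams basis_value
#' @return Numeric matrix with one column per node.
#' @export
basis_matrix <- function(partition, x) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  d <- outer(x, partition$nodes, `-`) / partition$h
  v <- 0.5 * (1 + cospi(d))
  v[abs(d) > 1] <- 0
  v[x < partition$a | x > partition$b, ] <- 0
  pmin(pmax(v, 0), 1)
}

#' Test sufficient density of a point set with respect to a partition
#'
#' A point set is sufficiently dense when every basic function covers at
#' least one point with strictly positive membership — the solvability
#' condition for the discrete direct transforms (every component average
#' has a non-empty weight set).
#'
#' @inheritParams basis_value
#' @param points Nonempty numeric vector of sample abscissae in `[a, b]`.
#' @return A list with `dense` (logical) and `first_failing_node` (the
#'   smallest uncovered node index, or `NA` when dense).
#' @export
is_sufficiently_dense <- function(partition, points) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (length(points) == 0L) stop("'points' must be nonempty")
  covered <- colSums(basis_matrix(partition, points) > 0) > 0
  if (all(covered)) {
    list(dense = TRUE, first_failing_node = NA_integer_)
  } else {
    list(dense = FALSE, first_failing_node = which(!covered)[1L])
  }
}
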