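#' Discrete direct F-transform (order 0)
#'
#' Maps sampled values of a function to one component per node of the
#' partition, `F_k = sum_i f(p_i) A_k(p_i) / sum_i A_k(p_i)` — a
#' membership-weighted local average. Requires the sample to be
#' sufficiently dense with respect to the partition so every denominator
#' is positive.
#'
#' @param partition A [fuzzy_partition()].
#' @param points Sample abscissae in `[a, b]`.
#' @param values Sampled function values, same length as `points`.
#' @return An object of class `f0_components` with element `F` (one
#'   component per node).
#' @export
f_transform <- function(partition, points, values) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (length(points) != length(values))
    stop("'points' and 'values' must have the same length")
  dens <- is_sufficiently_dense(partition, points)
  if (!dens$dense)
    stop(sprintf("points are not sufficiently dense: node %d is uncovered",
                 dens$first_failing_node))
  A <- basis_matrix(partition, points)
  structure(list(F = as.vector(crossprod(A, values) / colSums(A))),
            class = "f0_components")
}

#' Discrete inverse F-transform (order 0)
#'
#' Reconstructs an approximation of the sampled function as the
#' membership-weighted combination `sum_k F_k A_k(x)`.
#'
#' @inheritParams f_transform
#' @param components An `f0_components` object from [f_transform()].
#' @param x Evaluation points; must lie in `[a, b]`.
#' @return Numeric vector of reconstructed values.
#' @export
inverse_f_transform <- function(partition, components, x) {
  stopifnot(inherits(partition, "fuzzy_partition"),
            inherits(components, "f0_components"))
  if (any(x < partition$a | x > partition$b))
    stop("evaluation points must lie within the partition domain [a, b]")
  as.vector(basis_matrix(partition, x) %*% components$F)
}

#' Discrete F1-transform components
#'
#' Order-1 extension of the direct transform: for each node the local
#' model is a line `F1_k(x) = c0_k + c1_k (x - x_k)`. The intercepts
#' `c0_k` coincide with the order-0 components; the slopes are
#' `c1_k = sum_i f(p_i)(p_i - x_k) A_k(p_i) / sum_i (p_i - x_k)^2 A_k(p_i)`,
#' a weighted least-squares slope through the node. When every covering
#' point sits exactly at the node the slope is unidentifiable and is set
#' to 0, falling back to the order-0 behaviour.
#'
#' @inheritParams f_transform
#' @return An object of class `f1_components` with elements `c0` and `c1`.
#' @export
f1_transform <- function(partition, points, values) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (length(points) != length(values))
    stop("'points' and 'values' must have the same length")
  dens <- is_sufficiently_dense(partition, points)
  if (!dens$dense)
    stop(sprintf("points are not sufficiently dense: node %d is uncovered",
                 dens$first_failing_node))
  A <- basis_matrix(partition, points)
  c0 <- as.vector(crossprod(A, values) / colSums(A))
  D <- outer(points, partition$nodes, `-`)
  num <- colSums(values * D * A)
  den <- colSums(D * D * A)
  c1 <- ifelse(den > 0, num / den, 0)
  # den == 0 => every covering point is at the node: slope unidentifiable
  structure(list(c0 = c0, c1 = as.vector(c1)), class = "f1_components")
}

#' Evaluate a single F1 component
#'
#' The k-th local linear model `F1_k(x) = c0_k + c1_k (x - x_k)`.
#'
#' @inheritParams inverse_f_transform
#' @param components An `f1_components` object.
#' @param k Node index in `1..n`.
#' @export
f1_component_eval <- function(components, partition, k, x) {
  stopifnot(inherits(components, "f1_components"),
            inherits(partition, "fuzzy_partition"))
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > partition$n)
    stop(sprintf("node index k = %s out of range 1..%d", k, partition$n))
  components$c0[k] + components$c1[k] * (x - partition$nodes[k])
}

#' Discrete inverse F1-transform
#'
#' Reconstructs the function as the membership-weighted combination of the
#' local lines, `sum_k F1_k(x) A_k(x) / sum_k A_k(x)`. On `[a, b]` the
#' denominator is identically 1 for this basis family (partition of
#' unity); it is kept explicitly so the formula stays valid for any
#' partition satisfying the density requirement, and points where it
#' vanishes (outside the domain) raise an error.
#'
#' @inheritParams inverse_f_transform
#' @param components An `f1_components` object from [f1_transform()].
#' @export
inverse_f1_transform <- function(partition, components, x) {
  stopifnot(inherits(partition, "fuzzy_partition"),
            inherits(components, "f1_components"))
  A <- basis_matrix(partition, x)
  s <- rowSums(A)
  if (any(s == 0))
    stop("inverse F1-transform undefined where no basic function is positive (x outside [a, b])")
  num <- A %*% components$c0 +
    (A * outer(x, partition$nodes, `-`)) %*% components$c1
  as.vector(num) / s
}
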