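test_that("direct F-transform components are membership-weighted averages", {
  p <- fuzzy_partition(0, 2, 3)
  pts <- c(0, 0.5, 1, 1.5, 2)

  # constant function: every component equals the constant
  f0 <- f_transform(p, pts, rep(7, 5))
  expect_equal(f0$F, rep(7, 3))

  # identity function: hand-computed sums
  f0 <- f_transform(p, pts, pts)
  expect_equal(f0$F[2], 1)
  expect_equal(f0$F[1], 1 / 6)

  expect_error(f_transform(p, pts, 1:3), "same length")
  expect_error(f_transform(p, c(0, 2), c(0, 2)), "node 2")
})

test_that("inverse F-transform reconstructs at nodes and midpoints", {
  p <- fuzzy_partition(0, 4, 5)
  comps <- structure(list(F = c(2, 4, 6, 8, 10)), class = "f0_components")
  expect_equal(inverse_f_transform(p, comps, p$nodes), comps$F)
  expect_equal(inverse_f_transform(p, comps, 0.5), 3)   # 0.5*2 + 0.5*4
  const <- structure(list(F = rep(3.3, 5)), class = "f0_components")
  expect_equal(inverse_f_transform(p, const, runif(20, 0, 4)), rep(3.3, 20))
  expect_error(inverse_f_transform(p, comps, 4.5), "domain")
})

test_that("F1 slopes recover linear structure and vanish by symmetry", {
  p <- fuzzy_partition(0, 2, 3)
  pts <- c(0, 0.5, 1, 1.5, 2)
  c1 <- f1_transform(p, pts, pts)
  expect_equal(c1$c1[2], 1)                 # interior slope of identity, exact

  # constant f: interior slopes vanish by support symmetry; the boundary
  # slopes do not — the Eq. slope is an uncentred projection onto (x - x_k),
  # and over a half support sum((p - x_k) A_k(p)) != 0. Oracle-frozen values.
  c5 <- f1_transform(p, pts, rep(5, 5))
  expect_equal(c5$c0, rep(5, 3))
  expect_equal(c5$c1, c(10, 0, -10))

  psym <- fuzzy_partition(-1, 1, 3)
  sq <- f1_transform(psym, c(-1, -0.5, 0, 0.5, 1), c(1, 0.25, 0, 0.25, 1))
  expect_equal(sq$c1[2], 0)                 # odd integrand cancels at x2 = 0
})

test_that("F1 component evaluation is the local line", {
  p <- fuzzy_partition(0, 2, 3)
  comps <- structure(list(c0 = c(2, 2, 2), c1 = c(3, 3, 0)), class = "f1_components")
  expect_equal(f1_component_eval(comps, p, 2, p$nodes[2]), 2)
  expect_equal(f1_component_eval(comps, p, 1, 0.5), 3.5)
  expect_equal(f1_component_eval(comps, p, 3, c(1.5, 2)), c(2, 2))
  expect_error(f1_component_eval(comps, p, 4, 1), "out of range")
})

test_that("zero slope denominator falls back to the order-0 component", {
  # all points covering the middle node sit exactly at it
  p <- fuzzy_partition(0, 2, 3)
  pts <- c(0, 1, 2)
  comps <- f1_transform(p, pts, c(5, 9, 13))
  expect_equal(comps$c1[2], 0)
  expect_equal(comps$c0[2], 9)
})

test_that("F0/F1 components match the naive double-loop oracle", {
  set.seed(99)
  for (rep in 1:50) {
    a <- runif(1, -3, 3); b <- a + runif(1, 1, 8); n <- sample(3:10, 1)
    m <- sample(20:200, 1)
    pts <- sort(runif(m, a, b))
    pts[1] <- a; pts[m] <- b
    vals <- rnorm(m)
    p <- fuzzy_partition(a, b, n)
    if (!is_sufficiently_dense(p, pts)$dense) next
    f0 <- f_transform(p, pts, vals)
    f1 <- f1_transform(p, pts, vals)
    expect_lt(max(abs(f0$F - oracle_f0(a, b, n, pts, vals))), 1e-12)
    expect_lt(max(abs(f1$c0 - oracle_f0(a, b, n, pts, vals))), 1e-12)
    expect_lt(max(abs(f1$c1 - oracle_f1_slopes(a, b, n, pts, vals))), 1e-12)
    x <- runif(5, a, b)
    expect_lt(max(abs(inverse_f1_transform(p, f1, x) -
                      sapply(x, function(xx)
                        oracle_inverse_f1(a, b, n, f1$c0, f1$c1, xx)))), 1e-12)
  }
})

test_that("order-0 reconstruction error decreases with n (convergence)", {
  m <- 2000
  pts <- seq(0, 2 * pi, length.out = m)
  f <- sin(pts)
  inner <- pts >= 0.1 * 2 * pi & pts <= 0.9 * 2 * pi
  errs_full <- errs_inner <- numeric(0)
  for (n in c(5, 9, 17, 33)) {
    p <- fuzzy_partition(0, 2 * pi, n)
    rec <- inverse_f_transform(p, f_transform(p, pts, f), pts)
    errs_full <- c(errs_full, max(abs(f - rec)))
    errs_inner <- c(errs_inner, max(abs(f - rec)[inner]))
  }
  expect_true(all(diff(errs_full) < 0))
  expect_true(all(diff(errs_inner) < 0))
  # oracle-frozen levels at n = 33 (boundary components use half supports,
  # so the full-domain error is edge-dominated)
  expect_lt(errs_full[4], 0.06)
  expect_lt(errs_inner[4], 0.022)
})

test_that("F1 slopes approximate the derivative with order >= 1 in h", {
  m <- 2000
  pts <- seq(0, 2 * pi, length.out = m)
  f <- sin(pts)
  errs <- sapply(c(9, 17, 33), function(n) {
    p <- fuzzy_partition(0, 2 * pi, n)
    comps <- f1_transform(p, pts, f)
    interior <- 2:(n - 1)
    max(abs(comps$c1[interior] - cos(p$nodes[interior])))
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 0.8))
})

test_that("inverse F1 reconstruction converges with order >= 1.5 away from edges", {
  m <- 2000
  pts <- seq(0, 2 * pi, length.out = m)
  f <- sin(pts)
  inner <- pts >= 0.1 * 2 * pi & pts <= 0.9 * 2 * pi
  errs <- sapply(c(9, 17, 33), function(n) {
    p <- fuzzy_partition(0, 2 * pi, n)
    rec <- inverse_f1_transform(p, f1_transform(p, pts, f), pts)
    max(abs(f - rec)[inner])
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.5))
})

test_that("discrete components approach the integral (quadrature) forms", {
  a <- 0; b <- 2 * pi; n <- 7
  p <- fuzzy_partition(a, b, n)
  pts <- seq(a, b, length.out = 1e5)
  comps <- f1_transform(p, pts, sin(pts))
  Afun <- function(x, k) sapply(x, function(xx) oracle_basis(a, b, n, k, xx))
  for (k in seq_len(n)) {
    lo <- max(a, p$nodes[k] - p$h); hi <- min(b, p$nodes[k] + p$h)
    c0_int <- integrate(function(x) sin(x) * Afun(x, k), lo, hi)$value /
      integrate(function(x) Afun(x, k), lo, hi)$value
    c1_int <- integrate(function(x) sin(x) * (x - p$nodes[k]) * Afun(x, k), lo, hi)$value /
      integrate(function(x) (x - p$nodes[k])^2 * Afun(x, k), lo, hi)$value
    expect_lt(abs(comps$c0[k] - c0_int), 1e-4)
    expect_lt(abs(comps$c1[k] - c1_int), 1e-4)
  }
})

test_that("inverse F1 with zero slopes reduces to the order-0 inverse", {
  set.seed(5)
  p <- fuzzy_partition(0, 10, 6)
  pts <- seq(0, 10, by = 0.1)
  vals <- rnorm(length(pts))
  f0 <- f_transform(p, pts, vals)
  flat <- structure(list(c0 = f0$F, c1 = rep(0, p$n)), class = "f1_components")
  x <- runif(200, 0, 10)
  expect_lt(max(abs(inverse_f1_transform(p, flat, x) -
                    inverse_f_transform(p, f0, x))), 1e-12)

  # linear function, n = 3: the boundary component is an offset line
  # (c0_1 = 1/6 for the identity sample), so the reconstruction at 0.75
  # is the oracle-frozen 0.774407768234, not 0.75 exactly
  p3 <- fuzzy_partition(0, 2, 3)
  lin <- f1_transform(p3, c(0, 0.5, 1, 1.5, 2), c(0, 0.5, 1, 1.5, 2))
  expect_equal(inverse_f1_transform(p3, lin, 0.75), 0.774407768234,
               tolerance = 1e-10)

  # away from the boundary supports a linear function is reproduced exactly
  p6 <- fuzzy_partition(0, 10, 6)
  pts2 <- seq(0, 10, by = 0.25)
  lin6 <- f1_transform(p6, pts2, 2 + 3 * pts2)
  xs <- seq(2.1, 7.9, by = 0.37)
  expect_lt(max(abs(inverse_f1_transform(p6, lin6, xs) - (2 + 3 * xs))), 1e-10)
})
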