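# Independent naive oracles, written directly from the defining formulas
# with scalar double loops. They deliberately share no code with the
# package implementation.

oracle_basis <- function(a, b, n, k, x) {
  h <- (b - a) / (n - 1)
  xk <- a + h * (k - 1)
  lo <- if (k == 1) a else xk - h
  hi <- if (k == n) b else xk + h
  if (x < lo || x > hi || x < a || x > b) return(0)
  0.5 * (1 + cos(pi * (x - xk) / h))
}

oracle_f0 <- function(a, b, n, points, values) {
  sapply(seq_len(n), function(k) {
    num <- 0; den <- 0
    for (i in seq_along(points)) {
      w <- oracle_basis(a, b, n, k, points[i])
      num <- num + values[i] * w
      den <- den + w
    }
    num / den
  })
}

oracle_f1_slopes <- function(a, b, n, points, values) {
  h <- (b - a) / (n - 1)
  sapply(seq_len(n), function(k) {
    xk <- a + h * (k - 1)
    num <- 0; den <- 0
    for (i in seq_along(points)) {
      w <- oracle_basis(a, b, n, k, points[i])
      num <- num + values[i] * (points[i] - xk) * w
      den <- den + (points[i] - xk)^2 * w
    }
    if (den == 0) 0 else num / den
  })
}

oracle_inverse_f1 <- function(a, b, n, c0, c1, x) {
  h <- (b - a) / (n - 1)
  num <- 0; den <- 0
  for (k in seq_len(n)) {
    xk <- a + h * (k - 1)
    w <- oracle_basis(a, b, n, k, x)
    num <- num + (c0[k] + c1[k] * (x - xk)) * w
    den <- den + w
  }
  num / den
}

# Published NWS heat-index chart cells (degrees F), RH% rows by T columns
# 86..96 step 2. Integer apparent temperatures as printed in the chart.
noaa_chart <- local({
  # the RH = 40% row of the chart sits on the strict regression guard
  # (RH > 40) and is excluded
  rows <- list(
    `45` = c(87,  89,  93,  96, 100, 104),
    `50` = c(88,  91,  95,  99, 103, 108),
    `55` = c(89,  93,  97, 101, 106, 112),
    `60` = c(91,  95, 100, 105, 110, 116),
    `65` = c(93,  98, 103, 108, 114, 121),
    `70` = c(95, 100, 105, 112, 119, 126),
    `75` = c(97, 103, 109, 116, 124, 132))
  do.call(rbind, lapply(names(rows), function(rh)
    data.frame(t_f = seq(86, 96, by = 2), rh = as.numeric(rh), hi_f = rows[[rh]])))
})
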