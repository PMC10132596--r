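# Independent loop-based scalar reference for the outranking engine, written
# straight from the definitions. Deliberately naive: explicit loops, no reuse
# of package internals.

oracle_sigma <- function(values, reference, q, p, v, weights) {
  k <- length(values)
  conc <- numeric(k)
  disc <- numeric(k)
  for (j in seq_len(k)) {
    deficit <- reference[j] - values[j]
    conc[j] <- if (deficit <= q) 1
               else if (deficit >= p) 0
               else (p - deficit) / (p - q)
    disc[j] <- if (deficit <= p) 0
               else if (deficit >= v) 1
               else (deficit - p) / (v - p)
  }
  C <- 0
  for (j in seq_len(k)) C <- C + weights[j] * conc[j]
  sigma <- C
  for (j in seq_len(k)) {
    if (disc[j] > C) sigma <- sigma * (1 - disc[j]) / (1 - C)
  }
  sigma
}

oracle_pair <- function(values, boundary, q, p, v, weights) {
  c(sigma_ab = oracle_sigma(values, boundary, q, p, v, weights),
    sigma_ba = oracle_sigma(boundary, values, q, p, v, weights))
}

# Convenience builders -------------------------------------------------------

grid4 <- c(240, 250, 260, 270)

fp4 <- function(id, a, truth = "unknown")
  fingerprint(id, grid4, a, truth_label = truth)

# a random admissible (sample, boundary, thresholds, weights) instance
random_instance <- function() {
  k <- sample(2:6, 1L)
  q <- runif(1, 0, 0.05)
  p <- q + runif(1, 0.001, 0.1)
  v <- p + runif(1, 0.01, 0.2)
  w <- runif(k, 0.1, 1)
  list(values = runif(k, 0, 2),
       boundary = runif(k, 0, 2),
       q = q, p = p, v = v,
       weights = w / sum(w))
}

# a random non-degenerate category system on grid4
random_system <- function(min_gap = 0.2) {
  lower <- runif(4, 0.1, 1.4)
  upper <- lower + runif(4, min_gap, 0.5)
  category_system(grid4, lower, pmin(upper, 2))
}
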