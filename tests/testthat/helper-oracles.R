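# Independent brute-force oracles, kept deliberately naive (double loops)
# so they share no code path with the package implementations.

moran_brute_force <- function(values, weights) {
  n <- length(values)
  xbar <- mean(values)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + weights[i, j] * (values[i] - xbar) * (values[j] - xbar)
      s0 <- s0 + weights[i, j]
    }
  }
  (n / s0) * num / sum((values - xbar)^2)
}

moran_weights_brute_force <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt((lat[i] - lat[j])^2 + (lon[i] - lon[j])^2)
    }
  }
  w <- 1 - d / max(d)
  diag(w) <- 0
  w
}

# small random map for property tests
random_map <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(year = 2000L,
                 lat = runif(n, 54, 60), lon = runif(n, 14, 22),
                 density = rlnorm(n, 5, 1))
}
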