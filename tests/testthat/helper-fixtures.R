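# shared fixtures built in code

# profiles drawn around a shape library: labels + noisy 5-point profiles
make_labelled_profiles <- function(n, shapes, sigma, seed) {
  set.seed(seed)
  lab <- sample.int(nrow(shapes), n, replace = TRUE)
  x <- shapes[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(shapes), 0, sigma), n)
  rownames(x) <- sprintf("p%04d", seq_len(n))
  list(x = x, labels = lab)
}

# a small single-organ config for fast pipeline-stage tests
small_config <- function(...) {
  sim_config(n_entities = 200L, organs = "leaf", seed = 42L, ...)
}

# dense multivariate normal density, the brute-force oracle
# (explicit inverse and determinant; independent of the package's
# Cholesky-factor route)
dense_mvn <- function(x, mu, sigma) {
  d <- length(mu)
  q <- drop(t(x - mu) %*% solve(sigma) %*% (x - mu))
  exp(-0.5 * q) / sqrt((2 * pi)^d * det(sigma))
}

# random symmetric positive-definite matrix
random_pd <- function(d, seed) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d)
  crossprod(a) + diag(d) * 0.5
}

# direct step-up Benjamini-Hochberg, written from the definition
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  adj
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
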