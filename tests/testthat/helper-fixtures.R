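# Shared fixtures, built in code at test time.

# Small replicate table on the log2 scale with explicit values.
make_log2_table <- function(values, treatments, n_rep, control = "control",
                            layer = "layer") {
  replicate_table(values,
                  treatment = rep(treatments, each = n_rep),
                  replicate = rep(seq_len(n_rep), length(treatments)),
                  control_label = control, layer_name = layer,
                  log2_scale = TRUE)
}

# Block-structured expression matrix: `k` modules of `size` analytes over
# `n_samples`, zero noise unless stated; returns list(x, module_of).
make_block_matrix <- function(k = 3, size = 30, n_samples = 12, noise = 0,
                              n_grey = 0, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(k * n_samples), k)
  x <- do.call(rbind, lapply(seq_len(k), function(m) {
    load <- runif(size, 0.6, 0.95) * sample(c(-1, 1), size, TRUE)
    outer(load, E[m, ]) + matrix(rnorm(size * n_samples, 0, noise), size)
  }))
  if (n_grey > 0) {
    x <- rbind(x, matrix(rnorm(n_grey * n_samples), n_grey))
  }
  rownames(x) <- sprintf("a%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(n_samples))
  module_of <- stats::setNames(
    c(rep(paste0("planted_", seq_len(k)), each = size),
      rep("grey", n_grey)), rownames(x))
  list(x = x, module_of = module_of, eigengenes = E)
}

# Brute-force BH step-up oracle: p_(i) * m / i with monotone enforcement.
bh_oracle <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  m <- length(q)
  o <- order(q)
  adj <- numeric(m)
  adj[o] <- vapply(seq_len(m), function(i) {
    min(1, min(q[o][i:m] * m / (i:m)))
  }, numeric(1))
  out <- rep(NA_real_, length(p))
  out[ok] <- adj
  out
}

# Brute-force triple-loop TOM oracle.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# Random symmetric adjacency in [0,1] with unit diagonal.
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("a%02d", 1:n), sprintf("a%02d", 1:n))
  a
}
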