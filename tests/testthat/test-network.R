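test_that("integer range scaling maps layer extremes and rounds half away from zero", {
  m <- matrix(c(-2, 0, 2), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  s <- scale_to_int_range(m)
  expect_equal(unname(s$values[, 1]), c(0, 50, 100))
  m2 <- matrix(c(-2, -1, 2), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(scale_to_int_range(m2)$values[, 1]), c(0, 25, 100))
  const <- matrix(1.5, 2, 3, dimnames = list(c("a", "b"), NULL))
  expect_true(all(scale_to_int_range(const)$values == 50))
  expect_true(all(scale_to_int_range(m)$values ==
                    round(scale_to_int_range(m)$values)))
})

test_that("soft-threshold adjacency obeys the power law and affine invariance", {
  set.seed(4)
  x <- matrix(rnorm(5 * 20), 5, dimnames = list(paste0("a", 1:5), NULL))
  x[2, ] <- 2 * x[1, ] + 5                    # affine image: cor 1
  net <- adjacency_network(x, beta = 18)
  expect_equal(net$adjacency["a1", "a2"], 1)
  expect_equal(diag(net$adjacency), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
  # a = |cor|^beta: cor 0.9 -> 0.9^18
  r <- cor(x["a3", ], x["a4", ])
  expect_equal(net$adjacency["a3", "a4"], abs(r)^18, tolerance = 1e-12)
  expect_equal(0.9^18, 0.15009, tolerance = 1e-4)
  # unsigned adjacency invariant under negative affine transforms too
  x2 <- x; x2[3, ] <- -3 * x[3, ] + 1
  net2 <- adjacency_network(x2, beta = 18)
  expect_equal(net2$adjacency["a3", "a4"], net$adjacency["a3", "a4"],
               tolerance = 1e-12)
  # signed network: a = ((1+cor)/2)^beta
  nets <- adjacency_network(x, beta = 6, network_type = "signed")
  expect_equal(nets$adjacency["a3", "a4"], ((1 + r) / 2)^6, tolerance = 1e-12)
})

test_that("pairs with too few shared samples get zero adjacency", {
  x <- matrix(rnorm(3 * 6), 3, dimnames = list(paste0("a", 1:3), NULL))
  x[1, 3:6] <- NA                              # only 2 shared with others
  net <- adjacency_network(x, beta = 2)
  expect_equal(net$adjacency["a1", "a2"], 0)
  expect_equal(net$adjacency["a1", "a1"], 1)
})

test_that("scale-free fit is perfect on an exact power law and degrades on noise", {
  k <- rep(c(10, 20, 40, 80, 160), times = c(160, 80, 40, 20, 10))
  fit <- scale_free_fit(k, n_bins = 40)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(fit$slope, 0)
  expect_true(is.na(scale_free_fit(rep(3, 10))$r_squared))
  expect_error(scale_free_fit(5), "at least 2")
  # a modular network with graded module sizes (hub-like connectivity
  # spectrum) fits the power law far better than an Erdos-Renyi-like
  # constant-probability adjacency of the same size
  set.seed(2)
  E <- matrix(rnorm(6 * 12), 6)
  sizes <- c(60, 40, 25, 15, 10, 6)
  x <- do.call(rbind, lapply(1:6, function(m) {
    load <- runif(sizes[m], 0.6, 0.95) * sample(c(-1, 1), sizes[m], TRUE)
    outer(load, E[m, ]) + matrix(rnorm(sizes[m] * 12, 0, 0.3), sizes[m])
  }))
  x <- rbind(x, matrix(rnorm(100 * 12), 100))
  rownames(x) <- sprintf("a%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", 1:12)
  net_mod <- adjacency_network(x, beta = 18)
  set.seed(3)
  n <- nrow(x)
  a <- matrix(rbinom(n * n, 1, 0.1) * 1.0, n)
  a <- pmax(a, t(a)); diag(a) <- 1
  dimnames(a) <- list(rownames(x), rownames(x))
  net_er <- structure(list(adjacency = a, tom = NULL, beta = 1,
                           network_type = "unsigned"),
                      class = "coexpression_network")
  expect_gt(scale_free_fit(net_mod)$r_squared,
            scale_free_fit(net_er)$r_squared + 0.3)
})

test_that("TOM matches the hand example and the triple-loop oracle", {
  # 3-node network, all off-diagonal adjacency 0.5
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(paste0("a", 1:3), paste0("a", 1:3))
  net <- structure(list(adjacency = a, tom = NULL, beta = 1,
                        network_type = "unsigned"),
                   class = "coexpression_network")
  tom <- tom_similarity(net)$tom
  expect_equal(tom["a1", "a2"], (0.25 + 0.5) / (1 + 1 - 0.5))
  # zero off-diagonal adjacency -> zero off-diagonal TOM
  z <- diag(4); dimnames(z) <- list(paste0("a", 1:4), paste0("a", 1:4))
  netz <- structure(list(adjacency = z, tom = NULL, beta = 1,
                         network_type = "unsigned"),
                    class = "coexpression_network")
  expect_true(all(tom_similarity(netz)$tom == diag(4)))
  # oracle equivalence on random 15-node networks
  for (s in 1:20) {
    a <- random_adjacency(15, seed = s)
    net <- structure(list(adjacency = a, tom = NULL, beta = 1,
                          network_type = "unsigned"),
                     class = "coexpression_network")
    tom <- tom_similarity(net)$tom
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("module eigengenes match the eigendecomposition oracle", {
  # identical standardized rows: eigengene equals the profile, VE = 1
  prof <- rnorm(8)
  x <- outer(2:5, prof)        # scaled copies of one profile
  rownames(x) <- paste0("a", 1:4); colnames(x) <- paste0("s", 1:8)
  me <- module_eigengenes(x, setNames(rep("m1", 4), rownames(x)))
  expect_equal(me$variance_explained[["m1"]], 1, tolerance = 1e-12)
  expect_equal(abs(cor(me$values["m1", ], prof)), 1, tolerance = 1e-12)
  expect_gte(cor(me$values["m1", ], colMeans(t(scale(t(x))))), 0)
  expect_equal(sd(me$values["m1", ]), 1, tolerance = 1e-12)
  # variance explained equals the leading eigenvalue fraction (oracle)
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(rnorm(10 * 8), 10,
                dimnames = list(paste0("a", 1:10), paste0("s", 1:8)))
    me <- module_eigengenes(x, setNames(rep("m1", 10), rownames(x)))
    z <- t(scale(t(x)))
    ev <- eigen(crossprod(z), symmetric = TRUE)$values
    expect_equal(me$variance_explained[["m1"]], ev[1] / sum(ev),
                 tolerance = 1e-10)
  }
  # sign convention: flipping every analyte flips the mean profile and the
  # eigengene with it, so the convention stays satisfied
  me_flip <- module_eigengenes(-x, setNames(rep("m1", 10), rownames(x)))
  expect_gte(cor(me_flip$values["m1", ], colMeans(t(scale(t(-x))))), 0)
})

test_that("module detection recovers planted zero-noise modules exactly", {
  blk <- make_block_matrix(k = 3, size = 30, n_samples = 12, noise = 0, seed = 7)
  net <- tom_similarity(adjacency_network(blk$x, beta = 18))
  part <- detect_modules(net, blk$x, min_module_size = 25)
  expect_equal(mclust::adjustedRandIndex(part$module_of, blk$module_of), 1)
  expect_setequal(unique(part$module_of), c("turquoise", "blue", "brown"))
  # labels ordered by size: all equal here, ties by internal label
  sizes <- table(part$module_of)
  expect_true(all(sizes >= 25))
})

test_that("min_module_size above every planted module leaves all analytes grey", {
  blk <- make_block_matrix(k = 3, size = 20, n_samples = 12, noise = 0, seed = 7)
  net <- tom_similarity(adjacency_network(blk$x, beta = 18))
  part <- detect_modules(net, blk$x, min_module_size = 50)
  expect_true(all(part$module_of == "grey"))
})

test_that("modules with nearly identical eigengenes are merged", {
  set.seed(11)
  e <- rnorm(12)
  e2 <- 0.98 * scale(e)[, 1] + sqrt(1 - 0.98^2) * scale(resid(lm(rnorm(12) ~ e)))[, 1]
  expect_gt(cor(e, e2), 0.95)
  x <- rbind(outer(runif(30, 0.6, 0.95), scale(e)[, 1]),
             outer(runif(30, 0.6, 0.95), e2)) +
    matrix(rnorm(60 * 12, 0, 0.01), 60)
  rownames(x) <- paste0("a", 1:60); colnames(x) <- paste0("s", 1:12)
  net <- tom_similarity(adjacency_network(x, beta = 18))
  part <- detect_modules(net, x, min_module_size = 25, merge_cut_height = 0.1)
  expect_equal(length(setdiff(unique(part$module_of), "grey")), 1)
  # and kept apart when the merge cut is tightened below their dissimilarity
  part2 <- detect_modules(net, x, min_module_size = 25,
                          merge_cut_height = 0.001)
  expect_equal(length(setdiff(unique(part2$module_of), "grey")), 2)
})

test_that("partition labels are stable under analyte permutation", {
  blk <- make_block_matrix(k = 3, size = 30, n_samples = 12, noise = 0.1,
                           n_grey = 10, seed = 13)
  net <- tom_similarity(adjacency_network(blk$x, beta = 18))
  part <- detect_modules(net, blk$x, min_module_size = 25)
  set.seed(1)
  perm <- sample(nrow(blk$x))
  xp <- blk$x[perm, ]
  netp <- tom_similarity(adjacency_network(xp, beta = 18))
  partp <- detect_modules(netp, xp, min_module_size = 25)
  expect_equal(mclust::adjustedRandIndex(part$module_of,
                                         partp$module_of[names(part$module_of)]), 1)
})
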