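test_that("top-3 peptide quantification follows the stated rule", {
  peptides <- matrix(c(10, 20, 30, 40,   # protein P1, 4 peptides, sample s1
                       3, 6, 9, NA,
                       7, NA, NA, NA),
                     nrow = 4, ncol = 3,
                     dimnames = list(paste0("pep", 1:4),
                                     c("A.1", "B.1", "C.1")))
  # pad to give every protein >= 2 peptides
  peptides <- rbind(peptides,
                    pep5 = c(NA, 3, 7), pep6 = c(NA, NA, NA))
  protein_of <- c("P1", "P1", "P1", "P1", "P2", "P2")
  out <- protein_quant_top3(peptides, protein_of,
                            treatment = c("A", "B", "C"),
                            replicate = c(1, 1, 1), control_label = "A")
  # {10,20,30,40} -> mean of top three (40,30,20) = 30
  expect_equal(out$values["P1", "A.1"], 30)
  # exactly three present {3,6,9} -> mean of all = 6
  expect_equal(out$values["P1", "B.1"], 6)
  # single peptide {7} -> 7
  expect_equal(out$values["P1", "C.1"], 7)
  # zero quantified peptides -> absent, not zero
  expect_true(is.na(out$values["P2", "A.1"]))
})

test_that("log2 median normalization centers each column at zero", {
  v <- matrix(c(2, 4, 8,
                5, 5, 5,
                2, NA, 8), nrow = 3, byrow = FALSE,
              dimnames = list(c("a1", "a2", "a3"), NULL))
  tab <- replicate_table(v, treatment = c("T", "T", "control"),
                         replicate = c(1, 2, 1), control_label = "control")
  out <- normalize_log2_median(tab)
  # column {2,4,8}: log2 {1,2,3}, median 2 -> {-1,0,1}
  expect_equal(unname(out$values[, 1]), c(-1, 0, 1))
  # identical values -> all zeros
  expect_equal(unname(out$values[, 2]), c(0, 0, 0))
  # absent entry: median over remaining entries only
  expect_equal(unname(out$values[, 3]), c(-1, NA, 1))
  expect_true(out$log2_scale)
  # non-positive intensity names the offending entry
  v[2, 1] <- 0
  tab0 <- replicate_table(v, treatment = c("T", "T", "control"),
                          replicate = c(1, 2, 1), control_label = "control")
  expect_error(normalize_log2_median(tab0), "a2")
})

test_that("cell-count normalization divides by counts and blanks sub-LOD values", {
  v <- matrix(c(100, 50, 8, 200, 80, 12), nrow = 3,
              dimnames = list(c("m1", "m2", "m3"), NULL))
  tab <- replicate_table(v, treatment = c("T", "control"),
                         replicate = c(1, 1), control_label = "control",
                         cell_counts = c(4e6, 2e6),
                         lod = c(m1 = 0, m2 = 0, m3 = 10))
  out <- normalize_cell_count(tab, reference = 1e6)
  expect_equal(out$values["m1", 1], 25)            # 100 / (4e6/1e6)
  expect_true(is.na(out$values["m3", 1]))          # 8 below LOD 10
  expect_equal(out$values["m3", 2], 6)             # 12 >= LOD, / 2
  # equal counts leave values proportional to input
  tab2 <- replicate_table(v, treatment = c("T", "control"),
                          replicate = c(1, 1), control_label = "control",
                          cell_counts = c(2e6, 2e6))
  out2 <- normalize_cell_count(tab2)
  expect_equal(unname(out2$values), unname(v / 2))
  # missing counts error
  tab$cell_counts <- NULL
  expect_error(normalize_cell_count(tab), "cell counts")
})

test_that("replicate filter requires min_present in every treatment", {
  v <- matrix(1, nrow = 3, ncol = 10,
              dimnames = list(c("full", "gap", "edge"), NULL))
  v["gap", 1:3] <- NA                 # 2/5 present in treatment T
  v["edge", 1:2] <- NA                # exactly 3/5 present
  tab <- make_log2_table(v, c("T", "control"), n_rep = 5)
  expect_setequal(replicate_filter(tab, 3), c("full", "edge"))
  expect_setequal(replicate_filter(tab, 0), c("full", "gap", "edge"))
  # monotone: raising min_present never retains more
  n_kept <- vapply(0:5, function(m) length(replicate_filter(tab, m)), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("fold-change t-test matches the closed-form pooled-variance oracle", {
  x <- c(1.1, 1.3, 1.2); y <- c(0.1, 0.2, 0.0)
  v <- matrix(c(x, y), nrow = 1,
              dimnames = list("a1", NULL))
  tab <- make_log2_table(v, c("T", "control"), n_rep = 3)
  fc <- fold_change_test(tab)
  expect_equal(fc$log2fc["a1", "T"], mean(x) - mean(y))
  # closed-form pooled t with 4 df
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(abs(t_stat), df = 4, lower.tail = FALSE)
  expect_equal(fc$p_raw["a1", "T"], p_oracle, tolerance = 1e-12)
})

test_that("identical treatment and control replicates give zero FC and p = 1", {
  v <- matrix(c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1,
                2, 2, 2, 2, 2, 2, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("shifted", "flat"), NULL))
  tab <- make_log2_table(v, c("T", "control"), n_rep = 5)
  fc <- fold_change_test(tab)
  expect_equal(fc$log2fc["flat", "T"], 0)
  expect_equal(fc$p_raw["flat", "T"], 1)
  expect_equal(fc$log2fc["shifted", "T"], 1)   # means differ by 1
})

test_that("results are invariant to analyte row order", {
  set.seed(1)
  v <- matrix(rnorm(20 * 10, 10), nrow = 20,
              dimnames = list(sprintf("a%02d", 1:20), NULL))
  tab <- make_log2_table(v, c("T", "control"), n_rep = 5)
  perm <- sample(20)
  tabp <- make_log2_table(v[perm, ], c("T", "control"), n_rep = 5)
  fc <- fold_change_test(tab); fcp <- fold_change_test(tabp)
  expect_equal(fcp$log2fc[rownames(fc$log2fc), , drop = FALSE], fc$log2fc)
  expect_equal(fcp$p_adj[rownames(fc$p_adj), , drop = FALSE], fc$p_adj)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)                      # single p unchanged
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))    # all equal
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # adjusted >= raw, rank order preserved
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("significant counts respect alpha and recover planted effects", {
  g <- c(1, 1.2, 0.8, 1, 1.1)
  v <- rbind(a = c(g + 1, g),          # clear increase
             b = c(g, g + 1),         # clear decrease
             c = c(g, g + 0.001))     # negligible shift: p far above 0.05
  tab <- make_log2_table(v, c("T", "control"), n_rep = 5)
  fc <- fold_change_test(tab)
  expect_gt(fc$p_raw["c", "T"], 0.5)
  cnt05 <- count_significant(fc, alpha = 0.05)
  expect_equal(cnt05$total, 2L)
  expect_equal(cnt05$up, 1L)
  expect_equal(cnt05$down, 1L)
  # alpha = 1 counts every tested analyte
  expect_equal(count_significant(fc, alpha = 1)$total, 3L)
  # planted differential analytes: adjusted-count totals within 10%
  ratios <- sapply(1:20, function(s) {
    cfg <- generator_config(n_treatments = 6, layers = c(proteomics = 200),
                            network_layers = "proteomics", n_modules = 0,
                            traits = NULL, effect_size = 2, noise_sd = 0.1,
                            active_pattern = list(proteomics = c("NM01", "NM02")),
                            treatment_names = sprintf("NM%02d", 1:6), seed = s)
    ds <- generate_dataset(cfg)
    tab <- normalize_log2_median(ds$layers$proteomics)
    fc <- fold_change_test(tab)
    cnt <- count_significant(fc, use_adjusted = TRUE)
    planted <- colSums(ds$truth$differential_flags$proteomics)
    cnt$total[cnt$treatment == "NM01"] / planted["NM01"]
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
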