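test_that("log2_transform maps values and preserves missingness", {
  x <- rbind(c(8, 1, 2, NA), c(1024, 4, NA, 0.5))
  m <- tiny_matrix(rbind(x, x))
  l <- log2_transform(m)
  expect_equal(l$intensity[1, 1], 3)
  expect_equal(l$intensity[1, 2], 0)
  expect_true(is.na(l$intensity[1, 4]))
  expect_equal(l$scale, "log2")
  # inverse round trip
  expect_equal(2^l$intensity, m$intensity, tolerance = 1e-12)
  # applying twice is a no-op
  expect_identical(log2_transform(l)$intensity, l$intensity)
})

test_that("impute_constant fills with global minimum minus offset", {
  x <- rbind(c(12, 10, 11, NA), c(13, NA, 15, 14),
             c(10.5, 11, 12, 13), c(NA, NA, 12, 12))
  m <- tiny_matrix(x)
  m$scale <- "log2"
  imp <- impute_constant(m, analysis_config(imputation_offset = 1))
  expect_equal(unname(imp$intensity[1, 4]), 9)   # min observed 10, offset 1
  expect_false(anyNA(imp$intensity))
  expect_identical(unname(imp$mask), unname(!is.na(x)))
  # imputed cells sit strictly below every observed value
  expect_lt(max(imp$intensity[!imp$mask]), min(x, na.rm = TRUE))
  # no missing values: identity
  x2 <- x; x2[is.na(x2)] <- 11
  m2 <- tiny_matrix(x2); m2$scale <- "log2"
  expect_identical(impute_constant(m2)$intensity, m2$intensity)
  # fully missing matrix is an error
  m3 <- tiny_matrix(matrix(NA_real_, 4, 4)); m3$scale <- "log2"
  expect_error(impute_constant(m3), "fully missing")
  # linear input is rejected
  expect_error(impute_constant(tiny_matrix(x)), "log2")
})

test_that("ttest_contrast matches the textbook oracle and its conventions", {
  d <- two_group_design()
  A <- d$sample[d$treatment == "trt"]; B <- d$sample[d$treatment == "ctl"]
  x <- rbind(c(10.0, 10.2, 9.8, 8.0, 8.2, 7.8),   # oracle row
             c(1, 2, 3, 1, 2, 3),                 # identical groups
             c(5, 5, 5, 4, 4, 4),                 # zero variance, diff means
             c(5, 5, 5, 5, 5, 5))                 # zero variance, equal
  m <- matrix_from(x, d)
  r <- ttest_contrast(m, A, B)
  expect_equal(r$estimate[1], 2.0, tolerance = 1e-12)
  # frozen from the textbook statistic t = 2.0/(0.2*sqrt(2/3)), df = 4
  expect_equal(r$p_value[1], 0.000255216749442, tolerance = 1e-9)
  expect_equal(r$estimate[2], 0)
  expect_equal(r$p_value[2], 1)
  expect_equal(r$p_value[3], 0)   # zero pooled variance, unequal means
  expect_equal(r$p_value[4], 1)   # zero pooled variance, equal means
  expect_true(r$significant[1] && !r$significant[2])

  # invariance under adding a constant; antisymmetry under group swap
  m_shift <- matrix_from(x + 100, d)
  expect_equal(ttest_contrast(m_shift, A, B)$p_value, r$p_value,
               tolerance = 1e-9)
  r_swap <- ttest_contrast(m, B, A)
  expect_equal(r_swap$estimate, -r$estimate)
  expect_equal(r_swap$p_value, r$p_value, tolerance = 1e-12)

  # contract violations
  expect_error(ttest_contrast(m, A, c(B, A[1])), "overlap")
  expect_error(ttest_contrast(m, A[1], B), ">= 2")
})

test_that("Welch option agrees with stats::t.test", {
  set.seed(1)
  d <- two_group_design(3, 4)
  x <- matrix(rnorm(7 * 10), 10, 7)
  m <- matrix_from(x, d)
  A <- d$sample[d$treatment == "trt"]; B <- d$sample[d$treatment == "ctl"]
  r <- ttest_contrast(m, A, B, analysis_config(welch = TRUE))
  ref <- apply(x, 1, function(v)
    t.test(v[1:3], v[4:7], var.equal = FALSE)$p.value)
  expect_equal(r$p_value, unname(ref), tolerance = 1e-12)
})

test_that("anova_all_groups: F = t^2, null identity and the LSD rule", {
  cfg <- analysis_config()
  # F = t^2 identity on 100 random instances
  set.seed(42)
  d <- two_group_design()
  A <- d$sample[d$treatment == "trt"]; B <- d$sample[d$treatment == "ctl"]
  x <- matrix(rnorm(600), 100, 6)
  m <- matrix_from(x, d)
  tt <- ttest_contrast(m, A, B, cfg)
  an <- anova_all_groups(m, list(trt = A, ctl = B), cfg)
  tstat <- tt$estimate /
    sqrt(((apply(x[, 1:3], 1, var) + apply(x[, 4:6], 1, var)) / 2) * (2 / 3))
  expect_equal(attr(an, "F"), tstat^2, tolerance = 1e-8)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)

  # all groups identical -> p = 1
  x0 <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 5), 5, 6)
  m0 <- matrix_from(x0, d)
  expect_true(all(anova_all_groups(m0, list(A = A, B = B), cfg)$p_value == 1))

  # LSD critical difference equals its closed form and shrinks with n
  crit <- attr(an, "critical_difference")
  ms_w <- (apply(x[, 1:3], 1, var) + apply(x[, 4:6], 1, var)) / 2
  expect_equal(crit, qt(0.975, 4) * sqrt(2 * median(ms_w) / 3),
               tolerance = 1e-12)
  d8 <- two_group_design(6, 6)
  x8 <- cbind(x, x)[, 1:12]
  m8 <- matrix_from(x8, d8)
  an8 <- anova_all_groups(m8, split(d8$sample, d8$treatment), cfg)
  expect_lt(attr(an8, "critical_difference"), crit)

  expect_error(anova_all_groups(m, list(A = A)), ">= 2 groups")
  expect_error(anova_all_groups(m, list(A = A, B = c(B, A[1]))), "overlap")
})

test_that("pca_samples separates duplicated groups and conserves variance", {
  d <- two_group_design()
  set.seed(7)
  base <- rnorm(20, 10, 1)
  x <- cbind(base, base + 0.01, base - 0.01,
             base + 5, base + 5.01, base + 4.99) +
    matrix(rnorm(120, 0, 0.01), 20, 6)
  m <- matrix_from(x, d)
  pc <- pca_samples(m)
  s1 <- pc$scores[1:3, 1]; s2 <- pc$scores[4:6, 1]
  expect_true(all(sign(s1) == sign(s1[1])) &&
                all(sign(s2) == -sign(s1[1])))
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1)
  # total variance conservation: component variances sum to the matrix's
  total_var <- sum(apply(t(x), 2, var))
  expect_equal(sum(apply(pc$scores, 2, var)), total_var, tolerance = 1e-9)
})

test_that("cluster_significant builds the expected average-linkage tree", {
  d <- two_group_design()
  set.seed(3)
  p1 <- c(0, 1, 2, 3, 4, 5)
  x <- rbind(p1, p1 + 1e-9, rev(p1), rev(p1) + c(0, 0.5, 0, 0.5, 0, 0.5))
  m <- matrix_from(x, d)
  m$scale <- "log2"
  cl <- cluster_significant(m, proteins(m), analysis_config())
  # identical profiles merge first at height ~0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-6)
  expect_setequal(-cl$hclust$merge[1, ], c(1, 2))
  # final average-linkage height equals the hand-computed mean of the four
  # cross-pair Euclidean distances of the z-scored profiles
  z <- cl$z
  cross <- c(sqrt(sum((z[1, ] - z[3, ])^2)), sqrt(sum((z[1, ] - z[4, ])^2)),
             sqrt(sum((z[2, ] - z[3, ])^2)), sqrt(sum((z[2, ] - z[4, ])^2)))
  expect_equal(max(cl$hclust$height), mean(cross), tolerance = 1e-9)
  # cophenetic distances are ultrametric
  cop <- as.matrix(cophenetic(cl$hclust))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(cop[i, j], max(cop[i, k], cop[k, j]) + 1e-12)
  # Newick string parses back to the same number of tips
  tree <- ape::read.tree(text = cl$newick)
  expect_equal(sort(tree$tip.label), sort(proteins(m)))
  expect_error(cluster_significant(m, proteins(m)[1]), ">= 2")
})

test_that("type-I error is calibrated under the global null", {
  # smaller companion to the acceptance-scale calibration check
  cfg <- simulation_config(n_proteins = 400, frac_de_hx = 0, frac_de_as = 0,
                           detection_limit = -Inf, seed = 99)
  m <- simulate_matrix(simulate_catalog(cfg), cfg)
  ml <- impute_constant(log2_transform(m))
  d <- m$design; br <- d[d$rep_kind == "BR", ]
  A <- br$sample[br$cell_line == "LNCaP" & br$timepoint == "8h" &
                   br$treatment == "DMOG"]
  B <- br$sample[br$cell_line == "LNCaP" & br$timepoint == "8h" &
                   br$treatment == "control"]
  frac <- mean(ttest_contrast(ml, A, B)$significant)
  bounds <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})
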